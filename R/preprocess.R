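#' Variance-stabilizing-style transform of a count matrix
#'
#' Library-size correction by median-of-ratios size factors (the geometric
#' mean over rows with no zero or missing values is the reference) followed by
#' `log2(value / size_factor + 1)`. Monotone within each sample; missing
#' values stay missing.
#'
#' @param m Non-negative orthogroup x sample matrix (NA allowed).
#' @return Transformed matrix of the same shape, with the size factors in
#'   attribute `"size_factors"`.
#' @export
vst_transform <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  all_zero <- colSums(m, na.rm = TRUE) == 0 & colSums(!is.na(m)) > 0
  if (any(all_zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[all_zero], collapse = ", "), call. = FALSE)
  }
  complete <- rowSums(is.na(m)) == 0 & rowSums(m == 0, na.rm = TRUE) == 0
  if (!any(complete)) {
    warning("no rows free of zeros/missing values; size factors set to 1")
    sf <- rep(1, ncol(m))
  } else {
    ref <- exp(rowMeans(log(m[complete, , drop = FALSE])))
    sf <- apply(m[complete, , drop = FALSE] / ref, 2, stats::median)
  }
  out <- log2(sweep(m, 2, sf, "/") + 1)
  attr(out, "size_factors") <- stats::setNames(sf, colnames(m))
  out
}

#' Quantile normalization across samples
#'
#' Forces every column to the same distribution: the across-column mean of
#' order statistics, with ties averaged and missing values excluded from rank
#' computation (and left missing).
#'
#' @param m Numeric matrix (orthogroups x samples).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 1) {
    warning("single-column matrix returned unchanged")
    return(m)
  }
  if (any(colSums(!is.na(m)) == 0)) {
    stop("fully-missing column(s) cannot be quantile normalized", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Filter orthogroups on missingness and expression variance in two stages
#'
#' Removes any orthogroup with more than `max_missing` missing values or with
#' variance strictly below `min_variance` in either stage; when
#' `require_common = TRUE` the two returned matrices keep the identical
#' surviving row set. Variance is computed on the values as given (apply after
#' the transform: the default threshold 0.3 is meaningful on a log-like
#' scale), missingness on the NA pattern, which the transforms preserve from
#' the raw counts.
#'
#' @param bud,d Expression matrices for the two stages sharing an orthogroup
#'   id universe (row names).
#' @param max_missing Maximum tolerated fraction of missing values per row.
#' @param min_variance Rows with variance `< min_variance` are removed
#'   (a row at exactly the threshold is kept).
#' @param require_common Keep only rows surviving in both stages.
#' @return List with elements `bud`, `d` (filtered matrices) and `report`
#'   (tibble of removal counts per criterion and stage).
#' @export
filter_orthogroups <- function(bud, d, max_missing = 0.5, min_variance = 0.3,
                               require_common = TRUE) {
  if (length(intersect(rownames(bud), rownames(d))) == 0) {
    stop("`bud` and `d` share no orthogroup ids", call. = FALSE)
  }
  crit <- function(m) {
    miss <- rowMeans(is.na(m)) > max_missing
    v <- apply(m, 1, stats::var, na.rm = TRUE)
    lowvar <- !is.na(v) & v < min_variance
    lowvar[is.na(v)] <- TRUE
    list(miss = miss, lowvar = lowvar, keep = !(miss | lowvar))
  }
  cb <- crit(bud); cd <- crit(d)
  report <- tibble::tibble(
    stage = c("bud", "d"),
    n_input = c(nrow(bud), nrow(d)),
    removed_missing = c(sum(cb$miss), sum(cd$miss)),
    removed_low_variance = c(sum(cb$lowvar), sum(cd$lowvar)),
    removed_either = c(sum(!cb$keep), sum(!cd$keep))
  )
  keep_b <- rownames(bud)[cb$keep]
  keep_d <- rownames(d)[cd$keep]
  if (require_common) {
    common <- intersect(keep_b, keep_d)
    keep_b <- rownames(bud)[rownames(bud) %in% common]
    keep_d <- rownames(d)[rownames(d) %in% common]
  }
  list(bud = bud[keep_b, , drop = FALSE], d = d[keep_d, , drop = FALSE],
       report = report)
}

#' Regress confounder principal components out of an expression matrix
#'
#' Rows are standardized, the top-`k` sample-space principal components are
#' computed, and each row is replaced by its least-squares residual on those
#' components (row mean restored). `k = "auto"` selects the number of
#' components whose eigenvalue exceeds the 95th percentile of `n_null`
#' row-permutation nulls (a Buja-Eyuboglu-style parallel analysis).
#'
#' @param m Expression matrix (orthogroups x samples). Missing entries are
#'   mean-imputed for the component estimation and left missing in the output.
#' @param k Number of components to remove, or `"auto"`.
#' @param seed Integer seed (used by `"auto"` and ignored otherwise).
#' @param n_null Number of permutation nulls for `"auto"`.
#' @return Residual matrix of the same shape, with attribute `"k"`.
#' @export
remove_confounder_pcs <- function(m, k = "auto", seed = 1, n_null = 100) {
  m <- as.matrix(m)
  n <- ncol(m)
  auto <- identical(k, "auto")
  if (!auto && (!is.numeric(k) || k >= n || k < 0)) {
    stop("`k` must be \"auto\" or an integer in [0, n_samples)", call. = FALSE)
  }
  if (!auto && k == 0) {
    attr(m, "k") <- 0L
    return(m)
  }
  row_mean <- rowMeans(m, na.rm = TRUE)
  row_sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(row_sd) & row_sd > 0
  z <- (m[keep, , drop = FALSE] - row_mean[keep]) / row_sd[keep]
  z_imp <- z
  z_imp[is.na(z_imp)] <- 0

  sv <- svd(z_imp, nu = 0, nv = n)
  eig <- sv$d^2
  if (auto) {
    set.seed(as.integer(seed))
    null_top <- matrix(NA_real_, n_null, length(eig))
    for (b in seq_len(n_null)) {
      zp <- t(apply(z_imp, 1, sample))
      null_top[b, ] <- svd(zp, nu = 0, nv = 0)$d^2
    }
    thresh <- apply(null_top, 2, stats::quantile, probs = 0.95)
    k <- match(FALSE, eig > thresh, nomatch = length(eig) + 1L) - 1L
    if (k == 0) {
      attr(m, "k") <- 0L
      return(m)
    }
  }
  k <- as.integer(k)
  pcs <- sv$v[, seq_len(k), drop = FALSE] # samples x k, orthonormal

  out <- m
  rows <- which(keep)
  for (i in rows) {
    y <- m[i, ]
    ok <- !is.na(y)
    X <- cbind(1, pcs[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, y[ok])
    out[i, ok] <- fit$residuals + mean(y[ok])
  }
  attr(out, "k") <- k
  out
}

#' Run the full per-stage preprocessing chain
#'
#' Transform ([vst_transform()]) then quantile normalize
#' ([quantile_normalize()]) each stage, filter jointly
#' ([filter_orthogroups()]; missingness from the NA pattern, variance on the
#' transformed scale), then remove confounder principal components
#' ([remove_confounder_pcs()]).
#'
#' @inheritParams filter_orthogroups
#' @inheritParams remove_confounder_pcs
#' @param bud,d Raw count matrices for the two stages.
#' @return List `bud`, `d`, `report` as in [filter_orthogroups()].
#' @export
preprocess_stages <- function(bud, d, max_missing = 0.5, min_variance = 0.3,
                              require_common = TRUE, k = 0, seed = 1) {
  tb <- quantile_normalize(vst_transform(bud))
  td <- quantile_normalize(vst_transform(d))
  flt <- filter_orthogroups(tb, td, max_missing = max_missing,
                            min_variance = min_variance,
                            require_common = require_common)
  flt$bud <- remove_confounder_pcs(flt$bud, k = k, seed = seed)
  flt$d <- remove_confounder_pcs(flt$d, k = k, seed = seed)
  flt
}
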
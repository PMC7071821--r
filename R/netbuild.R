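#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation. For a vector x with median m and
#' `MAD = median(|x - m|)`, define `u_i = (x_i - m) / (9 MAD)` and Tukey
#' weights `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (else 0); the biweight
#' midcorrelation of x and y is the inner product of the weighted, normalized
#' deviations. `max_p_outliers` caps the influence of extreme points: if the
#' `max_p_outliers` (or `1 - max_p_outliers`) quantile of u lies beyond ±1,
#' that side of u is shrunk so the quantile maps to ±1, guaranteeing that at
#' most that fraction of points per side receives zero weight.
#'
#' Pairs are computed over pairwise-complete samples. A vector with zero MAD
#' (within a pair's complete samples) falls back to Pearson for the pairs it
#' enters, with a warning; pairs with fewer than 4 shared samples get `NA`.
#'
#' @param m Expression matrix (genes x samples, NA allowed).
#' @param max_p_outliers Maximum fraction of samples per side allowed to be
#'   downweighted to zero (default 0.05).
#' @return Symmetric genes x genes correlation matrix, diagonal 1, with
#'   attributes `method = "bicor"` and `max_p_outliers`.
#' @export
bicor_matrix <- function(m, max_p_outliers = 0.05) {
  m <- as.matrix(m)
  if (ncol(m) < 4) stop("need at least 4 samples", call. = FALSE)
  p <- nrow(m)

  prep <- function(x) {
    med <- stats::median(x)
    mad <- stats::median(abs(x - med))
    if (mad == 0) return(NULL) # caller falls back to Pearson
    u <- (x - med) / (9 * mad)
    lo <- stats::quantile(u, max_p_outliers, names = FALSE)
    hi <- stats::quantile(u, 1 - max_p_outliers, names = FALSE)
    if (lo < -1) u[u < 0] <- u[u < 0] / abs(lo)
    if (hi > 1) u[u > 0] <- u[u > 0] / hi
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- (x - med) * w
    s <- sqrt(sum(xt^2))
    if (s == 0) return(NULL)
    xt / s
  }

  has_na <- anyNA(m)
  pearson_fallback <- FALSE
  if (!has_na) {
    rows <- vector("list", p)
    fallback_rows <- logical(p)
    for (i in seq_len(p)) {
      r <- prep(m[i, ])
      if (is.null(r)) {
        fallback_rows[i] <- TRUE
        x <- m[i, ] - mean(m[i, ])
        s <- sqrt(sum(x^2))
        r <- if (s == 0) rep(NA_real_, ncol(m)) else x / s
      }
      rows[[i]] <- r
    }
    pearson_fallback <- any(fallback_rows)
    cmat <- tcrossprod(do.call(rbind, rows))
    ## a fallback row mixes bicor and Pearson normalizations; recompute those
    ## pairs as plain Pearson for consistency
    if (pearson_fallback) {
      fb <- which(fallback_rows)
      pc <- suppressWarnings(stats::cor(t(m)))
      cmat[fb, ] <- pc[fb, ]
      cmat[, fb] <- pc[, fb]
    }
  } else {
    cmat <- matrix(NA_real_, p, p)
    for (i in seq_len(p)) {
      cmat[i, i] <- 1
      for (j in seq_len(p)[-seq_len(i)]) {
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        if (sum(ok) < 4) next
        xi <- prep(m[i, ok]); yj <- prep(m[j, ok])
        if (is.null(xi) || is.null(yj)) {
          pearson_fallback <- TRUE
          v <- suppressWarnings(stats::cor(m[i, ok], m[j, ok]))
        } else {
          v <- sum(xi * yj)
        }
        cmat[i, j] <- cmat[j, i] <- v
      }
    }
  }
  if (pearson_fallback) {
    warning("zero-MAD gene(s): Pearson fallback used for affected pairs")
  }
  cmat <- pmin(pmax(cmat, -1), 1)
  diag(cmat) <- 1
  dimnames(cmat) <- list(rownames(m), rownames(m))
  attr(cmat, "method") <- "bicor"
  attr(cmat, "max_p_outliers") <- max_p_outliers
  cmat
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`: positively correlated genes are strongly
#' connected, perfectly anti-correlated genes are unconnected. Missing
#' correlations contribute adjacency 0 (count recorded in attribute
#' `"n_missing"`).
#'
#' @param cor_mat Symmetric correlation matrix in \[-1, 1\].
#' @param power Soft-threshold exponent beta (integer >= 1).
#' @return Adjacency matrix in \[0, 1\], diagonal 1.
#' @export
signed_adjacency <- function(cor_mat, power) {
  if (power < 1) stop("`power` must be >= 1", call. = FALSE)
  n_missing <- sum(is.na(cor_mat[upper.tri(cor_mat)]))
  a <- ((1 + cor_mat) / 2)^power
  a[is.na(a)] <- 0
  diag(a) <- 1
  attr(a, "power") <- power
  attr(a, "n_missing") <- n_missing
  a
}

#' Scale-free topology fit of an adjacency's degree distribution
#'
#' Connectivity `k_i` (off-diagonal row sums) is binned into 10 equal-width
#' bins; `log10 p(k)` is regressed on `log10 mean(k)` per occupied bin. The
#' signed fit is `-sign(slope) * R^2`: high only when the degree distribution
#' decays, as a scale-free network's must.
#'
#' @param adj Adjacency matrix.
#' @return One-row tibble: `sft_r_sq` (signed fit), `slope`, `mean_k`,
#'   `median_k`, `max_k`.
#' @keywords internal
scale_free_fit <- function(adj) {
  k <- rowSums(adj) - diag(adj)
  if (all(k == 0)) stop("all connectivities are zero", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(k, bin, length)
  mean_k_bin <- tapply(k, bin, mean)
  ok <- !is.na(counts) & counts > 0 & !is.na(mean_k_bin) & mean_k_bin > 0
  if (sum(ok) < 3) {
    fit_r2 <- 0; slope <- 0
  } else {
    x <- log10(mean_k_bin[ok])
    y <- log10(counts[ok] / sum(counts[ok]))
    fit <- stats::lm(y ~ x)
    slope <- stats::coef(fit)[[2]]
    fit_r2 <- summary(fit)$r.squared
  }
  tibble::tibble(
    sft_r_sq = -sign(slope) * fit_r2,
    slope = slope,
    mean_k = mean(k), median_k = stats::median(k), max_k = max(k)
  )
}

#' Choose the soft-threshold power against scale-free topology
#'
#' Builds the signed adjacency at each candidate power and returns the lowest
#' power whose signed scale-free fit reaches `target_fit`; if none does, the
#' best-fitting power is returned and flagged.
#'
#' @param cor_mat Correlation matrix (e.g. from [bicor_matrix()]).
#' @param powers Candidate powers (default 1..20 then 22..30 by 2).
#' @param target_fit Required signed R^2 (default 0.9).
#' @return List with `power`, `fit_table` (tibble: one row per power),
#'   and `reached_target` (logical).
#' @export
pick_soft_threshold <- function(cor_mat, powers = c(1:20, seq(22, 30, 2)),
                                target_fit = 0.9) {
  if (length(powers) == 0 || any(powers < 1)) {
    stop("`powers` must be a nonempty vector of positive powers", call. = FALSE)
  }
  rows <- lapply(powers, function(b) {
    dplyr::bind_cols(tibble::tibble(power = b),
                     scale_free_fit(signed_adjacency(cor_mat, b)))
  })
  fit_table <- dplyr::bind_rows(rows)
  hit <- which(fit_table$sft_r_sq >= target_fit)
  if (length(hit) > 0) {
    power <- fit_table$power[hit[1]]
    reached <- TRUE
  } else {
    power <- fit_table$power[which.max(fit_table$sft_r_sq)]
    reached <- FALSE
    warning("no candidate power reached the target fit; returning best fit")
  }
  list(power = power, fit_table = fit_table, reached_target = reached)
}

#' Signed topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the off-diagonal row
#' sum: similarity is high when two genes are connected and share neighbors.
#' Diagonal is 1 by convention.
#'
#' @param adj Symmetric adjacency in \[0, 1\].
#' @return TOM matrix in \[0, 1\].
#' @export
signed_tom <- function(adj) {
  a <- as.matrix(adj)
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  diag(a) <- 0
  L <- a %*% a # sum over all u != i,j once diag is zeroed
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

## deepSplit 0..4 mapped to (static cut height as a fraction of the maximum
## merge height, relative merge-height gap needed to split a branch). Higher
## deepSplit cuts lower and splits on smaller gaps = more, smaller modules.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) stop("`deep_split` must be in 0..4", call. = FALSE)
  list(cut_frac = c(0.997, 0.995, 0.99, 0.985, 0.98)[deep_split + 1],
       gap_frac = c(0.50, 0.40, 0.30, 0.20, 0.10)[deep_split + 1])
}

## Recursive branch decomposition of an hclust tree: cut statically at
## cut_frac * max height, then split any cluster whose subtree shows an
## internal merge-height gap larger than gap_frac * (subtree height span),
## provided both sides could still form a module. Returns integer labels,
## 0 for unassigned (clusters below min_size).
dynamic_cut <- function(hc, cut_frac, gap_frac, min_size) {
  n <- length(hc$order)
  cut_height <- cut_frac * max(hc$height)
  base <- stats::cutree(hc, h = cut_height)

  ## members of each internal merge node
  members <- vector("list", nrow(hc$merge))
  node_members <- function(i) {
    if (i < 0) return(-i)
    members[[i]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    members[[i]] <- c(node_members(hc$merge[i, 1]), node_members(hc$merge[i, 2]))
  }

  split_cluster <- function(idx) {
    if (length(idx) < 2 * min_size) return(list(idx))
    ## merges fully inside this cluster
    inside <- vapply(seq_along(members),
                     function(i) all(members[[i]] %in% idx), logical(1))
    h <- hc$height[inside]
    if (length(h) < 2) return(list(idx))
    hs <- sort(h)
    gaps <- diff(hs)
    span <- max(hs) - min(hs)
    if (span <= 0) return(list(idx))
    gi <- which.max(gaps)
    if (gaps[gi] < gap_frac * span) return(list(idx))
    ## cut this subtree just above the gap
    thr <- hs[gi] + gaps[gi] / 2
    sub <- stats::cutree(hc, h = thr)[idx]
    parts <- split(idx, sub)
    if (length(parts) < 2) return(list(idx))
    unlist(lapply(parts, split_cluster), recursive = FALSE)
  }

  clusters <- unlist(lapply(split(seq_len(n), base), split_cluster),
                     recursive = FALSE)
  labels <- integer(n)
  nxt <- 1L
  for (cl in clusters) {
    if (length(cl) >= min_size) {
      labels[cl] <- nxt
      nxt <- nxt + 1L
    }
  }
  labels
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM`, a dynamic "tree"-style cut (recursive branch decomposition by
#' merge-height gaps, with sensitivity set by `deep_split` in 0..4), removal
#' of clusters below `min_module_size` to the unassigned label 0, and
#' iterative merging of modules whose eigengenes are closer than
#' `merge_cut_height` (dissimilarity `1 - cor`). Final labels are renumbered
#' by decreasing module size; label 0 collects unassigned genes.
#'
#' @param tom TOM matrix from [signed_tom()].
#' @param expr The expression matrix the network was built from (genes x
#'   samples; needed for eigengene merging).
#' @param deep_split Split sensitivity 0 (coarse) .. 4 (fine); default 2.
#' @param merge_cut_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param min_module_size Smallest retained module (default 20).
#' @param min_kme_to_stay After merging, genes whose correlation with their
#'   own module eigengene (kME) is below this value return to the unassigned
#'   label 0 (default 0.3; 0 disables pruning).
#' @return A `module_partition`: tibble with columns `gene`, `module`, plus
#'   attributes `dendrogram` (the hclust), `deep_split`, `merge_cut_height`,
#'   `min_module_size`.
#' @export
detect_modules <- function(tom, expr, deep_split = 2, merge_cut_height = 0.25,
                           min_module_size = 20, min_kme_to_stay = 0.3) {
  tom <- as.matrix(tom)
  if (nrow(tom) == 0) stop("empty TOM", call. = FALSE)
  if (nrow(tom) != ncol(tom)) stop("TOM must be square", call. = FALSE)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- sprintf("g%05d", seq_len(nrow(tom)))
  expr <- as.matrix(expr)[genes, , drop = FALSE]

  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  ps <- deep_split_params(deep_split)
  labels <- dynamic_cut(hc, ps$cut_frac, ps$gap_frac, min_module_size)

  ## iterative eigengene merging
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eig <- t(vapply(mods, function(m) {
      module_eigengene_vector(expr[labels == m, , drop = FALSE])
    }, numeric(ncol(expr))))
    d <- 1 - stats::cor(t(eig))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= merge_cut_height) break
    labels[labels == mods[ij[2]]] <- mods[ij[1]]
  }

  ## prune weak members: a gene stays in its module only if its kME to the
  ## module eigengene reaches min_kme_to_stay
  if (min_kme_to_stay > 0) {
    for (m in sort(unique(labels[labels > 0]))) {
      idx <- which(labels == m)
      e <- module_eigengene_vector(expr[idx, , drop = FALSE])
      kme <- suppressWarnings(as.numeric(stats::cor(t(expr[idx, , drop = FALSE]), e)))
      labels[idx[is.na(kme) | kme < min_kme_to_stay]] <- 0L
    }
  }

  ## renumber by decreasing size
  mods <- unique(labels[labels > 0])
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new_id <- stats::setNames(rank(-sizes, ties.method = "first"), mods)
  out <- ifelse(labels > 0, new_id[as.character(labels)], 0L)

  part <- tibble::tibble(gene = genes, module = as.integer(out))
  attr(part, "dendrogram") <- hc
  attr(part, "deep_split") <- deep_split
  attr(part, "merge_cut_height") <- merge_cut_height
  attr(part, "min_module_size") <- min_module_size
  class(part) <- c("module_partition", class(part))
  part
}
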
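## ---- NG86 counting machinery -------------------------------------------
## Synonymous/nonsynonymous site counts per sense codon and per-pair
## difference counts (averaged over minimal substitution pathways, skipping
## pathways through stop codons when possible) are precomputed once and
## cached for the session.
.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  gc_all <- Biostrings::GENETIC_CODE
  aa <- sense_codons()
  codons <- names(aa)
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, ""))
  nucs <- c("A", "C", "G", "T")

  ## synonymous sites: fraction of the 3 possible changes per position that
  ## are synonymous; changes to stop codons count as nonsynonymous, so
  ## S + N = 3 exactly for every codon
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(nucs, cm[i, pos])) {
        mut <- cm[i, ]
        mut[pos] <- alt
        mutc <- paste(mut, collapse = "")
        if (gc_all[[mutc]] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  names(syn_sites) <- codons

  ## per-pair difference decomposition over minimal pathways
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  sd_ <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      diff_pos <- which(cm[i, ] != cm[j, ])
      paths <- perms[[as.character(length(diff_pos))]]
      stats_per_path <- lapply(paths, function(ord) {
        cur <- cm[i, ]
        ns <- 0; ss <- 0; via_stop <- FALSE
        for (pos_idx in ord) {
          pos <- diff_pos[pos_idx]
          prev <- paste(cur, collapse = "")
          cur[pos] <- cm[j, pos]
          nxt <- paste(cur, collapse = "")
          if (gc_all[[nxt]] == "*") via_stop <- TRUE
          prev_aa <- gc_all[[prev]]
          nxt_aa <- gc_all[[nxt]]
          if (prev_aa == nxt_aa && prev_aa != "*") ss <- ss + 1 else ns <- ns + 1
        }
        c(ns = ns, ss = ss, via_stop = as.numeric(via_stop))
      })
      mat <- do.call(rbind, stats_per_path)
      ok <- mat[, "via_stop"] == 0
      use <- if (any(ok)) mat[ok, , drop = FALSE] else mat
      nd[i, j] <- nd[j, i] <- mean(use[, "ns"])
      sd_[i, j] <- sd_[j, i] <- mean(use[, "ss"])
    }
  }
  .ng86_cache$tables <- list(codons = codons, syn_sites = syn_sites,
                             nd = nd, sd = sd_)
  .ng86_cache$tables
}

## Split a DNA string into codon index vector over the 61 sense codons:
## NA for codons with gaps/ambiguity; error on internal stop codons.
codon_indices <- function(seqstring, name, codons) {
  s <- toupper(seqstring)
  if (nchar(s) %% 3 != 0) {
    stop("alignment length not divisible by 3", call. = FALSE)
  }
  cds <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  if (any(cds %in% c("TAA", "TAG", "TGA"))) {
    stop("internal stop codon in sequence ", name, call. = FALSE)
  }
  match(cds, codons)
}

#' Nei-Gojobori (NG86) dN/dS for a codon alignment
#'
#' For every sequence pair, synonymous and nonsynonymous sites are counted
#' per codon (averaged between the two sequences; changes to stop codons
#' count as nonsynonymous so sites sum to 3 per codon) and differences are
#' decomposed by averaging over minimal substitution pathways (pathways
#' through stop codons are excluded when any stop-free pathway exists).
#' Proportions are Jukes-Cantor corrected, `d = -3/4 log(1 - 4p/3)`; the
#' orthogroup dN and dS are unweighted means over pairs with defined
#' corrections, and `omega = dN/dS`. Codons containing gaps or ambiguity
#' codes are skipped pairwise.
#'
#' @param alignment Named character vector of equal-length in-frame DNA
#'   sequences (>= 2), or a `DNAStringSet`.
#' @return One-row tibble: `dn`, `ds`, `omega`, `n_pairs`, `n_pairs_used`,
#'   `flag` (`"ok"`, `"zero_ds"` when dS = 0 so omega is undefined, or
#'   `"undefined"` when no pair admits the correction).
#' @export
ng86_dnds <- function(alignment) {
  if (inherits(alignment, "DNAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (length(alignment) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1) {
    stop("sequences must be aligned (equal lengths)", call. = FALSE)
  }
  tb <- ng86_tables()
  nm <- names(alignment)
  if (is.null(nm)) nm <- paste0("seq", seq_along(alignment))
  idx <- lapply(seq_along(alignment), function(i) {
    codon_indices(alignment[[i]], nm[i], tb$codons)
  })

  nseq <- length(idx)
  dn_pairs <- c(); ds_pairs <- c()
  n_pairs <- 0L
  for (i in seq_len(nseq - 1)) {
    for (j in seq((i + 1), nseq)) {
      n_pairs <- n_pairs + 1L
      ok <- !is.na(idx[[i]]) & !is.na(idx[[j]])
      if (!any(ok)) next
      ci <- idx[[i]][ok]; cj <- idx[[j]][ok]
      S <- (sum(tb$syn_sites[ci]) + sum(tb$syn_sites[cj])) / 2
      N <- 3 * length(ci) - S
      pairs_mat <- cbind(ci, cj)
      nd <- sum(tb$nd[pairs_mat])
      sd_ <- sum(tb$sd[pairs_mat])
      pn <- if (N > 0) nd / N else 0
      ps <- if (S > 0) sd_ / S else 0
      # JC correction is undefined at p >= 3/4; each component is kept
      # for the pairs where its own correction exists
      if (pn < 0.75) dn_pairs <- c(dn_pairs, -3 / 4 * log(1 - 4 * pn / 3))
      if (ps < 0.75) ds_pairs <- c(ds_pairs, -3 / 4 * log(1 - 4 * ps / 3))
    }
  }
  dn <- if (length(dn_pairs) > 0) mean(dn_pairs) else NA_real_
  ds <- if (length(ds_pairs) > 0) mean(ds_pairs) else NA_real_
  n_used <- min(length(dn_pairs), length(ds_pairs))
  flag <- if (is.na(dn) || is.na(ds)) "undefined"
          else if (ds == 0) "zero_ds" else "ok"
  omega <- if (flag == "ok") dn / ds else NA_real_
  tibble::tibble(dn = dn, ds = ds, omega = omega, n_pairs = n_pairs,
                 n_pairs_used = n_used, flag = flag)
}

#' NG86 rates for a set of orthogroup alignments
#'
#' @param alignments Named list of alignments (see [ng86_dnds()]).
#' @return Tibble with one row per orthogroup: `orthogroup` plus the
#'   [ng86_dnds()] columns.
#' @export
ng86_rates <- function(alignments) {
  rows <- purrr::imap(alignments, function(aln, og) {
    dplyr::bind_cols(tibble::tibble(orthogroup = og), ng86_dnds(aln))
  })
  dplyr::bind_rows(rows)
}

#' Assemble the per-orthogroup rate table
#'
#' Joins rate estimates with per-network connectivity, mean expression,
#' module assignment and optional node-role and module-association columns.
#'
#' @param rates Tibble from [ng86_rates()] (or any table with `orthogroup`
#'   and `omega`; an externally estimated omega column can be supplied here
#'   so the downstream statistics run unchanged).
#' @param connectivity Tibble from [compute_connectivity()] (`gene`,
#'   `k_total`, `module`).
#' @param mean_expression Named numeric vector of per-orthogroup mean
#'   expression.
#' @param roles Optional tibble from [call_hubs_periphery()].
#' @param module_assoc Optional tibble mapping `module` to a syndrome
#'   association label (modules without a row get `"none"`).
#' @return Tibble: one row per orthogroup present in both `rates` and
#'   `connectivity`.
#' @export
rate_table <- function(rates, connectivity, mean_expression, roles = NULL,
                       module_assoc = NULL) {
  out <- dplyr::inner_join(rates,
                           dplyr::rename(connectivity, orthogroup = "gene"),
                           by = "orthogroup")
  out$mean_expr <- as.numeric(mean_expression[out$orthogroup])
  if (!is.null(roles)) {
    out <- dplyr::left_join(
      out, dplyr::select(roles, orthogroup = "gene", "is_hub", "is_periphery"),
      by = "orthogroup")
  }
  if (!is.null(module_assoc)) {
    out <- dplyr::left_join(out, module_assoc, by = "module")
    out$syndrome_assoc[is.na(out$syndrome_assoc)] <- "none"
  }
  out
}

#' Filter a rate table for the rate-model analyses
#'
#' Removes rows whose omega equals the sentinel used by maximum-likelihood
#' estimators for zero synonymous differences (999 by convention), rows with
#' missing/invalid omega, and rows where any of omega, connectivity or mean
#' expression is non-positive (all three enter the models on the log scale).
#'
#' @param table Rate table ([rate_table()]).
#' @param sentinel Sentinel omega value to drop (default 999).
#' @return Filtered tibble with removal counts in attribute `"removed"`.
#' @export
filter_rates <- function(table, sentinel = 999) {
  n0 <- nrow(table)
  bad_sentinel <- !is.na(table$omega) & table$omega == sentinel
  bad_invalid <- is.na(table$omega) | !is.finite(table$omega)
  if ("flag" %in% names(table)) bad_invalid <- bad_invalid | table$flag != "ok"
  nonpos <- table$omega <= 0
  if ("k_total" %in% names(table)) nonpos <- nonpos | table$k_total <= 0
  if ("mean_expr" %in% names(table)) nonpos <- nonpos | table$mean_expr <= 0
  nonpos[is.na(nonpos)] <- FALSE
  keep <- !(bad_sentinel | bad_invalid | nonpos)
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- c(sentinel = sum(bad_sentinel),
                            invalid = sum(bad_invalid & !bad_sentinel),
                            non_positive = sum(nonpos & !bad_invalid &
                                                 !bad_sentinel),
                            total = n0 - nrow(out))
  out
}

## Shared bootstrap-OLS core: y ~ X (full rank), case resampling.
boot_ols <- function(X, y, n_boot, seed) {
  if (kappa(X) > 1e10) stop("collinear predictors", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  n <- length(y)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  f_stat <- ((tss - rss) / (p - 1)) / (rss / (n - p))

  ## per-term eta squared from sequential sums of squares
  ss_seq <- numeric(p - 1)
  prev_rss <- tss
  for (j in 2:p) {
    f_j <- stats::lm.fit(X[, seq_len(j), drop = FALSE], y)
    rss_j <- sum(f_j$residuals^2)
    ss_seq[j - 1] <- prev_rss - rss_j
    prev_rss <- rss_j
  }
  eta_sq <- ss_seq / tss
  names(eta_sq) <- colnames(X)[-1]

  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bc <- matrix(NA_real_, n_boot, p)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bc[b, ] <- tryCatch(stats::lm.fit(X[idx, , drop = FALSE],
                                        y[idx])$coefficients,
                          error = function(e) rep(NA_real_, p))
    }
    ci <- t(apply(bc, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
    rownames(ci) <- colnames(X)
  }
  list(coefficients = coefs, ci = ci, f_statistic = f_stat,
       df = c(p - 1, n - p), eta_sq = eta_sq, n = n,
       r_squared = 1 - rss / tss)
}

rate_lm_result <- function(core, n_boot, model) {
  ci_lo <- if (is.null(core$ci)) rep(NA_real_, length(core$coefficients)) else core$ci[, 1]
  ci_hi <- if (is.null(core$ci)) rep(NA_real_, length(core$coefficients)) else core$ci[, 2]
  structure(list(
    coefficients = tibble::tibble(
      term = names(core$coefficients),
      estimate = unname(core$coefficients),
      ci_lo = unname(ci_lo), ci_hi = unname(ci_hi)
    ),
    f_statistic = core$f_statistic, df = core$df, eta_sq = core$eta_sq,
    r_squared = core$r_squared, n = core$n, n_boot = n_boot, model = model
  ), class = "rate_lm")
}

#' @export
print.rate_lm <- function(x, ...) {
  cat("Rate linear model:", x$model, "\n")
  cat(sprintf("  F(%d, %d) = %.3f, R^2 = %.3f, n = %d (%d bootstrap reps)\n",
              x$df[1], x$df[2], x$f_statistic, x$r_squared, x$n, x$n_boot))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @export
tidy.rate_lm <- function(x, ...) x$coefficients

#' @export
#' @importFrom generics glance
glance.rate_lm <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 r_squared = x$r_squared, n = x$n, n_boot = x$n_boot)
}

#' Linear model of evolutionary rate on connectivity and expression
#'
#' OLS of `log(omega)` on `log(k_total)`, `log(mean_expr)` and their
#' interaction, with overall F statistic, per-term eta squared, and
#' nonparametric case-resampling bootstrap confidence intervals for all
#' coefficients.
#'
#' @param table Filtered rate table ([filter_rates()]) with positive `omega`,
#'   `k_total`, `mean_expr`.
#' @param n_boot Bootstrap pseudoreplicates (default 10,000; 0 skips CIs).
#' @param seed Integer seed.
#' @return A `rate_lm` object (see [tidy()], [glance()]).
#' @export
rates_vs_connectivity_lm <- function(table, n_boot = 10000, seed = 1) {
  if (nrow(table) < 30) stop("need >= 30 rows after filtering", call. = FALSE)
  lk <- log(table$k_total); le <- log(table$mean_expr)
  X <- cbind(`(Intercept)` = 1, log_k = lk, log_expr = le,
             `log_k:log_expr` = lk * le)
  core <- boot_ols(X, log(table$omega), n_boot, seed)
  rate_lm_result(core, n_boot, "log(omega) ~ log(k) * log(expression)")
}

#' Permutation two-sample test of rates between a gene group and background
#'
#' Welch's t statistic on log-omega with a directional permutation p-value
#' (`(1 + #extreme) / (1 + n_perm)`), the log-scale mean difference
#' (group minus background), and Cohen's d with pooled SD.
#'
#' @param group,background Positive omega values (>= 5 each).
#' @param alternative `"less"` (group lower, e.g. hubs) or `"greater"`
#'   (group higher, e.g. periphery).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return Tibble: `t_statistic`, `df`, `p_value`, `mean_difference`,
#'   `cohens_d`, `n_group`, `n_background`.
#' @export
group_rate_permutation_test <- function(group, background,
                                        alternative = c("less", "greater"),
                                        n_perm = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  if (length(group) < 5 || length(background) < 5) {
    stop("both groups need >= 5 values", call. = FALSE)
  }
  if (any(c(group, background) <= 0)) {
    stop("omega values must be positive for the log transform", call. = FALSE)
  }
  g <- log(group); b <- log(background)
  welch <- function(x, y) {
    vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
    (mean(x) - mean(y)) / sqrt(vx + vy)
  }
  t_obs <- welch(g, b)
  tt <- stats::t.test(g, b) # Welch df for reporting
  pooled <- c(g, b)
  n_g <- length(g)
  set.seed(as.integer(seed))
  t_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), n_g)
    welch(pooled[idx], pooled[-idx])
  }, numeric(1))
  extreme <- if (alternative == "less") sum(t_perm <= t_obs) else sum(t_perm >= t_obs)
  p <- (1 + extreme) / (1 + n_perm)
  sp <- sqrt(((n_g - 1) * stats::var(g) + (length(b) - 1) * stats::var(b)) /
               (n_g + length(b) - 2))
  tibble::tibble(
    t_statistic = t_obs, df = unname(tt$parameter), p_value = p,
    mean_difference = mean(g) - mean(b),
    cohens_d = (mean(g) - mean(b)) / sp,
    n_group = n_g, n_background = length(b)
  )
}

#' Linear model of evolutionary rate on module syndrome association
#'
#' OLS of `log(omega)` on the module's syndrome-association factor, with
#' non-associated modules (`"none"`) as the reference level; overall F,
#' per-term eta squared and bootstrap CIs per level.
#'
#' @param table Filtered rate table with a `syndrome_assoc` column.
#' @param n_boot Bootstrap pseudoreplicates (default 10,000).
#' @param seed Integer seed.
#' @return A `rate_lm` object; terms are the non-reference syndrome levels.
#' @export
syndrome_rate_lm <- function(table, n_boot = 10000, seed = 1) {
  if (!"syndrome_assoc" %in% names(table)) {
    stop("`table` needs a syndrome_assoc column", call. = FALSE)
  }
  f <- stats::relevel(factor(table$syndrome_assoc), ref = "none")
  if (nlevels(f) < 2) stop("need >= 2 syndrome categories", call. = FALSE)
  X <- stats::model.matrix(~f)
  colnames(X) <- sub("^f", "", colnames(X))
  core <- boot_ols(X, log(table$omega), n_boot, seed)
  out <- rate_lm_result(core, n_boot, "log(omega) ~ syndrome_association")
  out$reference_level <- "none"
  out
}
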
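## Observed preservation statistics for one gene set S, given precomputed
## correlation matrices and expression in reference and test data.
## Density (computed in the test data): mean within-set correlation and the
## proportion of variance explained by the set's eigengene. Connectivity
## (ref vs test agreement): Spearman correlation of intramodular connectivity
## and Pearson correlation of kME to the set eigengene.
preservation_observed <- function(genes, ref_expr, test_expr,
                                  ref_cor, test_cor) {
  ct <- test_cor[genes, genes]
  cr <- ref_cor[genes, genes]
  off <- upper.tri(ct)
  mean_cor <- mean(ct[off])

  zt <- t(scale(t(test_expr[genes, , drop = FALSE])))
  svt <- svd(zt, nu = 0, nv = 1)
  pve <- svt$d[1]^2 / sum(svt$d^2)

  k_ref <- rowSums(cr) - 1
  k_test <- rowSums(ct) - 1
  cor_kim <- suppressWarnings(
    stats::cor(k_ref, k_test, method = "spearman"))

  e_ref <- module_eigengene_vector(ref_expr[genes, , drop = FALSE])
  e_test <- svt$v[, 1]
  kme_ref <- suppressWarnings(stats::cor(t(ref_expr[genes, , drop = FALSE]), e_ref))
  kme_test <- suppressWarnings(stats::cor(t(test_expr[genes, , drop = FALSE]), e_test))
  ## orient the test eigengene like the reference one so kME signs agree
  if (!is.na(stats::cor(kme_ref, kme_test)) && stats::cor(kme_ref, kme_test) < 0) {
    kme_test <- -kme_test
  }
  cor_kme <- suppressWarnings(stats::cor(kme_ref, kme_test))

  c(mean_cor = mean_cor, prop_var = pve,
    cor_kim = as.numeric(cor_kim), cor_kme = as.numeric(cor_kme))
}

#' Permutation module preservation between two datasets
#'
#' Quantifies how well reference-network modules retain their density and
#' connectivity pattern in a test dataset. For each module, four observed
#' statistics are computed (see Details); each is standardized against
#' `n_perm` random gene sets of the same size drawn from the common universe,
#' giving Z scores. `Zdensity` and `Zconnectivity` are the medians of their
#' component Zs, `Zsummary` their mean. `medianRank` is the median of the
#' per-statistic observed-value ranks across modules (1 = best preserved); a
#' "gold" module of `gold_size` randomly selected genes is carried through as
#' a calibration row.
#'
#' Density statistics (test data): mean within-module correlation;
#' proportion of variance explained by the module eigengene. Connectivity
#' statistics (reference/test agreement): Spearman correlation of
#' intramodular connectivity; Pearson correlation of kME.
#'
#' @param ref_expr,test_expr Expression matrices over a shared gene universe
#'   (genes x samples; the sample sets may differ).
#' @param ref_part Module partition of the reference network.
#' @param n_perm Number of random-gene-set permutations (default 200).
#' @param gold_size Size of the random gold module (default 1000, capped at
#'   half the universe).
#' @param seed Integer seed.
#' @return A `preservation_report` tibble: `module`, `size`, the four observed
#'   statistics, `z_density`, `z_connectivity`, `z_summary`, `median_rank`.
#' @export
preservation_stats <- function(ref_expr, test_expr, ref_part, n_perm = 200,
                               gold_size = 1000, seed) {
  ref_expr <- as.matrix(ref_expr)
  test_expr <- as.matrix(test_expr)
  universe <- intersect(rownames(ref_expr), rownames(test_expr))
  if (length(universe) < 10) stop("shared gene universe too small", call. = FALSE)
  ref_expr <- ref_expr[universe, , drop = FALSE]
  test_expr <- test_expr[universe, , drop = FALSE]
  set.seed(as.integer(seed))

  gold_size <- min(gold_size, floor(length(universe) / 2))
  mods <- sort(unique(ref_part$module[ref_part$module > 0]))
  sets <- lapply(mods, function(m) {
    intersect(ref_part$gene[ref_part$module == m], universe)
  })
  names(sets) <- paste0("ME", mods)
  sets$gold <- sample(universe, gold_size)
  sizes <- lengths(sets)
  if (any(sizes > length(universe))) {
    stop("module larger than the gene universe", call. = FALSE)
  }
  if (any(sizes < 3)) stop("modules must have >= 3 genes in the universe", call. = FALSE)

  ref_cor <- suppressWarnings(stats::cor(t(ref_expr)))
  test_cor <- suppressWarnings(stats::cor(t(test_expr)))

  obs <- t(vapply(sets, preservation_observed, numeric(4),
                  ref_expr = ref_expr, test_expr = test_expr,
                  ref_cor = ref_cor, test_cor = test_cor))

  ## permutation null per distinct module size
  z <- matrix(NA_real_, nrow(obs), 4, dimnames = dimnames(obs))
  for (sz in unique(sizes)) {
    perm <- matrix(NA_real_, n_perm, 4)
    for (b in seq_len(n_perm)) {
      perm[b, ] <- preservation_observed(sample(universe, sz),
                                         ref_expr, test_expr,
                                         ref_cor, test_cor)
    }
    mu <- colMeans(perm, na.rm = TRUE)
    sdv <- apply(perm, 2, stats::sd, na.rm = TRUE)
    rows <- which(sizes == sz)
    for (r in rows) {
      zz <- (obs[r, ] - mu) / sdv
      zz[sdv == 0] <- NA_real_
      z[r, ] <- zz
    }
  }
  if (anyNA(z)) warning("zero permutation SD: some Z statistics are missing")

  ## medians within class; a component whose permutation SD was zero (e.g.
  ## connectivity against an identical dataset) is missing and drops out of
  ## its class median, and an all-missing class drops out of Zsummary
  med_na <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  z_density <- apply(z[, c("mean_cor", "prop_var"), drop = FALSE], 1, med_na)
  z_connectivity <- apply(z[, c("cor_kim", "cor_kme"), drop = FALSE], 1, med_na)
  z_summary <- rowMeans(cbind(z_density, z_connectivity), na.rm = TRUE)
  z_summary[is.nan(z_summary)] <- NA_real_

  ranks <- apply(-obs, 2, rank, ties.method = "average")
  median_rank <- apply(ranks, 1, stats::median)

  out <- tibble::tibble(
    module = rownames(obs), size = as.integer(sizes),
    mean_cor = obs[, "mean_cor"], prop_var = obs[, "prop_var"],
    cor_kim = obs[, "cor_kim"], cor_kme = obs[, "cor_kme"],
    z_density = z_density, z_connectivity = z_connectivity,
    z_summary = z_summary, median_rank = median_rank
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "gold_size") <- gold_size
  class(out) <- c("preservation_report", class(out))
  out
}

#' Label module preservation from Zsummary
#'
#' `Zsummary > 10` is strong evidence of preservation, `< 2` no evidence,
#' anything between (including exactly 10 and exactly 2) is ambiguous.
#' `median_rank` is carried along for inspection but does not enter the label.
#'
#' @param report A `preservation_report` from [preservation_stats()].
#' @return The report with a `label` column added
#'   (`preserved` / `ambiguous` / `not_preserved`).
#' @export
classify_preservation <- function(report) {
  report$label <- dplyr::case_when(
    report$z_summary > 10 ~ "preserved",
    report$z_summary < 2 ~ "not_preserved",
    .default = "ambiguous"
  )
  report
}
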
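## First-principal-component summary profile of a module's expression
## (rows standardized; first right singular vector scaled to unit variance,
## oriented to correlate positively with the module mean profile).
module_eigengene_vector <- function(x) {
  z <- t(scale(t(x)))
  if (any(!is.finite(z))) {
    stop("module contains constant gene(s)", call. = FALSE)
  }
  v <- svd(z, nu = 0, nv = 1)$v[, 1]
  e <- v / stats::sd(v)
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  e
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix, scaled to unit variance across samples
#' and oriented so it correlates positively with the module's mean expression
#' profile. One eigengene is computed per module label present in the
#' partition (including the unassigned label 0, reported as `ME0`).
#'
#' @param expr Expression matrix (genes x samples).
#' @param partition A `module_partition` (or tibble with `gene`, `module`).
#' @return An `eigengene_set`: list with `values` (modules x samples matrix,
#'   rows `ME1`, `ME2`, ...) and `var_explained` (named numeric; share of the
#'   module's standardized variance carried by the first component).
#' @export
module_eigengenes <- function(expr, partition) {
  expr <- as.matrix(expr)
  mods <- sort(unique(partition$module))
  vals <- matrix(NA_real_, length(mods), ncol(expr),
                 dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- partition$gene[partition$module == mods[i]]
    if (length(genes) == 0) stop("empty module ME", mods[i], call. = FALSE)
    x <- expr[genes, , drop = FALSE]
    z <- t(scale(t(x)))
    if (any(!is.finite(z))) {
      stop("module ME", mods[i], " contains constant gene(s)", call. = FALSE)
    }
    sv <- svd(z, nu = 0, nv = 1)
    vals[i, ] <- {
      e <- sv$v[, 1] / stats::sd(sv$v[, 1])
      if (stats::cor(e, colMeans(z)) < 0) -e else e
    }
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = vals, var_explained = ve), class = "eigengene_set")
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat("Eigengene set:", nrow(x$values), "modules x", ncol(x$values),
      "samples\n")
  cat("  variance explained:",
      paste(sprintf("%s=%.2f", names(x$var_explained), x$var_explained),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.eigengene_set <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample", values_to = "value")
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's expression profile with every module
#' eigengene (not only the gene's own module). Constant genes get `NA`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param eigengenes An `eigengene_set` from [module_eigengenes()].
#' @return Genes x modules matrix of kME values in \[-1, 1\].
#' @export
compute_kme <- function(expr, eigengenes) {
  expr <- as.matrix(expr)
  E <- eigengenes$values
  if (ncol(expr) != ncol(E)) stop("sample sets do not match", call. = FALSE)
  suppressWarnings(stats::cor(t(expr), t(E)))
}

#' Whole-network and intramodular connectivity
#'
#' `k_total` is the sum of a gene's adjacency to all other genes, `k_within`
#' the part contributed by genes of its own module (computed uniformly for
#' every label, including the unassigned label 0), `k_out` the remainder.
#'
#' @param adj Adjacency matrix from [signed_adjacency()].
#' @param partition Module partition covering the adjacency's genes.
#' @return Tibble: `gene`, `module`, `k_total`, `k_within`, `k_out`.
#' @export
compute_connectivity <- function(adj, partition) {
  a <- as.matrix(adj)
  diag(a) <- 0
  genes <- rownames(a)
  mod <- partition$module[match(genes, partition$gene)]
  if (anyNA(mod)) stop("partition does not cover the adjacency", call. = FALSE)
  k_total <- unname(rowSums(a))
  k_within <- vapply(seq_along(genes), function(i) {
    sum(a[i, mod == mod[i]])
  }, numeric(1))
  tibble::tibble(gene = genes, module = mod, k_total = k_total,
                 k_within = k_within, k_out = k_total - k_within)
}

#' Call module hubs and network periphery
#'
#' Hubs are genes whose kME to their own (assigned, nonzero) module strictly
#' exceeds `hub_kme`. The periphery is the `floor(periphery_fraction * N)`
#' genes with the smallest total connectivity, over all genes including
#' unassigned ones, with ties broken by gene id.
#'
#' @param kme Genes x modules kME matrix from [compute_kme()].
#' @param connectivity Tibble from [compute_connectivity()].
#' @param hub_kme Strict hub threshold (default 0.9).
#' @param periphery_fraction Fraction of genes called peripheral (default
#'   0.10).
#' @return Tibble: `gene`, `module`, `kme_own`, `k_total`, `is_hub`,
#'   `is_periphery`; the realized periphery connectivity cutoff (largest
#'   peripheral `k_total`) and the thresholds used are attached as attributes.
#' @export
call_hubs_periphery <- function(kme, connectivity, hub_kme = 0.9,
                                periphery_fraction = 0.10) {
  genes <- connectivity$gene
  kme_own <- vapply(seq_along(genes), function(i) {
    col <- paste0("ME", connectivity$module[i])
    if (col %in% colnames(kme)) kme[genes[i], col] else NA_real_
  }, numeric(1))
  is_hub <- !is.na(kme_own) & kme_own > hub_kme & connectivity$module != 0

  n_periph <- floor(periphery_fraction * length(genes))
  ord <- order(connectivity$k_total, genes)
  is_periphery <- logical(length(genes))
  is_periphery[ord[seq_len(n_periph)]] <- TRUE
  cutoff <- if (n_periph > 0) max(connectivity$k_total[is_periphery]) else NA_real_

  out <- tibble::tibble(
    gene = genes, module = connectivity$module, kme_own = kme_own,
    k_total = connectivity$k_total, is_hub = is_hub,
    is_periphery = is_periphery
  )
  attr(out, "hub_kme") <- hub_kme
  attr(out, "periphery_fraction") <- periphery_fraction
  attr(out, "periphery_cutoff") <- cutoff
  out
}

## Fisher's exact machinery for one 2x2 overlap table.
overlap_fisher_cell <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or_sample <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p = ft$p.value, or_sample = or_sample,
       or_cmle = unname(ft$estimate))
}

#' Cross-network module overlap with Fisher's exact tests
#'
#' For every pair of modules (one from each partition over the same gene
#' universe), counts the 2x2 table (in both / A only / B only / neither) and
#' reports the two-sided hypergeometric p-value, the sample odds ratio
#' (`ad/bc`, Haldane 0.5 correction when any cell is zero), the conditional
#' maximum-likelihood odds ratio, and `-log10(p)` for plotting.
#'
#' @param part_a,part_b Module partitions over identical gene universes.
#' @return Tibble: `module_a`, `module_b`, `n_both`, `n_a_only`, `n_b_only`,
#'   `n_neither`, `p_value`, `odds_ratio_sample`, `odds_ratio_cmle`,
#'   `neg_log10_p`.
#' @export
module_overlap_fisher <- function(part_a, part_b) {
  if (!setequal(part_a$gene, part_b$gene)) {
    stop("partitions must share an identical gene universe", call. = FALSE)
  }
  b_mod <- part_b$module[match(part_a$gene, part_b$gene)]
  a_mod <- part_a$module
  n <- length(a_mod)
  grid <- tidyr::expand_grid(module_a = sort(unique(a_mod)),
                             module_b = sort(unique(b_mod)))
  rows <- purrr::pmap(grid, function(module_a, module_b) {
    in_a <- a_mod == module_a
    in_b <- b_mod == module_b
    a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
    c <- sum(!in_a & in_b); d <- n - a - b - c
    ft <- overlap_fisher_cell(a, b, c, d)
    tibble::tibble(module_a, module_b, n_both = a, n_a_only = b,
                   n_b_only = c, n_neither = d, p_value = ft$p,
                   odds_ratio_sample = ft$or_sample,
                   odds_ratio_cmle = ft$or_cmle,
                   neg_log10_p = -log10(ft$p))
  })
  dplyr::bind_rows(rows)
}

#' Fisher's exact overlap test for two arbitrary gene sets
#'
#' The same 2x2 construction as [module_overlap_fisher()] for user-supplied
#' sets (e.g. hubs of two networks) against a common universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return One-row tibble as in [module_overlap_fisher()].
#' @export
gene_set_fisher <- function(set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be contained in the universe", call. = FALSE)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c <- sum(!in_a & in_b); d <- length(universe) - a - b - c
  ft <- overlap_fisher_cell(a, b, c, d)
  tibble::tibble(n_both = a, n_a_only = b, n_b_only = c, n_neither = d,
                 p_value = ft$p, odds_ratio_sample = ft$or_sample,
                 odds_ratio_cmle = ft$or_cmle, neg_log10_p = -log10(ft$p))
}
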
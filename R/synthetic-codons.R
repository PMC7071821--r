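#' Specification for codon-alignment simulation
#'
#' Parameters of the codon substitution process used by
#' [simulate_codon_alignments()]: a Muse-Gaut-style rate matrix over the 61
#' sense codons with uniform codon frequencies, where single-nucleotide codon
#' changes occur at relative rate `kappa` for transitions (1 for
#' transversions), multiplied by `omega` when the change is nonsynonymous.
#' Stop codons are excluded from the state space, so simulated sequences can
#' never contain an internal stop.
#'
#' @param omega Target dN/dS (>= 0); 0 forbids amino-acid change, 1 is neutral.
#' @param kappa Transition/transversion rate ratio (default 1: the downstream
#'   counting estimator weighs all changes equally, so the neutral default
#'   keeps generator and estimator on the same footing).
#' @param n_codons Alignment length in codons (>= 10).
#' @param tree_scale Multiplier applied to branch lengths; with the unit-depth
#'   trees from [simulate_phylogeny()] this is the expected number of
#'   substitutions per codon from root to tip under neutrality. The default
#'   0.3 gives the moderate within-genus divergence at which counting
#'   estimators are well behaved.
#' @return A `codon_sim_spec` list.
#' @export
codon_sim_spec <- function(omega, kappa = 1, n_codons = 300, tree_scale = 0.3) {
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0) {
    stop("`omega` must be a single number >= 0", call. = FALSE)
  }
  if (n_codons < 10) stop("`n_codons` must be >= 10", call. = FALSE)
  if (kappa <= 0 || tree_scale <= 0) {
    stop("`kappa` and `tree_scale` must be positive", call. = FALSE)
  }
  structure(list(omega = omega, kappa = kappa, n_codons = as.integer(n_codons),
                 tree_scale = tree_scale),
            class = "codon_sim_spec")
}

## The 61 sense codons of the standard genetic code and their amino acids.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

## Rate matrix over sense codons: single-nucleotide changes only, rate
## kappa^(transition) * omega^(nonsynonymous); uniform codon frequencies make
## the matrix symmetric. Scaled so the mean substitution rate per codon is 1.
codon_rate_matrix <- function(omega, kappa) {
  aa <- sense_codons()
  codons <- names(aa)
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, ""))
  purines <- c("A", "G")
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(cm[i, ] != cm[j, ])
      if (length(diff) != 1) next
      a <- cm[i, diff]; b <- cm[j, diff]
      is_ts <- (a %in% purines) == (b %in% purines)
      r <- if (is_ts) kappa else 1
      if (aa[i] != aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  mean_rate <- -mean(diag(Q))
  if (mean_rate > 0) Q <- Q / mean_rate
  Q
}

#' Simulate codon alignments along a tree at a specified dN/dS
#'
#' Each orthogroup alignment is evolved independently: a uniform-random root
#' sequence over the 61 sense codons, then per-branch codon substitution with
#' transition probabilities `expm(Q * t)` from the rate matrix described in
#' [codon_sim_spec()]. Alignments are in frame, gap-free, and contain no stop
#' codons by construction.
#'
#' @param tree Species tree ([ape::phylo], branch lengths in expected
#'   substitutions per codon after `tree_scale`).
#' @param spec A [codon_sim_spec()].
#' @param n_orthogroups Number of independent alignments (>= 1).
#' @param seed Integer seed.
#' @return Named list of alignments (`og00001`, ...); each alignment is a
#'   named character vector of equal-length in-frame DNA sequences, one per
#'   species.
#' @export
simulate_codon_alignments <- function(tree, spec, n_orthogroups, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (!inherits(spec, "codon_sim_spec")) {
    stop("`spec` must be a codon_sim_spec", call. = FALSE)
  }
  if (n_orthogroups < 1) stop("`n_orthogroups` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  Q <- codon_rate_matrix(spec$omega, spec$kappa)
  codons <- rownames(Q)
  n_state <- length(codons)
  ## symmetric Q (uniform frequencies): eigendecomposition gives exact expm
  eg <- eigen(Q, symmetric = TRUE)
  p_matrix <- function(t) {
    P <- eg$vectors %*% (exp(eg$values * t) * t(eg$vectors))
    P[P < 0] <- 0
    P / rowSums(P)
  }
  lens <- unique(tree$edge.length) * spec$tree_scale
  P_by_len <- lapply(lens, p_matrix)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  preorder <- rev(ape::postorder(tree))

  out <- vector("list", n_orthogroups)
  for (og in seq_len(n_orthogroups)) {
    seqs <- matrix(0L, ntip + tree$Nnode, spec$n_codons)
    seqs[root, ] <- sample.int(n_state, spec$n_codons, replace = TRUE)
    for (i in preorder) {
      p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
      P <- P_by_len[[match(tree$edge.length[i] * spec$tree_scale, lens)]]
      parent_codons <- seqs[p, ]
      u <- stats::runif(spec$n_codons)
      cum <- t(apply(P[parent_codons, , drop = FALSE], 1, cumsum))
      cum[, n_state] <- 1
      seqs[ch, ] <- max.col(cum >= u, ties.method = "first")
    }
    aln <- vapply(seq_len(ntip), function(i) {
      paste(codons[seqs[i, ]], collapse = "")
    }, character(1))
    names(aln) <- tree$tip.label
    out[[og]] <- aln
  }
  names(out) <- sprintf("og%05d", seq_len(n_orthogroups))
  out
}
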
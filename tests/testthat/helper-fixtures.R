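# Shared fixtures and independent oracles used across test files.

# Small simulated two-stage dataset with two planted modules.
quick_sim <- function(seed = 1, n_modules = 2, module_size = 30,
                      target_cor = 0.8, n_background = 60,
                      trait_effects = NULL) {
  tree <- simulate_phylogeny(12, seed = seed)
  traits <- simulate_traits(tree, seed = seed)
  plan <- module_plan(n_modules, module_size, target_cor, n_background,
                      trait_effects = trait_effects)
  sim <- simulate_expression(tree, traits, plan, seed = seed + 1000)
  sim
}

# Brute-force signed TOM by triple loop (independent of the matrix-product
# implementation).
tom_brute_force <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
        next
      }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# Two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins (hypergeometric point probabilities).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# Closed-form OLS via normal equations.
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
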
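# Short sampler settings for unit tests; the calibration checks exercise
# the full default settings separately.
test_spec <- function(...) {
  mcmc_spec(iterations = 4000, burnin = 1000, thin = 3, ...)
}

test_that("mean path length smoothing makes any rooted tree ultrametric", {
  # hand case: caterpillar ((A:0.6,B:0.8):0.4,C:1.4) has tip depths
  # 1.0 / 1.2 / 1.4; the cherry node's mean tip distance is 0.7 and the
  # root's is 1.2, so after normalization the cherry hangs at 0.5/1.2
  tr <- ape::read.tree(text = "((A:0.6,B:0.8):0.4,C:1.4);")
  ut <- ultrametricize(tr)
  d <- node_depths(ut)
  expect_equal(unname(d), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(sort(ut$edge.length),
               sort(c(0.5 / 1.2, 0.7 / 1.2, 0.7 / 1.2, 1.2 / 1.2)),
               tolerance = 1e-12)

  # already-ultrametric trees are a fixed point up to global scaling
  tr2 <- simulate_phylogeny(10, seed = 2)
  ut2 <- ultrametricize(tr2)
  expect_lt(max(abs(ut2$edge.length - tr2$edge.length) /
                  pmax(tr2$edge.length, 1e-12)), 1e-9)

  # any output is ultrametric
  set.seed(3)
  tr3 <- ape::rtree(15)
  d3 <- node_depths(ultrametricize(tr3))
  expect_lt(max(d3) - min(d3), 1e-9)

  expect_error(ultrametricize(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("tree sampling is deterministic with a with-replacement fallback", {
  trees <- lapply(1:100, function(i) simulate_phylogeny(6, seed = i))
  s1 <- sample_trees(trees, n = 50, seed = 7)
  s2 <- sample_trees(trees, n = 50, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1, 50)
  expect_equal(formals(sample_trees)$n, 50)

  expect_warning(s3 <- sample_trees(trees[1:30], n = 50, seed = 7),
                 "replacement")
  expect_length(s3, 50)
  expect_error(sample_trees(list(), seed = 1), "nonempty")
})

test_that("convergence diagnostics reproduce hand-computable cases", {
  # {1,2,3} twice: W = 1, B = 0, PSRF = sqrt(2/3)
  ch <- matrix(1:3, 3, 1, dimnames = list(NULL, "b"))
  dg <- convergence_diagnostics(list(ch, ch))
  expect_equal(dg$psrf, sqrt(2 / 3), tolerance = 1e-12)

  # two i.i.d. standard-normal chains: PSRF near 1, ESS near the sample count
  set.seed(8)
  c1 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "b"))
  c2 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "b"))
  dg2 <- convergence_diagnostics(list(c1, c2))
  expect_lt(dg2$psrf, 1.01)
  expect_gt(dg2$ess, 4000)
  expect_lt(dg2$ess, 12000)

  # a strongly autocorrelated chain has much smaller ESS, and the estimate
  # agrees loosely with an established implementation
  set.seed(9)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  cha <- matrix(ar, ncol = 1, dimnames = list(NULL, "b"))
  dg3 <- convergence_diagnostics(list(cha))
  expect_lt(dg3$ess, 1000)
  if (requireNamespace("coda", quietly = TRUE)) {
    ref <- unname(coda::effectiveSize(ar))
    expect_lt(abs(dg3$ess - ref) / ref, 0.5)
  }

  # single chain: PSRF undefined, ESS still returned
  dg4 <- convergence_diagnostics(list(c1))
  expect_true(is.na(dg4$psrf))
  expect_gt(dg4$ess, 0)

  expect_error(convergence_diagnostics(list(c1, c1[1:10, , drop = FALSE])),
               "equal lengths")
})

test_that("the probit sampler is deterministic and validates its inputs", {
  tr <- simulate_phylogeny(12, seed = 1)
  y <- stats::setNames(rep(c(0L, 1L), 6), tr$tip.label)
  x <- stats::setNames(rnorm(12), tr$tip.label)
  f1 <- fit_phylo_probit(y, x, tr, test_spec(), seed = 4)
  f2 <- fit_phylo_probit(y, x, tr, test_spec(), seed = 4)
  expect_identical(f1$chains, f2$chains)

  expect_error(fit_phylo_probit(y * 0L, x, tr, test_spec(), seed = 1),
               "constant")
  expect_error(
    fit_phylo_probit(y[1:6], x, simulate_phylogeny(6, seed = 1),
                     test_spec(), seed = 1), "6 species|identical")

  # prior defaults: inverse-gamma shape and scale 0.001, residual fixed at 1
  sp <- mcmc_spec()
  expect_equal(sp$prior_shape, 0.001)
  expect_equal(sp$prior_scale, 0.001)
  expect_equal(sp$residual_variance, 1)
  expect_equal(sp$chains, 2L)
  expect_equal(sp$iterations, 250000L)
  expect_equal(sp$burnin, 50000L)
})

test_that("under a null slope the 95% credible interval is calibrated", {
  tr <- simulate_phylogeny(12, seed = 7)
  n <- 60
  nsig <- 0
  for (i in seq_len(n)) {
    set.seed(i)
    repeat {
      y <- stats::setNames(stats::rbinom(12, 1, 0.5), tr$tip.label)
      if (stats::var(y) > 0) break
    }
    x <- stats::setNames(rnorm(12), tr$tip.label)
    fit <- fit_phylo_probit(y, x, tr, test_spec(), seed = i)
    s <- do.call(rbind, fit$chains)[, "slope"]
    ci <- stats::quantile(s, c(0.025, 0.975))
    if (ci[1] > 0 || ci[2] < 0) nsig <- nsig + 1
  }
  expect_lte(nsig / n, 0.10 + 0.05) # nominal bound plus Monte-Carlo slack
})

test_that("a cleanly separated trait is detected with high power", {
  tr <- simulate_phylogeny(12, seed = 3)
  hits <- 0; n <- 25
  for (i in seq_len(n)) {
    set.seed(500 + i)
    x <- stats::setNames(rnorm(12), tr$tip.label)
    y <- stats::setNames(as.integer(x > 0), tr$tip.label)
    if (stats::var(y) == 0) { n <- n - 1; next }
    fit <- fit_phylo_probit(y, x, tr, test_spec(), seed = i)
    s <- do.call(rbind, fit$chains)[, "slope"]
    if (stats::quantile(s, 0.025) > 0) hits <- hits + 1
  }
  expect_gte(hits / n, 0.8)
})

test_that("association labels cover every rule combination", {
  expect_equal(classify_trait_association(FALSE, 0), "none")
  expect_equal(classify_trait_association(FALSE, 3), "none")
  expect_equal(classify_trait_association(TRUE, 0), "weak")
  expect_equal(classify_trait_association(TRUE, 1), "weak")
  expect_equal(classify_trait_association(TRUE, 2), "strong")
  expect_equal(classify_trait_association(TRUE, 5), "strong")
})

test_that("a planted eigengene shift is recovered over multiple trees", {
  tr <- simulate_phylogeny(12, seed = 5)
  traits <- simulate_traits(tr, seed = 5)
  expect_gte(sum(traits$syndrome == "hummingbird"), 2)
  eff <- tibble::tibble(module = 1L, trait = "syndrome",
                        level = "hummingbird", effect = 2)
  plan <- module_plan(2, 30, 0.8, 60, trait_effects = eff)
  sim <- simulate_expression(tr, traits, plan, seed = 11)
  pp <- preprocess_stages(sim$counts$Bud, sim$counts$D)
  part <- tibble::tibble(gene = sim$truth$orthogroup,
                         module = sim$truth$module)
  part <- part[part$module > 0, ]
  eig <- module_eigengenes(pp$bud, part)
  meta <- sim$meta[sim$meta$stage == "Bud", ]
  trees <- lapply(1:10, function(i) simulate_phylogeny(12, seed = 200 + i))
  res <- run_multitree_association(eig, meta, sim$traits, trees,
                                   mcmc_spec(iterations = 6000,
                                             burnin = 1500, thin = 5),
                                   seed = 3, trait_cols = "syndrome")
  hit <- res[res$module == "ME1" & res$level == "hummingbird", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "positive")
  expect_gt(hit$ci_lo, 0)

  # determinism given seeds
  res2 <- run_multitree_association(eig, meta, sim$traits, trees,
                                    mcmc_spec(iterations = 6000,
                                              burnin = 1500, thin = 5),
                                    seed = 3, trait_cols = "syndrome")
  expect_identical(res, res2)
})

test_that("eigengene species flags require every replicate beyond the cut", {
  samples <- c("spA_1", "spA_2", "spA_3", "spB_1", "spB_2", "spB_3",
               "spC_1", "spC_2", "spC_3")
  E <- matrix(c(1.2, 1.1, 1.4,    # spA: all above +1 -> high
                0.9, 1.3, 1.2,    # spB: one replicate at 0.9 -> none
                -1.2, -1.5, -1.1),# spC: all below -1 -> low
              nrow = 1, dimnames = list("ME1", samples))
  eig <- structure(list(values = E, var_explained = c(ME1 = 1)),
                   class = "eigengene_set")
  meta <- tibble::tibble(sample = samples,
                         species = rep(c("spA", "spB", "spC"), each = 3))
  flags <- floranet:::eigengene_species_flags(eig, meta, threshold = 1)
  expect_equal(flags$flag[flags$species == "spA"], "high")
  expect_equal(flags$flag[flags$species == "spB"], "none")
  expect_equal(flags$flag[flags$species == "spC"], "low")
})
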
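#' Sampler settings for the phylogenetic mixed model
#'
#' Defaults follow the convention for categorical phylogenetic mixed models:
#' a non-informative inverse-gamma prior on the phylogenetic variance with
#' shape and scale 0.001, residual variance fixed at 1 (the standard
#' identification constraint for threshold models), two chains of 250,000
#' iterations with a 50,000-iteration burn-in. Fixed effects get a proper
#' weakly-informative N(0, `fixed_effect_variance`) prior: the default SD of
#' 2.5 on the probit scale is the standard weakly-informative choice for
#' binary-response coefficients, keeps the posterior proper under complete
#' separation, and gives near-nominal interval calibration at small n.
#'
#' @param prior_shape,prior_scale Inverse-gamma prior on the phylogenetic
#'   variance (defaults 0.001, 0.001).
#' @param fixed_effect_variance Prior variance of intercept and slope
#'   (default 6.25, i.e. SD 2.5 on the probit scale).
#' @param chains Number of chains (>= 2 so PSRF is defined; default 2).
#' @param iterations Total MCMC iterations per chain (default 250,000).
#' @param burnin Discarded initial iterations (default 50,000).
#' @param thin Keep every `thin`-th post-burn-in sample (default 100).
#' @return An `mcmc_spec` list.
#' @export
mcmc_spec <- function(prior_shape = 0.001, prior_scale = 0.001,
                      fixed_effect_variance = 6.25, chains = 2,
                      iterations = 250000, burnin = 50000, thin = 100) {
  if (burnin >= iterations) stop("`burnin` must be < `iterations`", call. = FALSE)
  if (chains < 1) stop("`chains` must be >= 1", call. = FALSE)
  structure(list(prior_shape = prior_shape, prior_scale = prior_scale,
                 fixed_effect_variance = fixed_effect_variance,
                 residual_variance = 1,
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "mcmc_spec")
}

#' Fit the phylogenetic probit mixed model by Gibbs sampling
#'
#' Latent-threshold model for a binary species trait: the liability is
#' `b0 + b1 * predictor + u + e`, with `u ~ N(0, sigma2 * C)` where `C` is the
#' tree's shared-path-length correlation matrix, and `e` a fixed unit-variance
#' residual. Sampled by Gibbs with truncated-normal data augmentation for the
#' liabilities, a joint conjugate normal update for `(b0, b1, u)`, and a
#' conjugate inverse-gamma update for the phylogenetic variance.
#'
#' @param trait_binary Named 0/1 vector, one value per species.
#' @param predictor Named numeric vector (e.g. species-mean module
#'   eigengene), same species.
#' @param tree Ultrametric [ape::phylo] covering the same species.
#' @param spec An [mcmc_spec()].
#' @param seed Integer seed.
#' @return A `phylo_probit_fit`: list with `chains` (list of matrices with
#'   columns `intercept`, `slope`, `sigma2_phylo`; thinned post-burn-in
#'   samples) and `spec`.
#' @export
fit_phylo_probit <- function(trait_binary, predictor, tree,
                             spec = mcmc_spec(), seed) {
  species <- tree$tip.label
  if (length(species) < 6) stop("need at least 6 species", call. = FALSE)
  if (!setequal(names(trait_binary), species) ||
      !setequal(names(predictor), species)) {
    stop("species of trait, predictor and tree must be identical", call. = FALSE)
  }
  y <- as.integer(trait_binary[species])
  if (length(unique(y)) < 2) {
    stop("trait is constant across species (non-identifiable)", call. = FALSE)
  }
  x <- as.numeric(predictor[species])
  X <- cbind(1, x)
  C <- ape::vcv(tree, corr = TRUE)[species, species]
  Cinv <- solve(C + diag(1e-8, length(species)))

  set.seed(as.integer(seed))
  chains <- lapply(seq_len(spec$chains), function(ch) {
    s <- probit_gibbs_cpp(y, X, Cinv, spec$prior_shape, spec$prior_scale,
                          spec$fixed_effect_variance, spec$iterations,
                          spec$burnin, spec$thin)
    colnames(s) <- c("intercept", "slope", "sigma2_phylo")
    s
  })
  structure(list(chains = chains, spec = spec), class = "phylo_probit_fit")
}

#' @export
print.phylo_probit_fit <- function(x, ...) {
  pooled <- do.call(rbind, x$chains)
  cat("Phylogenetic probit fit:", length(x$chains), "chain(s),",
      nrow(pooled), "pooled samples\n")
  q <- apply(pooled[, 1:2, drop = FALSE], 2, stats::quantile,
             c(0.025, 0.5, 0.975))
  print(round(t(q), 3))
  invisible(x)
}

#' Gelman-Rubin and effective-sample-size diagnostics
#'
#' PSRF per parameter from `m >= 2` chains of length `n`:
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of chain means (times `n`).
#' ESS per parameter: per chain, `n / tau` with `tau` from Geyer's
#' initial-positive-sequence truncation of the autocorrelation sum, summed
#' over chains. With a single chain PSRF is `NA` and ESS is still returned.
#'
#' @param chains List of matrices with identical dimensions and column names
#'   (samples x parameters), or a single matrix.
#' @return Tibble: `parameter`, `psrf`, `ess`.
#' @export
convergence_diagnostics <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  if (length(unique(vapply(chains, nrow, integer(1)))) != 1) {
    stop("chains must have equal lengths", call. = FALSE)
  }
  params <- colnames(chains[[1]])
  if (is.null(params)) params <- paste0("param", seq_len(ncol(chains[[1]])))
  m <- length(chains)
  n <- nrow(chains[[1]])

  psrf_one <- function(j) {
    if (m < 2) return(NA_real_)
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B <- n * stats::var(colMeans(draws))
    if (W == 0) return(if (B == 0) NA_real_ else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }

  ess_chain <- function(x) {
    nn <- length(x)
    if (stats::var(x) == 0) return(0)
    rho <- as.numeric(stats::acf(x, lag.max = min(nn - 1, 2000),
                                 plot = FALSE)$acf)
    ## Geyer initial positive sequence: sum consecutive pairs while positive
    tau <- 0
    k <- 1
    while (k + 1 <= length(rho)) {
      g <- rho[k] + rho[k + 1]
      if (g <= 0) break
      tau <- tau + 2 * g
      k <- k + 2
    }
    tau <- tau - 1 # Gamma_0 contains rho_0 = 1 twice the needed amount
    if (k + 1 > length(rho) && k <= length(rho) && rho[k] > 0) {
      tau <- tau + 2 * rho[k]
    }
    nn / max(tau, .Machine$double.eps)
  }
  ess_one <- function(j) sum(vapply(chains, function(ch) ess_chain(ch[, j]),
                                    numeric(1)))

  tibble::tibble(
    parameter = params,
    psrf = vapply(seq_along(params), psrf_one, numeric(1)),
    ess = vapply(seq_along(params), ess_one, numeric(1))
  )
}

#' Classify the evidence for a module-trait association
#'
#' Pure decision rule: no significant pooled fixed effect gives `"none"`; a
#' significant effect coupled with extreme eigengene expression (all
#' replicates above +1 or below -1) in two or more species that share the
#' significant trait level gives `"strong"`; a significant effect with at most
#' one such species gives `"weak"`.
#'
#' @param significant Logical: does the pooled 95% credible interval exclude
#'   zero?
#' @param n_flagged_shared Number of species that are both eigengene-flagged
#'   and carry the significant trait level.
#' @return `"none"`, `"weak"` or `"strong"`.
#' @export
classify_trait_association <- function(significant, n_flagged_shared) {
  if (!significant) return("none")
  if (n_flagged_shared >= 2) "strong" else "weak"
}

## Species flagged per module: all replicates above +thr ("high") or below
## -thr ("low"). Returns tibble(module, species, flag).
eigengene_species_flags <- function(eigengenes, meta, threshold = 1) {
  E <- eigengenes$values
  sp <- meta$species[match(colnames(E), meta$sample)]
  rows <- list()
  for (m in rownames(E)) {
    for (s in unique(sp)) {
      v <- E[m, sp == s]
      flag <- if (all(v > threshold)) "high"
              else if (all(v < -threshold)) "low" else "none"
      rows[[length(rows) + 1]] <- tibble::tibble(module = m, species = s,
                                                 flag = flag)
    }
  }
  dplyr::bind_rows(rows)
}

#' Module-trait association over many trees
#'
#' For every module eigengene and every level of every categorical trait
#' (multi-level traits decomposed one-vs-rest; two-level traits modelled once
#' at their second sorted level), fits the phylogenetic probit model
#' ([fit_phylo_probit()]) on each supplied tree with the species-mean
#' eigengene as predictor, pools the post-burn-in samples across trees and
#' chains, and classifies the association with the strong/weak evidence rule
#' ([classify_trait_association()]): a species counts toward "strong" when
#' all of its replicates have eigengene expression beyond
#' `flag_threshold` in absolute value and it carries the significant trait
#' level.
#'
#' @param eigengenes An `eigengene_set` ([module_eigengenes()]).
#' @param meta Sample metadata tibble (`sample`, `species`, ...).
#' @param traits Trait table ([simulate_traits()] layout).
#' @param trees List of ultrametric trees covering all species.
#' @param spec An [mcmc_spec()].
#' @param seed Integer seed; per-fit seeds are derived deterministically.
#' @param flag_threshold Eigengene threshold for species flags (default 1.0).
#' @param trait_cols Trait columns of `traits` to test.
#' @return Tibble: `module`, `trait`, `level`, `post_mean`, `ci_lo`, `ci_hi`,
#'   `significant`, `psrf_max`, `ess_min`, `n_flagged_shared`, `direction`,
#'   `label`.
#' @export
run_multitree_association <- function(eigengenes, meta, traits, trees,
                                      spec = mcmc_spec(), seed,
                                      flag_threshold = 1,
                                      trait_cols = c("syndrome", "color",
                                                     "shape", "spur")) {
  E <- eigengenes$values
  sp_of_sample <- meta$species[match(colnames(E), meta$sample)]
  if (anyNA(sp_of_sample)) {
    stop("eigengene samples missing from metadata", call. = FALSE)
  }
  species <- sort(unique(traits$species))
  for (tr in trees) {
    if (!setequal(tr$tip.label, species)) {
      stop("every tree must cover exactly the trait table's species", call. = FALSE)
    }
  }
  flags <- eigengene_species_flags(eigengenes, meta, flag_threshold)

  out <- list()
  fit_counter <- 0L
  for (mod in rownames(E)) {
    pred <- tapply(E[mod, ], sp_of_sample, mean)[species]
    for (tc in trait_cols) {
      if (!tc %in% names(traits)) next
      tv <- stats::setNames(traits[[tc]], traits$species)[species]
      levels_all <- sort(unique(tv))
      test_levels <- if (length(levels_all) == 2) levels_all[2] else levels_all
      for (lev in test_levels) {
        y <- stats::setNames(as.integer(tv == lev), species)
        if (length(unique(y)) < 2) next # trait level absent or universal
        samples <- list(); psrf <- c()
        ess <- c(intercept = 0, slope = 0)
        for (ti in seq_along(trees)) {
          fit_counter <- fit_counter + 1L
          fit <- fit_phylo_probit(y, pred, trees[[ti]], spec,
                                  seed = (as.integer(seed) + fit_counter) %%
                                    .Machine$integer.max)
          diag_t <- convergence_diagnostics(fit$chains)
          fe <- match(c("intercept", "slope"), diag_t$parameter)
          psrf <- c(psrf, diag_t$psrf[fe])
          ess <- ess + diag_t$ess[fe]
          samples[[ti]] <- do.call(rbind, fit$chains)
        }
        pooled <- do.call(rbind, samples)
        ci <- stats::quantile(pooled[, "slope"], c(0.025, 0.975), names = FALSE)
        significant <- ci[1] > 0 || ci[2] < 0
        post_mean <- mean(pooled[, "slope"])
        fl <- flags[flags$module == mod & flags$flag != "none", ]
        shared <- sum(tv[fl$species] == lev)
        out[[length(out) + 1]] <- tibble::tibble(
          module = mod, trait = tc, level = lev,
          post_mean = post_mean, ci_lo = ci[1], ci_hi = ci[2],
          significant = significant,
          psrf_max = if (all(is.na(psrf))) NA_real_ else max(psrf, na.rm = TRUE),
          ess_min = min(ess),
          n_flagged_shared = shared,
          direction = ifelse(post_mean >= 0, "positive", "negative"),
          label = classify_trait_association(significant, shared)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
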
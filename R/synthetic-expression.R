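#' Describe the planted module structure of a simulated expression dataset
#'
#' A module plan fixes, for each planted co-expression module, how many genes
#' it contains and the average within-module correlation its genes should
#' reach, plus how many unstructured background genes surround the modules
#' and which species/trait effects drive each module eigengene.
#'
#' Within a module, gene g follows `a_g * E + sqrt(1 - a_g^2) * noise` on the
#' log-expression scale, where `E` is the module eigengene and the loadings
#' `a_g` are drawn uniformly around `sqrt(target_cor)` (half-width
#' `loading_spread`, capped at 0.99). The expected pairwise within-module
#' correlation is then `target_cor`, while the loading spread gives each
#' module the hub/periphery connectivity gradient seen in real networks.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (recycled to `n_modules`).
#' @param target_cor Average within-module correlation, in (0, 1]
#'   (recycled). `target_cor = 1` plants noise-free modules.
#' @param n_background Independent-noise genes with no module structure.
#' @param trait_effects Optional tibble with columns `module`, `trait`
#'   (one of `"syndrome"`, `"color"`, `"shape"`, `"spur"`), `level`, `effect`:
#'   species whose trait matches `level` have `effect` added to that module's
#'   eigengene (in eigengene SD units, before standardization).
#' @param bm_sd SD of the Brownian species effect on each eigengene over the
#'   unit-depth tree.
#' @param rep_noise_sd SD of the i.i.d. replicate noise on each eigengene.
#' @param loading_spread Half-width of the uniform loading distribution.
#' @return A `module_plan` tibble (one row per module) with the shared
#'   parameters stored as attributes.
#' @export
module_plan <- function(n_modules = 2, module_size = 30, target_cor = 0.8,
                        n_background = 60, trait_effects = NULL,
                        bm_sd = 0.5, rep_noise_sd = 0.3,
                        loading_spread = 0.14) {
  if (n_modules < 1) stop("`n_modules` must be >= 1", call. = FALSE)
  sizes <- rep_len(module_size, n_modules)
  cors <- rep_len(target_cor, n_modules)
  if (any(sizes < 1)) stop("module sizes must be positive", call. = FALSE)
  if (any(cors <= 0 | cors > 1)) {
    stop("`target_cor` must be in (0, 1]", call. = FALSE)
  }
  if (n_background < 0) stop("`n_background` must be >= 0", call. = FALSE)
  plan <- tibble::tibble(
    module = seq_len(n_modules),
    n_genes = as.integer(sizes),
    target_cor = cors
  )
  attr(plan, "n_background") <- as.integer(n_background)
  attr(plan, "trait_effects") <- trait_effects
  attr(plan, "bm_sd") <- bm_sd
  attr(plan, "rep_noise_sd") <- rep_noise_sd
  attr(plan, "loading_spread") <- loading_spread
  class(plan) <- c("module_plan", class(plan))
  plan
}

#' Simulate a two-stage orthogroup expression dataset with planted modules
#'
#' For every stage and every planted module, a module eigengene is built per
#' sample as Brownian species effect (on the tree) + trait effect + replicate
#' noise, then standardized. Module genes load on their eigengene as described
#' in [module_plan()]; background genes are independent noise. Log-scale
#' values `mu_g + x` (gene baselines `mu_g ~ U(4, 10)`) are exponentiated to a
#' non-negative count-like scale (`2^value - 1`), which the preprocessing
#' transform inverts up to library-size factors.
#'
#' @param tree Species tree from [simulate_phylogeny()].
#' @param traits Trait table from [simulate_traits()]; must cover exactly the
#'   tree's species.
#' @param plan A [module_plan()].
#' @param n_replicates Biological replicates per species per stage (>= 2).
#' @param stages Character vector of stage labels.
#' @param seed Integer seed; output is a pure function of all arguments.
#' @return An object of class `sim_expression`: a list with
#'   * `counts`: named list (per stage) of orthogroup x sample matrices,
#'   * `log_values`: the same data on the log2 scale before exponentiation,
#'   * `meta`: tibble `sample`, `species`, `stage`, `replicate`,
#'   * `truth`: tibble `orthogroup`, `module` (0 = background),
#'   * `eigengenes`: per-stage matrix of the true planted eigengenes,
#'   * `tree`, `traits`, `plan`.
#' @export
simulate_expression <- function(tree, traits, plan, n_replicates = 3,
                                stages = c("Bud", "D"), seed) {
  stopifnot(inherits(tree, "phylo"))
  if (!inherits(plan, "module_plan") || nrow(plan) == 0) {
    stop("`plan` must be a nonempty module_plan", call. = FALSE)
  }
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (!setequal(traits$species, tree$tip.label)) {
    stop("`traits` species do not match the tree's tip labels", call. = FALSE)
  }
  set.seed(as.integer(seed))

  species <- tree$tip.label
  n_bg <- attr(plan, "n_background")
  bm_sd <- attr(plan, "bm_sd")
  rep_sd <- attr(plan, "rep_noise_sd")
  spread <- attr(plan, "loading_spread")
  effects <- attr(plan, "trait_effects")

  n_genes <- sum(plan$n_genes) + n_bg
  og_ids <- sprintf("og%05d", seq_len(n_genes))
  truth <- tibble::tibble(
    orthogroup = og_ids,
    module = c(rep(plan$module, plan$n_genes), rep(0L, n_bg))
  )

  meta <- tidyr::expand_grid(
    stage = stages, species = species,
    replicate = seq_len(n_replicates)
  )
  meta$sample <- sprintf("%s_%s_r%d", meta$species, meta$stage, meta$replicate)
  meta <- meta[, c("sample", "species", "stage", "replicate")]

  ## per-gene baselines and module loadings are shared across stages so the
  ## two stages describe the same genes
  mu_g <- stats::runif(n_genes, 4, 10)
  loadings <- unlist(lapply(seq_len(nrow(plan)), function(m) {
    a <- sqrt(plan$target_cor[m])
    stats::runif(plan$n_genes[m], max(a - spread, 0.05), min(a + spread, 0.99))
  }))
  if (any(plan$target_cor == 1)) {
    loadings[rep(plan$target_cor, plan$n_genes) == 1] <- 1
  }

  trait_shift <- function(m) {
    shift <- stats::setNames(numeric(length(species)), species)
    if (is.null(effects)) return(shift)
    eff <- effects[effects$module == m, , drop = FALSE]
    if (nrow(eff) == 0) return(shift)
    for (i in seq_len(nrow(eff))) {
      hit <- traits$species[traits[[eff$trait[i]]] == eff$level[i]]
      shift[hit] <- shift[hit] + eff$effect[i]
    }
    shift
  }

  counts <- list(); logvals <- list(); eiglist <- list()
  for (st in stages) {
    sm <- meta[meta$stage == st, ]
    n_s <- nrow(sm)
    eig <- matrix(NA_real_, nrow(plan), n_s,
                  dimnames = list(paste0("module", plan$module), sm$sample))
    x <- matrix(NA_real_, n_genes, n_s, dimnames = list(og_ids, sm$sample))
    row0 <- 0L
    for (m in seq_len(nrow(plan))) {
      bm <- ape::rTraitCont(tree, model = "BM", sigma = bm_sd)
      shift <- trait_shift(plan$module[m])
      e <- bm[sm$species] + shift[sm$species] + stats::rnorm(n_s, 0, rep_sd)
      e <- as.numeric(scale(e))
      eig[m, ] <- e
      idx <- row0 + seq_len(plan$n_genes[m])
      a <- loadings[idx]
      noise <- matrix(stats::rnorm(length(idx) * n_s), length(idx), n_s)
      x[idx, ] <- a %o% e + sqrt(1 - a^2) * noise
      row0 <- row0 + plan$n_genes[m]
    }
    if (n_bg > 0) {
      x[row0 + seq_len(n_bg), ] <- matrix(stats::rnorm(n_bg * n_s), n_bg, n_s)
    }
    l <- mu_g + x
    counts[[st]] <- pmax(2^l - 1, 0)
    logvals[[st]] <- l
    eiglist[[st]] <- eig
  }

  structure(
    list(counts = counts, log_values = logvals, meta = meta, truth = truth,
         eigengenes = eiglist, tree = tree, traits = traits, plan = plan),
    class = "sim_expression"
  )
}

#' @export
print.sim_expression <- function(x, ...) {
  cat("Simulated expression dataset\n")
  cat("  stages:", paste(names(x$counts), collapse = ", "), "\n")
  cat("  orthogroups:", nrow(x$truth),
      sprintf("(%d planted in %d modules, %d background)\n",
              sum(x$truth$module > 0), max(x$truth$module),
              sum(x$truth$module == 0)))
  cat("  samples per stage:", ncol(x$counts[[1]]), "\n")
  invisible(x)
}
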
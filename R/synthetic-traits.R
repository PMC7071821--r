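#' Pollination syndrome trait mapping
#'
#' The floral-trait combinations permitted for each pollination syndrome:
#' bee-pollinated flowers are white or purple and funnelform without spurs;
#' hummingbird-pollinated flowers are red or yellow, tubular or salverform,
#' without spurs; butterfly-pollinated flowers are purple, salverform, and the
#' only syndrome in which corolla spurs occur.
#'
#' @format A tibble with columns `syndrome`, `colors`, `shapes`, `spur`
#'   (list-columns for the permitted colour/shape sets).
#' @export
syndrome_trait_map <- function() {
  tibble::tibble(
    syndrome = c("bee", "hummingbird", "butterfly"),
    colors   = list(c("white", "purple"), c("red", "yellow"), "purple"),
    shapes   = list("funnelform", c("tubular", "salverform"), "salverform"),
    spur     = c("absent", "absent", "present")
  )
}

#' Simulate pollination syndromes and floral traits on a phylogeny
#'
#' Syndromes evolve by a continuous-time Markov walk along the tree (a state
#' switch occurs on a branch with probability `1 - exp(-switch_rate * len)`,
#' the new state drawn from `proportions`), which induces phylogenetic signal.
#' Colour, shape and corolla spur are then drawn from the permitted set for
#' the species' syndrome (see [syndrome_trait_map()]): spurs occur only under
#' butterfly pollination.
#'
#' @param tree Ultrametric [ape::phylo] from [simulate_phylogeny()].
#' @param proportions Named numeric vector of syndrome proportions over
#'   `c("bee", "butterfly", "hummingbird")`; must sum to 1. The default
#'   mirrors a 12-species design with 3 bee, 4 butterfly and 5 hummingbird
#'   species.
#' @param switch_rate Markov switch rate per unit branch length (tree depth
#'   is 1, so ~`switch_rate` expected switch opportunities root-to-tip). The
#'   default 3 typically yields all three syndromes among 12 species -- as in
#'   the emulated design -- while keeping clear phylogenetic clustering.
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `syndrome`, `color`, `shape`,
#'   `spur`.
#' @export
simulate_traits <- function(tree,
                            proportions = c(bee = 3 / 12, butterfly = 4 / 12,
                                            hummingbird = 5 / 12),
                            switch_rate = 3,
                            seed) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) == 0) {
    stop("`tree` must be a nonempty phylo object", call. = FALSE)
  }
  syndromes <- c("bee", "butterfly", "hummingbird")
  if (!setequal(names(proportions), syndromes)) {
    stop("`proportions` must be named over bee/butterfly/hummingbird", call. = FALSE)
  }
  proportions <- proportions[syndromes]
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n_all <- ntip + tree$Nnode
  state <- character(n_all)
  state[root] <- sample(syndromes, 1, prob = proportions)
  ## preorder traversal: parents before children
  ord <- rev(ape::postorder(tree))
  for (i in ord) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]; len <- tree$edge.length[i]
    if (stats::runif(1) < 1 - exp(-switch_rate * len)) {
      state[ch] <- sample(syndromes, 1, prob = proportions)
    } else {
      state[ch] <- state[p]
    }
  }
  syn <- state[seq_len(ntip)]

  map <- syndrome_trait_map()
  draw_from <- function(x) if (length(x) == 1) x else sample(x, 1)
  rows <- lapply(seq_len(ntip), function(i) {
    m <- map[map$syndrome == syn[i], ]
    tibble::tibble(
      species = tree$tip.label[i],
      syndrome = syn[i],
      color = draw_from(m$colors[[1]]),
      shape = draw_from(m$shapes[[1]]),
      spur = m$spur
    )
  })
  dplyr::bind_rows(rows)
}
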
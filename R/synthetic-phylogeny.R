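#' Simulate an ultrametric species phylogeny
#'
#' Draws a pure-birth (Yule) tree over `n_species` tips and rescales it so
#' that every root-to-tip path has length exactly 1. This is the backbone for
#' simulated trait evolution, species effects on module eigengenes, and codon
#' evolution.
#'
#' @param n_species Number of tips (at least 2).
#' @param seed Integer seed; the tree is a pure function of
#'   `(n_species, seed)`.
#' @param birth Speciation rate of the pure-birth process. The value only
#'   shapes relative node depths; the output is always rescaled to depth 1.
#'
#' @return An [ape::phylo] object, rooted, binary, ultrametric with root
#'   depth 1, tips labelled `sp01`, `sp02`, ...
#' @export
#' @examples
#' tr <- simulate_phylogeny(12, seed = 1)
#' max(node_depths(tr)) # 1
simulate_phylogeny <- function(n_species, seed, birth = 1) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2) {
    stop("`n_species` must be a single number >= 2", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = birth, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  rescale_to_unit_depth(tree)
}

#' Root-to-tip path lengths of a rooted tree
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return Named numeric vector of root-to-tip distances, one per tip.
#' @export
node_depths <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}

## Scale all branch lengths so the maximum root-to-tip depth is 1. For an
## already-ultrametric tree this makes every depth exactly 1.
rescale_to_unit_depth <- function(tree) {
  d <- max(ape::node.depth.edgelength(tree))
  if (d <= 0) stop("tree has zero depth", call. = FALSE)
  tree$edge.length <- tree$edge.length / d
  tree
}

#' Make an arbitrary rooted tree ultrametric by mean path length smoothing
#'
#' Each internal node is assigned a distance-to-tips equal to the mean of its
#' original node-to-descendant-tip path lengths; branch lengths are rebuilt
#' from those node heights (a parent whose mean height falls below a child's
#' is clamped to the child's height, with a warning). The result is rescaled
#' to root depth 1. This is a light-weight stand-in for penalised-likelihood
#' time calibration: topology and the relative ordering of node heights are
#' preserved, and an already-ultrametric tree is a fixed point up to global
#' scaling.
#'
#' @param tree A rooted [ape::phylo] with positive branch lengths.
#' @return An ultrametric [ape::phylo], root depth 1.
#' @export
ultrametricize <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("`tree` must have non-negative branch lengths", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n_all <- ntip + nnode

  ## children list
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], i) # store edge index
  }

  ## mean distance to descendant tips + number of descendant tips, postorder
  height <- numeric(n_all) # mean node-to-tip distance
  ntips_below <- integer(n_all)
  ntips_below[seq_len(ntip)] <- 1L
  ## postorder over internal nodes: process edges in ape postorder
  ord <- ape::reorder.phylo(tree, "postorder")
  sum_paths <- numeric(n_all)
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]; len <- ord$edge.length[i]
    sum_paths[p] <- sum_paths[p] + sum_paths[ch] + ntips_below[ch] * len
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
  }
  height <- ifelse(ntips_below > 0, sum_paths / pmax(ntips_below, 1L), 0)
  height[seq_len(ntip)] <- 0

  ## enforce parent height > child height (clamp), rebuild branch lengths
  new_len <- numeric(nrow(tree$edge))
  clamped <- FALSE
  ## process edges parent-before-child so clamping propagates
  pre <- rev(seq_len(nrow(ord$edge)))
  h <- height
  for (i in pre) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    if (h[ch] > h[p]) {
      h[ch] <- h[p]
      clamped <- TRUE
    }
  }
  if (clamped) warning("non-monotone node heights clamped during smoothing")
  for (i in seq_len(nrow(tree$edge))) {
    new_len[i] <- h[tree$edge[i, 1]] - h[tree$edge[i, 2]]
  }
  out <- tree
  out$edge.length <- new_len
  rescale_to_unit_depth(out)
}

#' Sample trees for multi-tree analyses
#'
#' Samples `n` trees without replacement from a candidate list (gene trees,
#' bootstrap trees, ...). If fewer than `n` are available the sample is drawn
#' with replacement and a warning is raised.
#'
#' @param trees A list of [ape::phylo] objects (or a `multiPhylo`).
#' @param n Number of trees to draw (default 50).
#' @param seed Integer seed.
#' @return A list of `n` trees.
#' @export
sample_trees <- function(trees, n = 50, seed) {
  if (length(trees) == 0) stop("`trees` must be a nonempty list", call. = FALSE)
  trees <- unclass(trees)
  set.seed(as.integer(seed))
  if (length(trees) >= n) {
    idx <- sample.int(length(trees), n)
  } else {
    warning("fewer trees than requested; sampling with replacement")
    idx <- sample.int(length(trees), n, replace = TRUE)
  }
  trees[idx]
}
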
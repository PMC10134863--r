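#' Generate a rooted binary tree with positive branch lengths
#'
#' Substrate for ancestral-state reconstruction tests. Two topologies:
#' `"balanced"` recursively splits the tips in half (a complete binary
#' shape when `n_tips` is a power of two); `"random-split"` splits each
#' clade at a uniformly chosen point. Branch lengths are drawn uniformly
#' from `length_range`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param mode `"balanced"` or `"random-split"`.
#' @param seed Integer seed.
#' @param length_range Positive pair; branch lengths ~ U(min, max).
#' @return An [ape::phylo] tree, rooted, binary, tips labelled `t1..tn`.
#' @examples
#' tr <- gen_tree(8, "balanced", seed = 1)
#' ape::Ntip(tr)
#' @export
gen_tree <- function(n_tips, mode = c("random-split", "balanced"),
                     seed = 1L, length_range = c(0.1, 1)) {
  mode <- match.arg(mode)
  if (n_tips < 2) abort("A tree needs at least 2 tips.")
  stopifnot(length_range[1] > 0, length_range[2] >= length_range[1])
  build <- function(tips) {
    if (length(tips) == 1) {
      return(tips)
    }
    k <- if (mode == "balanced") {
      ceiling(length(tips) / 2)
    } else {
      sample.int(length(tips) - 1L, 1L)
    }
    paste0("(", build(tips[seq_len(k)]), ",",
           build(tips[-seq_len(k)]), ")")
  }
  withr::with_seed(seed, {
    topo <- paste0(build(paste0("t", seq_len(n_tips))), ";")
    tree <- ape::read.tree(text = topo)
    tree$edge.length <- runif(nrow(tree$edge),
                              length_range[1], length_range[2])
  })
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Exact Gaussian increments: each child's value is its parent's value plus
#' N(0, `sigma2` * branch length). The true state at every internal node is
#' returned alongside the tip values, giving ground truth for ancestral
#' reconstruction.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param sigma2 BM rate (variance per unit branch length), >= 0.
#' @param root_state Trait value at the root.
#' @param seed Integer seed.
#' @return List with `tip_traits` (named numeric over tip labels) and
#'   `node_states` (named numeric over internal node numbers as used by
#'   ape, root first at `Ntip + 1`).
#' @examples
#' tr <- gen_tree(8, seed = 1)
#' sim <- simulate_bm(tr, sigma2 = 1, root_state = 50, seed = 2)
#' sim$tip_traits
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Tree must have branch lengths on every edge.")
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  states <- numeric(ntip + nnode)
  states[ntip + 1L] <- root_state
  withr::with_seed(seed, {
    inc <- rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  })
  for (e in seq_len(nrow(tree$edge))) {
    states[tree$edge[e, 2]] <- states[tree$edge[e, 1]] + inc[e]
  }
  node_ids <- (ntip + 1L):(ntip + nnode)
  list(
    tip_traits = setNames(states[seq_len(ntip)], tree$tip.label),
    node_states = setNames(states[node_ids], node_ids)
  )
}
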
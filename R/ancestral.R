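#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser that the rest of the
#' package uses, plus the polytomy/zero-length normalisation required by
#' the contrast algorithm.
#'
#' @param x Newick text (a string containing `;`) or a file path.
#' @param tree An [ape::phylo] object.
#' @param file Optional output path; with `NULL` the Newick string is
#'   returned.
#' @param digits Branch-length precision for writing.
#' @return `read_newick()` returns a `phylo`; `write_newick()` a string
#'   (invisibly, when writing to file).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(tr)
#' @export
read_newick <- function(x) {
  tree <- if (grepl(";", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(tree)) abort("Malformed Newick input.")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Normalise a tree for contrast-based inference
#'
#' Resolves polytomies to binary (zero-length branches) and then replaces
#' all non-positive branch lengths by `eps` times the tree height, so that
#' every contrast has strictly positive expected variance.
#'
#' @param tree An [ape::phylo] tree.
#' @param eps Relative floor for branch lengths. Default `1e-8`.
#' @return A rooted, binary `phylo` with strictly positive branch lengths.
#' @export
resolve_tree <- function(tree, eps = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  height <- max(ape::node.depth.edgelength(tree))
  floor_len <- eps * max(height, 1)
  tree$edge.length[tree$edge.length <= 0] <- floor_len
  tree
}

# Shared scaffolding for the pruning passes: postorder parent list,
# per-node children and edge lengths. Assumes a resolved binary tree.
tree_scaffold <- function(tree, traits) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing) > 0) {
    abort(paste0("No trait value for tip(s): ",
                 paste(missing, collapse = ", ")))
  }
  child_len <- numeric(ntip + tree$Nnode)
  child_len[tree$edge[, 2]] <- tree$edge.length
  children <- split(tree$edge[, 2], tree$edge[, 1])
  list(
    tree = tree, ntip = ntip,
    parents_postorder = unique(tree$edge[, 1]), # children-first order
    children = children, child_len = child_len,
    x_tip = unname(traits[tree$tip.label])
  )
}

# Downward (post-order) pruning pass: per node, the ML state and the
# extra variance contributed by its subtree.
down_pass <- function(sc) {
  nn <- sc$ntip + sc$tree$Nnode
  x <- numeric(nn)
  v <- numeric(nn)
  x[seq_len(sc$ntip)] <- sc$x_tip
  for (p in sc$parents_postorder) {
    ch <- sc$children[[as.character(p)]]
    w <- v[ch] + sc$child_len[ch]
    x[p] <- sum(x[ch] / w) / sum(1 / w)
    v[p] <- 1 / sum(1 / w)
  }
  list(x = x, v = v)
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's recursion: each internal node of a binary tree
#' contributes one contrast between its two daughter values, with expected
#' variance equal to the sum of the daughters' variance-adjusted branch
#' lengths; daughter values are precision-weighted means and branch
#' lengths are inflated accordingly. Standardized contrasts are i.i.d.
#' N(0, sigma2) under Brownian motion, which is the basis for both rate
#' estimation and model checking.
#'
#' @param tree A rooted tree ([ape::phylo]); polytomies and zero branches
#'   are normalised via [resolve_tree()].
#' @param traits Named numeric vector covering every tip label.
#' @return Tibble `node` (ape node number), `contrast` (first daughter
#'   minus second), `variance` (expected, units of branch length), and
#'   `standardized` (`contrast / sqrt(variance)`).
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' pic_contrasts(tr, c(A = 0, B = 2))
#' @export
pic_contrasts <- function(tree, traits) {
  tree <- resolve_tree(tree)
  sc <- tree_scaffold(tree, traits)
  nn <- sc$ntip + tree$Nnode
  x <- numeric(nn)
  v <- numeric(nn)
  x[seq_len(sc$ntip)] <- sc$x_tip
  rows <- vector("list", length(sc$parents_postorder))
  for (k in seq_along(sc$parents_postorder)) {
    p <- sc$parents_postorder[k]
    ch <- sc$children[[as.character(p)]]
    w <- v[ch] + sc$child_len[ch]
    rows[[k]] <- tibble(
      node = p,
      contrast = x[ch[1]] - x[ch[2]],
      variance = sum(w)
    )
    x[p] <- sum(x[ch] / w) / sum(1 / w)
    v[p] <- 1 / sum(1 / w)
  }
  bind_rows(rows) |>
    mutate(standardized = .data$contrast / sqrt(.data$variance)) |>
    arrange(.data$node)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the trait value at every internal node of a rooted tree by
#' maximum likelihood under Brownian motion. The estimate at a node equals
#' the ML root estimate of the tree re-rooted at that node; it is computed
#' here in a single O(n) double pass (a downward pruning pass followed by
#' an upward pass propagating the complement of each subtree), which gives
#' identical values without physically re-rooting.
#'
#' The BM rate is estimated from the standardized contrasts
#' (`sigma2 = mean(standardized^2)`, the rooting-invariant REML form) and
#' scales each node's estimator variance; 95% confidence intervals are
#' `state +/- 1.96 * sqrt(variance)`.
#'
#' @inheritParams pic_contrasts
#' @return An object of class `anc_recon`: list with `estimates` (tibble
#'   `node`, `state`, `variance`, `ci_lower`, `ci_upper`), `sigma2`,
#'   `contrasts` (from [pic_contrasts()]), `tree` (the resolved tree) and
#'   `traits`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' tr <- read_newick("(A:1,B:3);")
#' anc_ml(tr, c(A = 0, B = 4))$estimates # root state 1.0
#' @export
anc_ml <- function(tree, traits) {
  tree <- resolve_tree(tree)
  sc <- tree_scaffold(tree, traits)
  tree <- sc$tree
  ntip <- sc$ntip
  root <- ntip + 1L
  down <- down_pass(sc)
  contrasts <- pic_contrasts(tree, traits)
  sigma2 <- mean(contrasts$standardized^2)

  # upward pass: (x_up, v_up) summarise the tree minus each node's
  # subtree, with variance measured at the node itself
  nn <- ntip + tree$Nnode
  x_up <- rep(NA_real_, nn)
  v_up <- rep(NA_real_, nn)
  for (p in rev(sc$parents_postorder)) { # root first
    ch <- sc$children[[as.character(p)]]
    for (i in seq_along(ch)) {
      ci <- ch[i]
      co <- ch[-i]
      xo <- down$x[co]
      wo <- down$v[co] + sc$child_len[co]
      if (p == root) {
        x_at_p <- xo
        v_at_p <- wo
      } else {
        prec <- 1 / wo + 1 / v_up[p]
        x_at_p <- (xo / wo + x_up[p] / v_up[p]) / prec
        v_at_p <- 1 / prec
      }
      x_up[ci] <- x_at_p
      v_up[ci] <- v_at_p + sc$child_len[ci]
    }
  }

  nodes <- root:nn
  state <- numeric(length(nodes))
  vhat <- numeric(length(nodes))
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    if (nd == root) {
      state[k] <- down$x[nd]
      vhat[k] <- sigma2 * down$v[nd]
    } else {
      prec <- 1 / down$v[nd] + 1 / v_up[nd]
      state[k] <- (down$x[nd] / down$v[nd] + x_up[nd] / v_up[nd]) / prec
      vhat[k] <- sigma2 / prec
    }
  }
  est <- tibble(
    node = nodes, state = state, variance = vhat,
    ci_lower = state - 1.96 * sqrt(vhat),
    ci_upper = state + 1.96 * sqrt(vhat)
  )
  structure(
    list(estimates = est, sigma2 = sigma2, contrasts = contrasts,
         tree = tree, traits = traits),
    class = "anc_recon"
  )
}

#' @export
print.anc_recon <- function(x, ...) {
  cat("<anc_recon> ", ape::Ntip(x$tree), " tips, ",
      x$tree$Nnode, " internal nodes\n", sep = "")
  cat(sprintf("  sigma2 = %.6g; root state = %.6g\n",
              x$sigma2, x$estimates$state[1]))
  invisible(x)
}

#' @export
tidy.anc_recon <- function(x, ...) x$estimates

#' @export
glance.anc_recon <- function(x, ...) {
  tibble(sigma2 = x$sigma2, n_tips = ape::Ntip(x$tree),
         n_nodes = x$tree$Nnode,
         root_state = x$estimates$state[1])
}

#' Recovery metrics for ancestral-state estimates
#'
#' Compares estimates against the true node states recorded by
#' [simulate_bm()], for calibration studies.
#'
#' @param true_states Named numeric (node number -> true value).
#' @param estimates `anc_recon` object or its `estimates` tibble.
#' @return One-row tibble `rmse`, `bias` (mean estimate minus truth), and
#'   `ci_coverage` (fraction of true values inside the 95% CI).
#' @export
recovery_metrics <- function(true_states, estimates) {
  if (inherits(estimates, "anc_recon")) estimates <- estimates$estimates
  est <- estimates[match(names(true_states),
                         as.character(estimates$node)), ]
  if (anyNA(est$node)) {
    abort("Node sets of truth and estimates do not match.")
  }
  err <- est$state - unname(true_states)
  tibble(
    rmse = sqrt(mean(err^2)),
    bias = mean(err),
    ci_coverage = mean(true_states >= est$ci_lower &
                         true_states <= est$ci_upper)
  )
}

#' Annotate a tree with ancestral-state labels
#'
#' Writes each internal node's ML state into the tree's node labels
#' (fixed two-decimal format) and returns the companion node table.
#'
#' @param recon An `anc_recon` object from [anc_ml()].
#' @return List with `tree` (labelled `phylo`, ready for
#'   [write_newick()]) and `table` (the estimates tibble with a `label`
#'   column).
#' @export
annotate_tree <- function(recon) {
  stopifnot(inherits(recon, "anc_recon"))
  tree <- recon$tree
  est <- recon$estimates
  labels <- sprintf("%.2f", est$state)
  tree$node.label <- labels[order(est$node)]
  list(tree = tree, table = mutate(est, label = labels))
}
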
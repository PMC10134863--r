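# Independent oracles used across tests. These recompute quantities from
# first principles, deliberately avoiding the package's own code paths.

# Direct Henderson-Hasselbalch net charge, written independently of the
# package internals (explicit residue loop, no shared helpers).
oracle_charge <- function(sequence, pH, pka) {
  res <- strsplit(gsub("[BJOUXZ*]", "", toupper(sequence)), "")[[1]]
  q <- rep(0, length(pH))
  # one N- and one C-terminus
  q <- q + 1 / (1 + 10^(pH - pka$n_term))
  q <- q - 1 / (1 + 10^(pka$c_term - pH))
  basic <- c(K = pka$side_chain[["K"]], R = pka$side_chain[["R"]],
             H = pka$side_chain[["H"]])
  acidic <- c(D = pka$side_chain[["D"]], E = pka$side_chain[["E"]],
              C = pka$side_chain[["C"]], Y = pka$side_chain[["Y"]])
  for (r in names(basic)) {
    n <- sum(res == r)
    if (n > 0) q <- q + n / (1 + 10^(pH - basic[[r]]))
  }
  for (r in names(acidic)) {
    n <- sum(res == r)
    if (n > 0) q <- q - n / (1 + 10^(acidic[[r]] - pH))
  }
  q
}

# Brute-force pI: pH grid scan minimising |Q|.
oracle_pi_grid <- function(sequence, pka, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(oracle_charge(sequence, grid, pka)))]
}

# Brute-force ML ancestral states: numerical maximisation of the joint BM
# likelihood over all internal states. For fixed sigma2 this is the
# minimiser of sum over edges of (x_child - x_parent)^2 / branch_length,
# independent of sigma2.
oracle_anc_bruteforce <- function(tree, traits) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tipx <- unname(traits[tree$tip.label])
  objective <- function(a) {
    x <- c(tipx, a)
    d <- x[tree$edge[, 2]] - x[tree$edge[, 1]]
    sum(d^2 / tree$edge.length)
  }
  start <- rep(mean(tipx), nnode)
  fit <- optim(start, objective, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-15))
  setNames(fit$par, (ntip + 1):(ntip + nnode))
}

# A random protein sequence with a realistic mix of ionizable residues.
random_protein <- function(len, seed) {
  withr::with_seed(seed, {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    paste(sample(aa, len, replace = TRUE), collapse = "")
  })
}
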
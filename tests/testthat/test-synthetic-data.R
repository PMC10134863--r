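test_that("gen_proteome respects degenerate weights, composition targets and determinism", {
  # degenerate weights: every residue is G
  p <- gen_proteome(3, c(5, 5), c(G = 1), seed = 1)
  expect_equal(p$sequence, rep("GGGGG", 3))
  expect_equal(nrow(p), 3)

  # law of large numbers: uniform weights -> each residue near 0.05
  p <- gen_proteome(100, c(100, 200), seed = 7)
  freqs <- residue_frequencies(p)
  expect_true(all(abs(freqs$freq - 0.05) <= 0.01))
  expect_equal(sum(freqs$freq), 1, tolerance = 1e-12)

  # determinism: identical seed gives identical records
  expect_identical(gen_proteome(10, c(50, 80), seed = 42),
                   gen_proteome(10, c(50, 80), seed = 42))
  expect_false(identical(gen_proteome(10, c(50, 80), seed = 42)$sequence,
                         gen_proteome(10, c(50, 80), seed = 43)$sequence))

  expect_error(gen_proteome(3, c(5, 5), c(G = 0), seed = 1), "positive")
  expect_error(gen_proteome(3, c(5, 5), c(G = -1), seed = 1),
               "non-negative")
})

test_that("gen_bimodal_proteome embeds the latent class structure", {
  p <- gen_bimodal_proteome(1000, frac_acidic = 0.3, seed = 1)
  expect_equal(sum(p$class == "acidic"), 300)
  expect_equal(sum(p$class == "basic"), 700)

  # one-component case: all D/E-enriched, all pIs below 7
  p1 <- gen_bimodal_proteome(40, frac_acidic = 1, seed = 2)
  expect_true(all(p1$class == "acidic"))
  pis <- proteome_pi(p1)
  expect_true(all(pis$pi < 7))

  expect_warning(out <- gen_bimodal_proteome(0, 0.5, seed = 1), "empty")
  expect_equal(nrow(out), 0)
})

test_that("gen_diverged_pair reports the realized identity exactly", {
  base <- gen_proteome(20, c(60, 60), seed = 1)
  # sub_rate 0: identical copy
  d0 <- gen_diverged_pair(base, 0, seed = 2)
  expect_identical(d0$b$sequence, base$sequence)
  expect_equal(d0$true_identity, 1)

  # direct recount of unchanged positions matches the reported truth
  d <- gen_diverged_pair(gen_proteome(100, c(100, 100), seed = 3),
                         sub_rate = 0.1, seed = 4)
  same <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, d$a$sequence, d$b$sequence)
  expect_equal(sum(same) / sum(nchar(d$a$sequence)), d$true_identity)
  expect_equal(d$true_identity, 0.9, tolerance = 0.011)

  # different seeds at the same rate give different sequences
  d1 <- gen_diverged_pair(base, 0.5, seed = 10)
  d2 <- gen_diverged_pair(base, 0.5, seed = 11)
  expect_false(identical(d1$b$sequence, d2$b$sequence))

  expect_error(gen_diverged_pair(base[0, ], 0.1), "empty")
})

test_that("gen_marker_table hits its completeness/contamination targets", {
  set <- marker_set("toy", sprintf("M%03d", 1:140))
  t1 <- gen_marker_table("g", set, completeness = 1, contamination = 0,
                         seed = 1)
  expect_equal(nrow(t1), 140)
  expect_true(all(t1$count == 1))

  t2 <- gen_marker_table("g", set, completeness = 0.5, seed = 1)
  expect_equal(nrow(t2), 70)

  set149 <- marker_set("a149", sprintf("M%03d", 1:149))
  t3 <- gen_marker_table("g", set149, completeness = 0.9,
                         contamination = 0.05, seed = 2)
  expect_equal(nrow(t3), round(0.9 * 149)) # 134 markers present
  expect_equal(sum(t3$count == 2), round(0.05 * 149))
  expect_error(gen_marker_table("g", character(), 1, 0), "empty")
})

test_that("gen_tree produces rooted binary trees and round-trips Newick", {
  t2 <- gen_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(nrow(t2$edge), 2)

  tb <- gen_tree(8, "balanced", seed = 1)
  expect_equal(tb$Nnode, 7)
  expect_true(ape::is.binary(tb) && ape::is.rooted(tb))
  expect_true(all(tb$edge.length > 0))

  tr <- gen_tree(64, "random-split", seed = 3)
  rt <- read_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(tr, rt, use.edge.length = FALSE))
  expect_identical(write_newick(rt), write_newick(tr))

  expect_error(gen_tree(1), "2 tips")
})

test_that("simulate_bm reproduces the BM variance/covariance structure", {
  tr <- gen_tree(6, seed = 1)
  # sigma2 = 0: everything equals the root state
  s0 <- simulate_bm(tr, sigma2 = 0, root_state = 5, seed = 2)
  expect_true(all(s0$tip_traits == 5))
  expect_true(all(s0$node_states == 5))

  # marginal variance at a tip = sigma2 * depth; sibling covariance =
  # shared path length (Monte Carlo over replicates)
  cherry <- read_newick("((A:1.5,B:1.5):0.5,C:2);")
  reps <- vapply(1:4000, function(i) {
    simulate_bm(cherry, 1, 0, seed = i)$tip_traits
  }, numeric(3))
  expect_equal(var(reps["A", ]), 2, tolerance = 0.1)   # depth 2, 5%
  expect_equal(cov(reps["A", ], reps["B", ]), 0.5, tolerance = 0.06)
  expect_lt(abs(cov(reps["A", ], reps["C", ])), 0.1)

  trNA <- tr
  trNA$edge.length <- NULL
  expect_error(simulate_bm(trNA, 1, 0, seed = 1), "branch length")
})

test_that("gen_annotations constructs the requested overlap fraction", {
  a0 <- gen_annotations(10000, 20, overlap_fraction = 0, seed = 1)
  expect_equal(overlap_ratio(a0), 0)

  a5 <- gen_annotations(20000, 100, overlap_fraction = 0.5, seed = 2)
  expect_equal(overlap_ratio(a5), 0.5)
  expect_equal(nrow(a5), 100)
  expect_true(all(a5$start >= 1))

  # odd overlap counts are handled via one cluster of three
  a3 <- gen_annotations(20000, 20, overlap_fraction = 0.35, seed = 3)
  expect_equal(overlap_ratio(a3), 7 / 20)

  expect_error(gen_annotations(100, 50, 0, gene_length = 90), "Infeasible")

  # one gene spanning the genome: coding density 1
  one <- tibble::tibble(seq_id = "c", start = 1, end = 500, strand = "+")
  expect_equal(coding_density(one, 500), 1)
})
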
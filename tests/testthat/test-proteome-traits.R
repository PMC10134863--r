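toy_proteome <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    genome_id = "g",
    protein_id = paste0("p", seq_along(seqs)),
    sequence = seqs
  )
}

test_that("residue_frequencies counts canonical residues and drops ambiguity", {
  f <- residue_frequencies(toy_proteome("GGGG"))
  expect_equal(f$freq[f$residue == "G"], 1)

  f2 <- residue_frequencies(toy_proteome("GA", "AG"))
  expect_equal(f2$freq[f2$residue %in% c("G", "A")], c(0.5, 0.5))

  # X is excluded from numerator and denominator
  f3 <- residue_frequencies(toy_proteome("GAXG"))
  expect_equal(f3$freq[f3$residue == "G"], 2 / 3)
  expect_equal(f3$freq[f3$residue == "A"], 1 / 3)
  expect_equal(sum(f3$freq), 1, tolerance = 1e-12)

  expect_error(residue_frequencies(toy_proteome("XXX")), "zero canonical")
})

test_that("ivywrel_fraction and group_fraction match hand counts and are order/concat invariant", {
  expect_equal(ivywrel_fraction(toy_proteome("IVYWREL"))$f_ivywrel, 1)
  expect_equal(ivywrel_fraction(toy_proteome("GGGG"))$f_ivywrel, 0)
  expect_equal(ivywrel_fraction(toy_proteome("IVYWRELGGGG"))$f_ivywrel,
               7 / 11)

  expect_equal(group_fraction(toy_proteome("RERE"), c("R", "E"))$fraction, 1)
  expect_equal(group_fraction(toy_proteome("GPGP"), "P")$fraction, 0.5)
  expect_equal(group_fraction(toy_proteome("RGEGG"), c("R", "E"))$fraction,
               0.4)
  expect_error(group_fraction(toy_proteome("RERE"), character()), "empty")

  # invariance to protein order and to concatenation into one record
  p <- gen_proteome(30, c(50, 120), seed = 9)
  shuffled <- p[rev(seq_len(nrow(p))), ]
  concat <- toy_proteome(paste(p$sequence, collapse = ""))
  expect_equal(ivywrel_fraction(p)$f_ivywrel,
               ivywrel_fraction(shuffled)$f_ivywrel)
  expect_equal(ivywrel_fraction(p)$f_ivywrel,
               ivywrel_fraction(concat)$f_ivywrel)
})

test_that("ogt_from_ivywrel is the documented affine map", {
  expect_equal(ogt_from_ivywrel(0), -335)
  expect_equal(ogt_from_ivywrel(1), 602)
  expect_equal(ogt_from_ivywrel(0.443), 80.091, tolerance = 1e-9)
  # affine in F
  a <- 0.3
  f1 <- 0.2
  f2 <- 0.6
  expect_equal(ogt_from_ivywrel(a * f1 + (1 - a) * f2),
               a * ogt_from_ivywrel(f1) + (1 - a) * ogt_from_ivywrel(f2))
  expect_error(ogt_from_ivywrel(1.2), "\\[0, 1\\]")
})

test_that("net charge has the right limits and is strictly decreasing", {
  for (seed in 1:20) {
    s <- random_protein(sample(10:80, 1), seed)
    grid <- seq(0, 14, by = 0.25)
    q <- net_charge(s, grid)
    expect_true(q[1] > 0)
    expect_true(q[length(q)] < 0)
    expect_true(all(diff(q) < 0))
  }
  # adding a lysine raises the charge everywhere
  s <- "GADE"
  grid <- seq(0, 14, by = 0.5)
  expect_true(all(net_charge(paste0(s, "K"), grid) > net_charge(s, grid)))
  # unknown residues are skipped with a warning
  expect_warning(q <- net_charge("GXG", 7), "skipped")
  expect_equal(q, net_charge("GG", 7))
})

test_that("the charge model agrees with an independently coded oracle", {
  pka <- get_pka("ipc")
  grid <- seq(0, 14, by = 0.1)
  for (seed in 1:10) {
    s <- random_protein(60, seed + 100)
    expect_equal(net_charge(s, grid, pka), oracle_charge(s, grid, pka),
                 tolerance = 1e-12)
  }
})

test_that("bisection pI matches the grid-scan oracle and behaves monotonically", {
  pka <- get_pka("ipc")
  # two-glycine chain: root of the two-terminal-group system
  pi_gg <- protein_pi("GG", pka)
  expect_equal(oracle_charge("GG", pi_gg, pka), 0, tolerance = 1e-4)
  expect_equal(pi_gg, (pka$n_term + pka$c_term) / 2, tolerance = 0.01)

  expect_lt(protein_pi("DDDD"), 7)
  expect_gt(protein_pi("KKKK"), 7)
  expect_gt(protein_pi("DDDDK"), protein_pi("DDDD"))

  for (seed in 1:50) {
    s <- random_protein(sample(20:150, 1), seed + 500)
    expect_equal(protein_pi(s, pka), oracle_pi_grid(s, pka),
                 tolerance = 2e-4)
  }
  # EMBOSS table shifts pI but the solver still matches its oracle
  emb <- get_pka("emboss")
  s <- random_protein(80, 1)
  expect_equal(protein_pi(s, emb), oracle_pi_grid(s, emb),
               tolerance = 2e-4)

  expect_error(protein_pi("GG", include_termini = FALSE), "ionizable")
})

test_that("proteome_pi averages defined pIs and flags undefined ones", {
  # constructed pIs around 5 and 9 average near 7 by symmetry of counts
  p <- toy_proteome("DDDDDDKK", "KKKKKKDD")
  out <- proteome_pi(p)
  expect_equal(nrow(out), 2)
  expect_true(out$pi[1] < 7 && out$pi[2] > 7)

  single <- proteome_pi(toy_proteome("ACDEF"))
  expect_equal(single$pi, protein_pi("ACDEF"))

  acid <- gen_bimodal_proteome(30, frac_acidic = 1, seed = 5)
  expect_lt(mean(proteome_pi(acid)$pi), 7)
})

test_that("pi_trough finds the valley between constructed modes", {
  withr::with_seed(11, {
    x <- c(rnorm(1000, 5, 0.5), rnorm(1000, 10, 0.5))
  })
  tr <- pi_trough(x)
  expect_false(tr$unimodal)
  expect_gt(tr$breakpoint, 6.5)
  expect_lt(tr$breakpoint, 8.5)

  # unimodal: fallback with flag
  withr::with_seed(12, u <- rnorm(500, 6, 0.5))
  tu <- pi_trough(u)
  expect_true(tu$unimodal)
  expect_equal(tu$breakpoint, 7)

  # symmetric mixture: trough within 0.25 of the midpoint
  withr::with_seed(13, {
    sym <- c(rnorm(2000, 7 - 2, 0.5), rnorm(2000, 7 + 2, 0.5))
  })
  expect_equal(pi_trough(sym)$breakpoint, 7, tolerance = 0.25 / 7)

  # tiny samples fall back
  expect_true(pi_trough(c(5, 9))$unimodal)
  expect_error(pi_trough(numeric()), "No pI")
})

test_that("pi_bias follows the sign convention and is antisymmetric", {
  expect_equal(pi_bias(c(8, 9, 10), 7)$pi_bias, 1)
  expect_equal(pi_bias(c(5, 6, 8, 9), 7)$pi_bias, 0)
  b <- pi_bias(c(rep(5, 30), rep(9, 70)), 7)
  expect_equal(b$pi_bias, 0.4)
  expect_equal(b$n_acidic, 30)
  expect_equal(b$n_basic, 70)
  # ties count as acidic
  expect_equal(pi_bias(c(7, 9), 7)$pi_bias, 0)

  # antisymmetry: reflecting pIs about the breakpoint flips the sign
  withr::with_seed(3, x <- runif(200, 3, 11))
  bp <- 6.8
  expect_equal(pi_bias(2 * bp - x, bp)$pi_bias,
               -pi_bias(x, bp)$pi_bias)
})

test_that("proteome_traits assembles a coherent per-genome row", {
  p <- dplyr::bind_rows(
    gen_bimodal_proteome(150, 0.7, seed = 1, genome_id = "acid_shifted"),
    gen_bimodal_proteome(150, 0.3, seed = 2, genome_id = "base_shifted")
  )
  tt <- proteome_traits(p)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$n_acidic + tt$n_basic, tt$n_proteins)
  expect_equal(tt$ogt_ivywrel, 937 * tt$f_ivywrel - 335)
  a <- tt[tt$genome_id == "acid_shifted", ]
  b <- tt[tt$genome_id == "base_shifted", ]
  expect_lt(a$pi_bias, b$pi_bias)
  expect_lt(a$average_pi, b$average_pi)
})
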
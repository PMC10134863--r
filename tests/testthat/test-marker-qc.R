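hits_tbl <- function(genome_id, markers, counts = 1L) {
  tibble::tibble(genome_id = genome_id, marker_id = markers,
                 count = as.integer(counts))
}

test_that("scg_occurrence counts present markers and total copies", {
  set <- marker_set("scg48", sprintf("S%02d", 1:48))
  all48 <- hits_tbl("g1", marker_ids(set))
  occ <- scg_occurrence(all48, set)
  expect_equal(occ$n_present, 48)
  expect_equal(occ$n_copies, 48)

  none <- scg_occurrence(hits_tbl("g2", "S01", 0L), set)
  expect_equal(none$n_present, 0)
  expect_equal(none$n_copies, 0)

  # 24 present, 3 duplicated -> (24, 27)
  h <- hits_tbl("g3", sprintf("S%02d", 1:24), c(rep(2L, 3), rep(1L, 21)))
  occ3 <- scg_occurrence(h, set)
  expect_equal(occ3$n_present, 24)
  expect_equal(occ3$n_copies, 27)

  expect_error(completeness(all48, "absent_genome", set), "absent_genome")
})

test_that("derive_exclusion keeps only genus-universal absences", {
  set <- marker_set("m", c("A", "B", "C", "D"))
  gmap <- tibble::tibble(genome_id = c("g1", "g2", "g3"), genus = "G")
  # marker D absent everywhere; C absent in 2 of 3 genomes
  h <- dplyr::bind_rows(
    hits_tbl("g1", c("A", "B", "C")),
    hits_tbl("g2", c("A", "B")),
    hits_tbl("g3", c("A", "B"))
  )
  ex <- derive_exclusion(h, set, gmap)
  expect_equal(ex$G, "D")

  expect_error(
    derive_exclusion(h, set, gmap[1:2, ]),
    "g3"
  )
})

test_that("the shipped exclusion lists reproduce the published cardinalities", {
  ex <- read_exclusions(reveco_extdata("parvarchaeales_exclusions.txt"))
  expect_equal(length(ex$shared), 9)
  expect_equal(length(ex$Jingweiarchaeum), 9)
  expect_equal(length(ex$Haiyanarchaeum), 21)
  expect_equal(length(ex$Rehaiarchaeum), 29)
  expect_equal(length(ex$Acidifodinimicrobium), 24)
  expect_equal(length(ex$Parvarchaeum), 17)
  # the shared list is contained in every per-genus list
  for (g in setdiff(names(ex), "shared")) {
    expect_true(all(ex$shared %in% ex[[g]]), info = g)
  }
})

test_that("derive_exclusion on a constructed table returns the printed Parvarchaeum list", {
  ex <- read_exclusions(reveco_extdata("parvarchaeales_exclusions.txt"))
  set <- read_marker_set(reveco_extdata("markers_archaea149_synthetic.txt"))
  present <- setdiff(marker_ids(set), ex$Parvarchaeum)
  partial <- withr::with_seed(21, sample(present, length(present) - 5))
  h <- dplyr::bind_rows(
    hits_tbl("pv1", present),
    hits_tbl("pv2", partial) # some additional, non-universal absences
  )
  gmap <- tibble::tibble(genome_id = c("pv1", "pv2"),
                         genus = "Parvarchaeum")
  derived <- derive_exclusion(h, set, gmap)
  expect_setequal(derived$Parvarchaeum, ex$Parvarchaeum)
})

test_that("adjusted_set performs exact set arithmetic", {
  set <- read_marker_set(reveco_extdata("markers_archaea149_synthetic.txt"))
  expect_equal(length(marker_ids(set)), 149)
  ex <- read_exclusions(reveco_extdata("parvarchaeales_exclusions.txt"))
  adj <- adjusted_set(set, ex$Parvarchaeum)
  expect_equal(length(marker_ids(adj)), 132) # 149 - 17
  expect_identical(
    marker_ids(adj),
    marker_ids(set)[!marker_ids(set) %in% ex$Parvarchaeum]
  )
  expect_identical(marker_ids(adjusted_set(set, character())),
                   marker_ids(set))
  expect_error(adjusted_set(set, marker_ids(set)), "empty")
  expect_error(adjusted_set(set, "NOT_A_MARKER"), "NOT_A_MARKER")
})

test_that("completeness and contamination follow the marker formulas", {
  set140 <- marker_set("m", sprintf("M%03d", 1:140))
  full <- hits_tbl("g", marker_ids(set140))
  expect_equal(completeness(full, "g", set140), 100)
  expect_equal(contamination(full, "g", set140), 0)

  half <- hits_tbl("g", marker_ids(set140)[1:70])
  expect_equal(completeness(half, "g", set140), 50)

  set100 <- marker_set("m", sprintf("M%03d", 1:100))
  dup1 <- hits_tbl("g", marker_ids(set100), c(2L, rep(1L, 99)))
  expect_equal(contamination(dup1, "g", set100), 1)

  # 5 markers at 3 copies on 149 markers -> 100*10/149
  set149 <- marker_set("m", sprintf("M%03d", 1:149))
  tri <- hits_tbl("g", marker_ids(set149)[1:5], 3L)
  expect_equal(contamination(tri, "g", set149), 100 * 10 / 149,
               tolerance = 1e-12)

  # generator truth: completeness 0.9 on 149 markers -> 100*134/149
  t9 <- gen_marker_table("g", set149, completeness = 0.9, seed = 3)
  expect_equal(completeness(t9, "g", set149), 100 * 134 / 149,
               tolerance = 1e-12)
})

test_that("excluding genus-universal absences raises completeness to 100%", {
  set <- marker_set("m", sprintf("M%03d", 1:50))
  missing <- sprintf("M%03d", 41:50)
  h <- hits_tbl("g1", setdiff(marker_ids(set), missing))
  gmap <- tibble::tibble(genome_id = "g1", genus = "G")
  ex <- derive_exclusion(h, set, gmap)
  expect_setequal(ex$G, missing)
  adj <- adjusted_set(set, ex$G)
  expect_equal(completeness(h, "g1", adj), 100)
  # monotonicity: exclusion of absent markers never lowers completeness
  for (seed in 1:10) {
    t <- gen_marker_table("g", set, completeness = runif(1, 0.3, 1),
                          seed = seed)
    absent <- setdiff(marker_ids(set), t$marker_id)
    if (length(absent) == 0 || length(absent) == 50) next
    expect_gte(completeness(t, "g", adjusted_set(set, absent)),
               completeness(t, "g", set))
  }
})

test_that("quality_report applies per-genus sets and quality_tier applies the thresholds", {
  set <- marker_set("m", sprintf("M%03d", 1:100))
  h <- dplyr::bind_rows(
    hits_tbl("g1", marker_ids(set)[1:90]),
    hits_tbl("g2", marker_ids(set)[1:90])
  )
  gmap <- tibble::tibble(genome_id = c("g1", "g2"), genus = c("A", "B"))
  ex <- list(A = sprintf("M%03d", 91:100)) # genus B keeps the full set
  qr <- quality_report(h, set, exclusions = ex, genus_map = gmap)
  expect_equal(qr$completeness[qr$genome_id == "g1"], 100)
  expect_equal(qr$completeness[qr$genome_id == "g2"], 90)
  expect_equal(qr$n_expected, c(90, 100))

  expect_equal(quality_tier(95, 1, TRUE, 20), "high")
  expect_equal(quality_tier(60, 2, FALSE, 10), "medium")
  expect_equal(quality_tier(40, 2, FALSE, 10), "low")
  # completeness alone is not enough for high
  expect_equal(quality_tier(95, 1, FALSE, 20), "medium")
  expect_equal(quality_tier(95, 6, TRUE, 20), "low")
})
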
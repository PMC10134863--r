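#' Residue frequencies of a proteome
#'
#' Counts canonical residues pooled over all proteins of each genome.
#' Ambiguous residues (B, J, O, U, X, Z) and stops are excluded from both
#' numerator and denominator, so frequencies always sum to 1 over the
#' counted residues.
#'
#' @param proteome Proteome tibble (`genome_id`, `protein_id`, `sequence`).
#' @return Tibble `genome_id`, `residue`, `count`, `freq`; one row per
#'   canonical residue (zero-count residues included), frequencies summing
#'   to 1 within each genome.
#' @examples
#' p <- tibble::tibble(genome_id = "g", protein_id = "p1", sequence = "GAXG")
#' residue_frequencies(p)
#' @export
residue_frequencies <- function(proteome) {
  assert_proteome(proteome)
  counts <- proteome |>
    group_by(.data$genome_id) |>
    summarise(pooled = paste(sanitize_seq(.data$sequence), collapse = ""),
              .groups = "drop")
  if (any(nchar(counts$pooled) == 0)) {
    abort("A proteome contains zero canonical residues.")
  }
  tab <- purrr::map2(counts$genome_id, counts$pooled, function(g, s) {
    res <- strsplit(s, "")[[1]]
    n <- unname(vapply(AA20, function(a) sum(res == a), numeric(1)))
    tibble(genome_id = g, residue = AA20, count = as.integer(n),
           freq = n / sum(n))
  })
  bind_rows(tab)
}

#' IVYWREL fraction of a proteome
#'
#' Summed frequency of Ile, Val, Tyr, Trp, Arg, Glu and Leu — the
#' seven-residue composition statistic whose overrepresentation correlates
#' positively with optimal growth temperature across prokaryotes.
#'
#' @inheritParams residue_frequencies
#' @return Tibble `genome_id`, `f_ivywrel`.
#' @examples
#' p <- gen_proteome(20, c(100, 100), seed = 1)
#' ivywrel_fraction(p)
#' @export
ivywrel_fraction <- function(proteome) {
  group_fraction(proteome, c("I", "V", "Y", "W", "R", "E", "L")) |>
    rename(f_ivywrel = "fraction")
}

#' Summed frequency of a residue group
#'
#' @inheritParams residue_frequencies
#' @param residues Character vector of canonical residues, e.g.
#'   `c("R", "E")` for the thermostability-linked Arg+Glu fraction or
#'   `"P"` for proline.
#' @return Tibble `genome_id`, `fraction`.
#' @export
group_fraction <- function(proteome, residues) {
  if (length(residues) == 0) abort("`residues` must be non-empty.")
  if (!all(residues %in% AA20)) {
    abort("`residues` must be canonical one-letter codes.")
  }
  residue_frequencies(proteome) |>
    group_by(.data$genome_id) |>
    summarise(
      fraction = sum(.data$freq[.data$residue %in% residues]),
      .groups = "drop"
    )
}

#' Optimal growth temperature from the IVYWREL fraction
#'
#' Affine map OGT = slope * F + intercept. The default coefficients are
#' the published proteome-wide IVYWREL regression against OGT
#' (slope 937, intercept -335); both are exposed because recalibrations
#' of the estimator differ slightly.
#'
#' @param f IVYWREL fraction(s) in \[0, 1\].
#' @param slope,intercept Regression coefficients (°C per unit fraction,
#'   °C).
#' @return OGT estimate(s) in °C.
#' @examples
#' ogt_from_ivywrel(0.443) # hyperthermophile regime
#' @export
ogt_from_ivywrel <- function(f, slope = 937, intercept = -335) {
  if (any(f < 0 | f > 1)) abort("IVYWREL fraction must lie in [0, 1].")
  slope * f + intercept
}

#' Per-protein isoelectric points of a proteome
#'
#' Applies the bisection solver [protein_pi()] to every protein. Proteins
#' whose sanitized sequence has no ionizable group get `NA` and are
#' reported with a warning.
#'
#' @inheritParams residue_frequencies
#' @param pka pKa set (see [get_pka()]).
#' @param tol Charge tolerance passed to [protein_pi()].
#' @return Tibble `genome_id`, `protein_id`, `pi` (`NA` when undefined).
#' @export
proteome_pi <- function(proteome, pka = get_pka("ipc"), tol = 1e-4) {
  assert_proteome(proteome)
  pka <- get_pka(pka)
  pis <- vapply(proteome$sequence, function(s) {
    counts <- ionizable_counts(sanitize_seq(s), pka)
    if (sum(counts) == 0) {
      return(NA_real_)
    }
    pi_from_counts(counts, pka, tol)
  }, numeric(1), USE.NAMES = FALSE)
  n_undef <- sum(is.na(pis))
  if (n_undef > 0) {
    warn(paste0(n_undef, " protein(s) have no ionizable group; ",
                "pI set to NA."))
  }
  tibble(genome_id = proteome$genome_id,
         protein_id = proteome$protein_id,
         pi = pis)
}

#' Trough of a proteome pI distribution
#'
#' Proteome pI distributions are typically bimodal, with an acidic and a
#' basic mode and a valley ("trough") near neutral pH. The trough is the
#' breakpoint that partitions proteins into acidic and basic classes for
#' the pI-bias statistic.
#'
#' A Gaussian kernel density (Silverman's rule by default) is evaluated on
#' a fixed grid over \[0, 14\]; the breakpoint is the grid location of the
#' minimum density between the two highest local maxima, restricted to
#' `search_window`. If the density is unimodal, or fewer than `min_n`
#' values are supplied, the fixed fallback breakpoint (7.0) is returned and
#' flagged.
#'
#' @param pi_values Numeric vector of pI values.
#' @param bandwidth Bandwidth rule or value for [stats::density()]
#'   (default `"nrd0"`, Silverman).
#' @param grid_step Grid resolution in pH units. Default 0.01.
#' @param search_window Numeric pair; the breakpoint is searched inside
#'   this pH interval. Default `c(4, 10)`.
#' @param fallback Breakpoint returned when no trough is found. Default 7.
#' @param min_n Minimum sample size for density-based detection.
#' @return List with `breakpoint` (numeric) and `unimodal` (logical flag;
#'   `TRUE` when the fallback was used).
#' @examples
#' x <- c(rnorm(300, 5, 0.4), rnorm(300, 10, 0.4))
#' pi_trough(x)$breakpoint
#' @export
pi_trough <- function(pi_values, bandwidth = "nrd0", grid_step = 0.01,
                      search_window = c(4, 10), fallback = 7,
                      min_n = 10L) {
  pi_values <- pi_values[!is.na(pi_values)]
  if (length(pi_values) == 0) abort("No pI values supplied.")
  if (length(pi_values) < min_n) {
    return(list(breakpoint = fallback, unimodal = TRUE))
  }
  grid <- seq(0, 14, by = grid_step)
  dens <- density(pi_values, bw = bandwidth, from = 0, to = 14,
                  n = length(grid))
  d <- dens$y
  # interior local maxima of the KDE, ignoring negligible tail wiggles
  # (< 5% of the peak) that are numerical artefacts of the fixed grid
  is_max <- which(diff(sign(diff(d))) < 0) + 1L
  is_max <- is_max[d[is_max] >= 0.05 * max(d)]
  if (length(is_max) < 2) {
    return(list(breakpoint = fallback, unimodal = TRUE))
  }
  top2 <- sort(is_max[order(d[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  in_window <- between[grid[between] >= search_window[1] &
                         grid[between] <= search_window[2]]
  if (length(in_window) == 0) {
    return(list(breakpoint = fallback, unimodal = TRUE))
  }
  list(breakpoint = grid[in_window[which.min(d[in_window])]],
       unimodal = FALSE)
}

#' pI bias of a proteome
#'
#' Signed imbalance between basic and acidic proteins, partitioned at the
#' trough breakpoint: `(n_basic - n_acidic) / (n_basic + n_acidic)`.
#' Positive values mean basic proteins outnumber acidic ones (a
#' circumneutral-or-basic intracellular milieu); values near -1 indicate
#' the acid-shifted proteomes typical of halophiles. Ties at the
#' breakpoint count as acidic, making the partition deterministic.
#'
#' @param pi_values Numeric vector of pI values (`NA` dropped).
#' @param breakpoint Partition point in (0, 14), usually from
#'   [pi_trough()].
#' @return List with `pi_bias`, `n_acidic`, `n_basic`.
#' @examples
#' pi_bias(c(4, 5, 9, 9, 10), breakpoint = 7)
#' @export
pi_bias <- function(pi_values, breakpoint) {
  stopifnot(breakpoint > 0, breakpoint < 14)
  pi_values <- pi_values[!is.na(pi_values)]
  if (length(pi_values) == 0) abort("No pI values supplied.")
  n_acidic <- sum(pi_values <= breakpoint)
  n_basic <- sum(pi_values > breakpoint)
  list(
    pi_bias = (n_basic - n_acidic) / (n_basic + n_acidic),
    n_acidic = n_acidic,
    n_basic = n_basic
  )
}

#' Per-genome proteome trait table
#'
#' One-stop computation of every composition trait used by the
#' reverse-ecology analysis: IVYWREL fraction and the derived OGT
#' estimate, Arg+Glu and proline fractions, per-protein pI summary
#' (average pI, trough breakpoint, pI bias, acidic/basic counts).
#'
#' @inheritParams proteome_pi
#' @param ogt_slope,ogt_intercept Coefficients for [ogt_from_ivywrel()].
#' @param trough_args Optional list of arguments passed to [pi_trough()].
#' @return Tibble with one row per genome and columns `genome_id`,
#'   `n_proteins`, `f_ivywrel`, `ogt_ivywrel` (°C), `f_re`, `f_p`,
#'   `average_pi`, `breakpoint`, `trough_unimodal`, `pi_bias`, `n_acidic`,
#'   `n_basic`.
#' @examples
#' gen_bimodal_proteome(60, 0.5, seed = 1) |> proteome_traits()
#' @export
proteome_traits <- function(proteome, pka = get_pka("ipc"),
                            ogt_slope = 937, ogt_intercept = -335,
                            trough_args = list()) {
  assert_proteome(proteome)
  comp <- ivywrel_fraction(proteome) |>
    left_join(rename(group_fraction(proteome, c("R", "E")), f_re = "fraction"),
              by = "genome_id") |>
    left_join(rename(group_fraction(proteome, "P"), f_p = "fraction"),
              by = "genome_id") |>
    mutate(ogt_ivywrel = ogt_from_ivywrel(.data$f_ivywrel,
                                          ogt_slope, ogt_intercept))
  pis <- proteome_pi(proteome, pka)
  prof <- pis |>
    group_by(.data$genome_id) |>
    summarise(
      n_proteins = n(),
      profile = list({
        v <- .data$pi[!is.na(.data$pi)]
        if (length(v) == 0) abort("Zero defined pIs in a proteome.")
        tr <- do.call(pi_trough, c(list(v), trough_args))
        pb <- pi_bias(v, tr$breakpoint)
        tibble(average_pi = mean(v), breakpoint = tr$breakpoint,
               trough_unimodal = tr$unimodal, pi_bias = pb$pi_bias,
               n_acidic = pb$n_acidic, n_basic = pb$n_basic)
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest("profile")
  comp |>
    left_join(prof, by = "genome_id") |>
    select("genome_id", "n_proteins", "f_ivywrel", "ogt_ivywrel",
           "f_re", "f_p", "average_pi", "breakpoint", "trough_unimodal",
           "pi_bias", "n_acidic", "n_basic")
}
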
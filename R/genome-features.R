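#' Genome size and GC content
#'
#' @param contigs Contig sequences: a character vector or a
#'   [Biostrings::DNAStringSet]. Ambiguous bases count toward size but are
#'   excluded from the GC denominator.
#' @return One-row tibble `genome_size` (bp), `gc` (fraction of unambiguous
#'   bases).
#' @examples
#' genome_size_gc(c("ATGC", "GGNN"))
#' @export
genome_size_gc <- function(contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (length(contigs) == 0) abort("No contigs supplied.")
  freq <- colSums(Biostrings::alphabetFrequency(contigs))
  acgt <- freq[c("A", "C", "G", "T")]
  tibble(
    genome_size = sum(Biostrings::width(contigs)),
    gc = sum(acgt[c("G", "C")]) / sum(acgt)
  )
}

#' Coding density of an annotated genome
#'
#' Fraction of genome positions covered by at least one CDS. Intervals from
#' both strands are merged before taking the union, since coverage is a
#' per-base property; abutting or overlapping genes therefore never count
#' a base twice.
#'
#' @param ann Annotation tibble `seq_id`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @param genome_size Total genome length in bp; must be at least
#'   `max(ann$end)`.
#' @return Coding density in \[0, 1\].
#' @examples
#' ann <- tibble::tibble(seq_id = "c", start = c(1, 51), end = c(100, 150),
#'                       strand = "+")
#' coding_density(ann, 1000) # union 150 bp -> 0.15
#' @export
coding_density <- function(ann, genome_size) {
  assert_annotations(ann)
  if (genome_size < max(ann$end)) {
    abort("An interval extends beyond `genome_size`.")
  }
  covered <- sum(
    vapply(split(ann, ann$seq_id), function(a) {
      r <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
      sum(IRanges::width(r))
    }, numeric(1))
  )
  covered / genome_size
}

#' Overlapping-gene ratio
#'
#' Fraction of genes sharing at least one base with at least one other gene
#' on the same contig, irrespective of strand. Genome compaction in
#' thermophiles shows up as high values of this ratio together with high
#' coding density.
#'
#' @inheritParams coding_density
#' @return Fraction in \[0, 1\].
#' @export
overlap_ratio <- function(ann) {
  assert_annotations(ann)
  n_overlapping <- sum(
    vapply(split(ann, ann$seq_id), function(a) {
      ir <- IRanges::IRanges(a$start, a$end)
      hits <- IRanges::findOverlaps(ir, minoverlap = 1L, drop.self = TRUE)
      length(unique(S4Vectors::queryHits(hits)))
    }, numeric(1))
  )
  n_overlapping / nrow(ann)
}

assert_annotations <- function(ann) {
  if (!is.data.frame(ann) ||
      !all(c("seq_id", "start", "end") %in% names(ann))) {
    abort("`ann` must have columns seq_id, start, end (and optionally strand).")
  }
  if (nrow(ann) == 0) abort("Annotation table is empty.")
  if (any(ann$start < 1) || any(ann$end < ann$start)) {
    abort("Coordinates must be 1-based with start <= end.")
  }
  invisible(ann)
}

#' Combined feature row for one genome
#'
#' @inheritParams genome_size_gc
#' @inheritParams coding_density
#' @param genome_id Identifier stored in the output.
#' @return One-row tibble `genome_id`, `genome_size`, `gc`, `n_cds`,
#'   `coding_density`, `overlap_ratio`.
#' @export
genome_features <- function(contigs, ann, genome_id = "genome") {
  sz <- genome_size_gc(contigs)
  tibble(
    genome_id = genome_id,
    genome_size = sz$genome_size,
    gc = sz$gc,
    n_cds = nrow(ann),
    coding_density = coding_density(ann, sz$genome_size),
    overlap_ratio = overlap_ratio(ann)
  )
}

#' Regression of CDS count on genome size
#'
#' Ordinary least squares of the number of protein-coding genes on genome
#' size across genomes — the streamlining diagnostic: in reduced genomes
#' size differences are explained almost entirely by gene count.
#'
#' @param features Tibble with columns `genome_size` and `n_cds`
#'   (one row per genome, >= 3 rows).
#' @return An object of class `size_cds_fit`: list with `slope` (CDS per
#'   bp), `intercept`, `adj_r_squared`, `p_value` (slope t-test), `n`, and
#'   the underlying `lm` fit. Supports [tidy()] and [glance()].
#' @examples
#' f <- tibble::tibble(genome_size = c(1, 2, 3), n_cds = c(1, 2, 4))
#' size_cds_regression(f)$slope
#' @export
size_cds_regression <- function(features) {
  stopifnot(all(c("genome_size", "n_cds") %in% names(features)))
  if (nrow(features) < 3) abort("Need at least 3 genomes.")
  if (var(features$genome_size) == 0) {
    abort("Genome size is constant; regression undefined.")
  }
  fit <- lm(n_cds ~ genome_size, data = features)
  s <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      adj_r_squared = s$adj.r.squared,
      p_value = unname(s$coefficients[2, 4]),
      n = nrow(features),
      fit = fit
    ),
    class = "size_cds_fit"
  )
}

#' @export
print.size_cds_fit <- function(x, ...) {
  cat("<size_cds_fit> n =", x$n, "\n")
  cat(sprintf("  n_cds = %.4g + %.4g * genome_size\n", x$intercept, x$slope))
  cat(sprintf("  adjusted R^2 = %.4f, slope P = %.4g\n",
              x$adj_r_squared, x$p_value))
  invisible(x)
}

#' @export
tidy.size_cds_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @export
glance.size_cds_fit <- function(x, ...) {
  tibble(adj_r_squared = x$adj_r_squared, p_value = x$p_value, n = x$n)
}
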
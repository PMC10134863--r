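#' Generate a marker hit table with set completeness and contamination
#'
#' For each genome, `round(completeness * |set|)` distinct markers are
#' present with one copy, and `round(contamination * |set|)` of the present
#' markers are raised to two copies. This is the exact ground truth the
#' completeness/contamination formulas of the QC stage should recover.
#'
#' @param genome_ids Character vector of genome identifiers.
#' @param marker_set A marker set (see [marker_set()]) or a character
#'   vector of marker ids.
#' @param completeness Fraction of markers present, in \[0, 1\].
#' @param contamination Fraction of the marker set duplicated, >= 0 (capped
#'   at the number of present markers).
#' @param seed Integer seed; which markers are present/duplicated is
#'   randomized per genome.
#' @return Long tibble `genome_id`, `marker_id`, `count` (zero-count rows
#'   omitted).
#' @examples
#' gen_marker_table("g1", paste0("M", 1:10), completeness = 0.5,
#'                  contamination = 0.1, seed = 1)
#' @export
gen_marker_table <- function(genome_ids, marker_set, completeness = 1,
                             contamination = 0, seed = 1L) {
  ids <- marker_ids(marker_set)
  if (length(ids) == 0) abort("Marker set is empty.")
  stopifnot(completeness >= 0, completeness <= 1, contamination >= 0)
  n_present <- round(completeness * length(ids))
  n_dup <- min(round(contamination * length(ids)), n_present)
  withr::with_seed(seed, {
    rows <- purrr::map(genome_ids, function(g) {
      present <- sample(ids, n_present)
      dup <- if (n_dup > 0) sample(present, n_dup) else character()
      tibble(
        genome_id = g,
        marker_id = present,
        count = ifelse(present %in% dup, 2L, 1L)
      )
    })
  })
  arrange(bind_rows(rows), .data$genome_id, .data$marker_id)
}

#' Generate a gene-coordinate table with a set overlapping-gene fraction
#'
#' Places `n_genes` intervals on a single contig so that exactly
#' `round(n_genes * overlap_fraction)` genes share at least one base with
#' another gene. Overlapping genes are laid out in clusters of two (plus one
#' cluster of three when the target count is odd); all remaining genes are
#' pairwise disjoint. Coordinates are 1-based inclusive, GFF-style.
#'
#' @param genome_length Contig length in bp.
#' @param n_genes Number of genes.
#' @param overlap_fraction Target fraction of overlapping genes in \[0, 1\].
#' @param gene_length Length of every gene (bp). Default 90.
#' @param seed Integer seed (randomizes strands and gene order).
#' @return Annotation tibble `seq_id`, `start`, `end`, `strand`.
#' @examples
#' ann <- gen_annotations(10000, 20, overlap_fraction = 0.5, seed = 1)
#' overlap_ratio(ann)
#' @export
gen_annotations <- function(genome_length, n_genes, overlap_fraction = 0,
                            gene_length = 90L, seed = 1L) {
  stopifnot(n_genes >= 1, overlap_fraction >= 0, overlap_fraction <= 1,
            gene_length >= 2)
  n_ov <- round(n_genes * overlap_fraction)
  if (n_ov == 1) n_ov <- 2 # a single gene cannot overlap anything
  # clusters of overlapping genes: pairs, plus one triple if n_ov is odd
  sizes <- if (n_ov == 0) integer() else if (n_ov %% 2 == 0) {
    rep(2L, n_ov / 2)
  } else {
    c(rep(2L, (n_ov - 3) / 2), 3L)
  }
  sizes <- c(sizes, rep(1L, n_genes - n_ov))
  shift <- floor(gene_length / 2) # overlap by half a gene within a cluster
  cluster_span <- function(k) gene_length + (k - 1) * shift
  needed <- sum(vapply(sizes, cluster_span, numeric(1))) + length(sizes) - 1
  if (needed > genome_length) {
    abort(sprintf(
      "Infeasible packing: %d bp needed but genome_length is %d.",
      needed, genome_length
    ))
  }
  # distribute the slack as inter-cluster gaps (>= 1 bp, so clusters stay
  # disjoint and singletons never overlap anything)
  withr::with_seed(seed, {
    gaps <- rep(1L, length(sizes))
    slack <- genome_length - needed
    if (slack > 0 && length(sizes) > 1) {
      idx <- seq_along(sizes)[-1]
      picks <- idx[sample.int(length(idx), slack, replace = TRUE)]
      extra <- table(picks)
      gaps[as.integer(names(extra))] <-
        gaps[as.integer(names(extra))] + as.integer(extra)
    }
    gaps[1] <- gaps[1] - 1L # first cluster may start at base 1
    order_sizes <- sample(seq_along(sizes))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  sizes <- sizes[order_sizes]
  rows <- list()
  pos <- 1L
  gi <- 0L
  for (ci in seq_along(sizes)) {
    pos <- pos + gaps[ci]
    for (j in seq_len(sizes[ci])) {
      gi <- gi + 1L
      start <- pos + (j - 1L) * shift
      rows[[gi]] <- tibble(
        seq_id = "contig_1",
        start = start,
        end = start + gene_length - 1L,
        strand = strands[gi]
      )
    }
    pos <- pos + cluster_span(sizes[ci])
  }
  bind_rows(rows)
}
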
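#' Alignment scoring configuration for AAI
#'
#' Reciprocal-best-hit orthology here uses Smith-Waterman local alignment
#' under BLOSUM62 with affine gaps. BLAST-style E-value screening is
#' replaced by a raw-score plus coverage filter: a hit is accepted when its
#' alignment score is at least `min_score` and the alignment spans at least
#' `min_coverage` of the shorter of the two sequences. Identity is
#' matches / alignment columns, gap columns included in the denominator.
#'
#' @param min_score Minimum local alignment score. Default 50.
#' @param min_coverage Minimum coverage of the shorter sequence. Default
#'   0.5.
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @return A list of scoring settings consumed by the `aai_*` functions.
#' @export
aai_filters <- function(min_score = 50, min_coverage = 0.5,
                        gap_opening = 11, gap_extension = 1) {
  list(min_score = min_score, min_coverage = min_coverage,
       gap_opening = gap_opening, gap_extension = gap_extension)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Align two protein sequences
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) of one sequence
#' pair, reporting the statistics used for reciprocal-best-hit filtering.
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings).
#' @param filters Scoring settings from [aai_filters()].
#' @return One-row tibble `score`, `identity` (matches / alignment columns,
#'   gaps included), `query_coverage`, `subject_coverage` (aligned span
#'   over full sequence length).
#' @examples
#' align_pair("MKLV", "MKIV")
#' @export
align_pair <- function(seq_a, seq_b, filters = aai_filters()) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("Cannot align an empty sequence.")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = filters$gap_opening, gapExtension = filters$gap_extension
  )
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  tibble(
    score = Biostrings::score(aln),
    identity = Biostrings::pid(aln, type = "PID1") / 100,
    query_coverage =
      (Biostrings::end(p) - Biostrings::start(p) + 1) / nchar(seq_a),
    subject_coverage =
      (Biostrings::end(s) - Biostrings::start(s) + 1) / nchar(seq_b)
  )
}

# Coverage of the shorter sequence, from an align_pair() row.
shorter_coverage <- function(hit, len_a, len_b) {
  if (len_a <= len_b) hit$query_coverage else hit$subject_coverage
}

#' Best hit of each query protein in a subject proteome
#'
#' Scores every query against every subject (score-only local alignment),
#' then confirms candidates in descending score order with a full
#' alignment until one passes the coverage filter. Score ties are broken
#' by the lexicographically smallest subject id. Queries with no passing
#' hit are absent from the result.
#'
#' @param proteome_a,proteome_b Proteome tibbles (queries resp. subjects).
#' @inheritParams align_pair
#' @return Tibble `query_id`, `subject_id`, `score`, `identity`.
#' @export
best_hits <- function(proteome_a, proteome_b, filters = aai_filters()) {
  assert_proteome(proteome_a, "proteome_a")
  assert_proteome(proteome_b, "proteome_b")
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) {
    abort("Both proteomes must be non-empty.")
  }
  subj_set <- Biostrings::AAStringSet(
    setNames(proteome_b$sequence, proteome_b$protein_id)
  )
  rows <- purrr::map(seq_len(nrow(proteome_a)), function(i) {
    qseq <- proteome_a$sequence[i]
    scores <- Biostrings::pairwiseAlignment(
      subj_set, Biostrings::AAString(qseq),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = filters$gap_opening,
      gapExtension = filters$gap_extension, scoreOnly = TRUE
    )
    ord <- order(-scores, proteome_b$protein_id)
    for (j in ord) {
      if (scores[j] < filters$min_score) break
      hit <- align_pair(qseq, proteome_b$sequence[j], filters)
      cov <- shorter_coverage(hit, nchar(qseq),
                              nchar(proteome_b$sequence[j]))
      if (cov >= filters$min_coverage) {
        return(tibble(query_id = proteome_a$protein_id[i],
                      subject_id = proteome_b$protein_id[j],
                      score = hit$score, identity = hit$identity))
      }
    }
    NULL
  })
  bind_rows(rows)
}

#' Reciprocal best hits between two proteomes
#'
#' Operational orthologs: protein pairs (x, y) where y is x's best hit in
#' the forward direction and x is y's best hit in the reverse direction.
#'
#' @inheritParams best_hits
#' @return Tibble `protein_a`, `protein_b`, `identity` (from the forward
#'   alignment).
#' @export
rbbh <- function(proteome_a, proteome_b, filters = aai_filters()) {
  fwd <- best_hits(proteome_a, proteome_b, filters)
  rev <- best_hits(proteome_b, proteome_a, filters)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(tibble(protein_a = character(), protein_b = character(),
                  identity = numeric()))
  }
  fwd |>
    dplyr::inner_join(rev, by = c(query_id = "subject_id",
                                  subject_id = "query_id"),
                      suffix = c("", "_rev")) |>
    dplyr::transmute(protein_a = .data$query_id,
                     protein_b = .data$subject_id,
                     identity = .data$identity)
}

#' Average amino-acid identity of a proteome pair
#'
#' AAI = 100 * mean alignment identity over reciprocal best hits.
#'
#' @inheritParams best_hits
#' @return One-row tibble `genome_a`, `genome_b`, `aai` (%), `n_orthologs`.
#'   When no reciprocal pair passes the filters, `aai` is `NA` with a
#'   warning.
#' @examples
#' p <- gen_proteome(15, c(60, 60), seed = 1, genome_id = "g1")
#' d <- gen_diverged_pair(p, 0.1, seed = 2, genome_id = "g2")
#' aai_pair(d$a, d$b)
#' @export
aai_pair <- function(proteome_a, proteome_b, filters = aai_filters()) {
  pairs <- rbbh(proteome_a, proteome_b, filters)
  ga <- proteome_a$genome_id[1]
  gb <- proteome_b$genome_id[1]
  if (nrow(pairs) == 0) {
    warn(paste0("No reciprocal best hits between ", ga, " and ", gb,
                "; AAI undefined."))
    return(tibble(genome_a = ga, genome_b = gb, aai = NA_real_,
                  n_orthologs = 0L))
  }
  tibble(genome_a = ga, genome_b = gb,
         aai = 100 * mean(pairs$identity),
         n_orthologs = nrow(pairs))
}

#' All-vs-all AAI matrix
#'
#' @param proteomes Either one proteome tibble with several `genome_id`
#'   values or a list of proteome tibbles. Genome ids must be unique.
#' @inheritParams best_hits
#' @return List with `pairs` (long tibble from [aai_pair()], each
#'   unordered pair computed once) and `matrix` (symmetric numeric matrix,
#'   diagonal 100).
#' @export
aai_matrix <- function(proteomes, filters = aai_filters()) {
  if (is.data.frame(proteomes)) {
    proteomes <- split(proteomes, proteomes$genome_id)
  }
  ids <- vapply(proteomes, function(p) p$genome_id[1], character(1))
  if (anyDuplicated(ids)) abort("Duplicate genome ids.")
  if (length(ids) < 2) abort("Need at least 2 proteomes.")
  names(proteomes) <- ids
  combos <- utils::combn(ids, 2, simplify = FALSE)
  pairs <- bind_rows(lapply(combos, function(ab) {
    aai_pair(proteomes[[ab[1]]], proteomes[[ab[2]]], filters)
  }))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(m) <- 100
  for (k in seq_len(nrow(pairs))) {
    m[pairs$genome_a[k], pairs$genome_b[k]] <- pairs$aai[k]
    m[pairs$genome_b[k], pairs$genome_a[k]] <- pairs$aai[k]
  }
  list(pairs = pairs, matrix = m)
}
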
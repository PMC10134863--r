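#' Marker sets
#'
#' A marker set is an ordered collection of unique single-copy-gene (SCG)
#' marker identifiers (typically Pfam/TIGRFAM accessions) against which
#' genome completeness and contamination are scored.
#'
#' `marker_set()` builds one from ids; `read_marker_set()` reads a
#' plain-text file with one id per line (`#` comments allowed). The
#' package ships `markers_archaea149_synthetic.txt`, a 149-id archaeal
#' set containing the 40 published genus-exclusion accessions plus
#' clearly-labelled synthetic filler ids — sufficient for exercising the
#' lineage-exclusion arithmetic, but not a substitute for a curated
#' marker roster.
#'
#' @param name Set name.
#' @param ids Character vector of unique marker ids.
#' @param path File with one marker id per line.
#' @return A `marker_set` object (list with `name`, `ids`).
#' @examples
#' ms <- marker_set("toy", paste0("M", 1:10))
#' length(marker_ids(ms))
#' @export
marker_set <- function(name, ids) {
  ids <- as.character(ids)
  if (length(ids) == 0) abort("A marker set must be non-empty.")
  if (anyDuplicated(ids)) abort("Marker ids must be unique.")
  structure(list(name = name, ids = ids), class = "marker_set")
}

#' @rdname marker_set
#' @export
read_marker_set <- function(path, name = basename(path)) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  marker_set(name, lines)
}

#' @rdname marker_set
#' @param x A marker set or character vector of ids.
#' @export
marker_ids <- function(x) {
  if (inherits(x, "marker_set")) x$ids else as.character(x)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", x$name, ": ", length(x$ids), " markers\n", sep = "")
  invisible(x)
}

assert_hits <- function(hits) {
  if (!is.data.frame(hits) ||
      !all(c("genome_id", "marker_id", "count") %in% names(hits))) {
    abort("`hits` must have columns genome_id, marker_id, count.")
  }
  if (any(hits$count < 0) || any(hits$count != round(hits$count))) {
    abort("Marker counts must be non-negative integers.")
  }
  invisible(hits)
}

genome_counts <- function(hits, genome_id, set) {
  assert_hits(hits)
  if (!genome_id %in% hits$genome_id) {
    abort(paste0("Genome '", genome_id, "' absent from the hit table."))
  }
  h <- hits[hits$genome_id == genome_id & hits$marker_id %in% marker_ids(set), ]
  setNames(h$count, h$marker_id)
}

#' Single-copy-marker occurrence per genome
#'
#' @param hits Marker hit tibble `genome_id`, `marker_id`, `count`.
#' @param set Marker set (or id vector) to score against.
#' @return Tibble `genome_id`, `n_present` (markers with >= 1 copy),
#'   `n_copies` (total copies over the set).
#' @export
scg_occurrence <- function(hits, set) {
  assert_hits(hits)
  ids <- marker_ids(set)
  hits |>
    filter(.data$marker_id %in% ids) |>
    group_by(.data$genome_id) |>
    summarise(
      n_present = sum(.data$count >= 1),
      n_copies = sum(.data$count),
      .groups = "drop"
    )
}

#' Derive per-genus marker exclusion lists
#'
#' The lineage-aware twist on universal-marker QC: a marker missing from
#' *every* genome of a genus is taken as a genuine lineage-level gene loss
#' rather than genome incompleteness, and is excluded from that genus's
#' expected set. Markers missing from only some members stay in.
#'
#' @inheritParams scg_occurrence
#' @param genus_map Tibble `genome_id`, `genus` covering every genome in
#'   `hits`.
#' @return Named list: genus -> character vector of excluded marker ids
#'   (ordered as in `set`).
#' @export
derive_exclusion <- function(hits, set, genus_map) {
  assert_hits(hits)
  ids <- marker_ids(set)
  stopifnot(all(c("genome_id", "genus") %in% names(genus_map)))
  genomes <- unique(hits$genome_id)
  missing_map <- setdiff(genomes, genus_map$genome_id)
  if (length(missing_map) > 0) {
    abort(paste0("No genus assigned for: ",
                 paste(missing_map, collapse = ", ")))
  }
  present <- hits |>
    filter(.data$count >= 1, .data$marker_id %in% ids) |>
    left_join(genus_map, by = "genome_id")
  genera <- sort(unique(genus_map$genus[genus_map$genome_id %in% genomes]))
  out <- lapply(genera, function(g) {
    seen <- unique(present$marker_id[present$genus == g])
    ids[!ids %in% seen]
  })
  setNames(out, genera)
}

#' Remove excluded markers from a set
#'
#' @param set Marker set.
#' @param exclusion Character vector of ids to drop; must all be members.
#' @return A new `marker_set` with the exclusion removed, original order
#'   preserved.
#' @export
adjusted_set <- function(set, exclusion) {
  ids <- marker_ids(set)
  bad <- setdiff(exclusion, ids)
  if (length(bad) > 0) {
    abort(paste0("Not in the marker set: ", paste(bad, collapse = ", ")))
  }
  kept <- ids[!ids %in% exclusion]
  if (length(kept) == 0) abort("Exclusion would empty the marker set.")
  name <- if (inherits(set, "marker_set")) set$name else "adjusted"
  marker_set(paste0(name, "_adj"), kept)
}

#' Marker-based completeness
#'
#' `100 * (#set markers with count >= 1) / |set|`.
#'
#' @inheritParams scg_occurrence
#' @param genome_id Genome to score.
#' @return Percentage in \[0, 100\].
#' @export
completeness <- function(hits, genome_id, set) {
  counts <- genome_counts(hits, genome_id, set)
  100 * sum(counts >= 1) / length(marker_ids(set))
}

#' Marker-based contamination
#'
#' Excess-copy formula: `100 * sum(max(count - 1, 0)) / |set|`. This scores
#' duplicated single-copy markers as contamination; it does not reproduce
#' CheckM's collocated-marker-set weighting.
#'
#' @inheritParams completeness
#' @return Percentage, >= 0 (can exceed 100 for grossly chimeric bins).
#' @export
contamination <- function(hits, genome_id, set) {
  counts <- genome_counts(hits, genome_id, set)
  100 * sum(pmax(counts - 1, 0)) / length(marker_ids(set))
}

#' Quality report over a marker hit table
#'
#' @inheritParams scg_occurrence
#' @param exclusions Optional named list (genus -> excluded ids), e.g. from
#'   [derive_exclusion()] or [read_exclusions()]; requires `genus_map`.
#' @param genus_map Optional tibble `genome_id`, `genus`.
#' @return Tibble `genome_id`, `marker_set_used`, `n_expected`,
#'   `n_present`, `n_multicopy`, `completeness`, `contamination` (both %).
#' @export
quality_report <- function(hits, set, exclusions = NULL, genus_map = NULL) {
  assert_hits(hits)
  genomes <- sort(unique(hits$genome_id))
  rows <- lapply(genomes, function(g) {
    gset <- set
    if (!is.null(exclusions)) {
      if (is.null(genus_map)) abort("`exclusions` requires `genus_map`.")
      genus <- genus_map$genus[match(g, genus_map$genome_id)]
      if (!is.na(genus) && genus %in% names(exclusions) &&
          length(exclusions[[genus]]) > 0) {
        gset <- adjusted_set(set, exclusions[[genus]])
      }
    }
    counts <- genome_counts(hits, g, gset)
    tibble(
      genome_id = g,
      marker_set_used = if (inherits(gset, "marker_set")) gset$name else "custom",
      n_expected = length(marker_ids(gset)),
      n_present = sum(counts >= 1),
      n_multicopy = sum(counts > 1),
      completeness = completeness(hits, g, gset),
      contamination = contamination(hits, g, gset)
    )
  })
  bind_rows(rows)
}

#' MIMAG-style quality tier
#'
#' High quality requires completeness >= 90%, contamination < 5%, both
#' rRNAs (16S and 23S) and more than 18 tRNAs; medium requires
#' completeness > 50% and contamination < 5%; everything else is low.
#' rRNA/tRNA presence are inputs — this package performs no detection.
#'
#' @param completeness,contamination Percentages.
#' @param has_rrna Both 16S and 23S rRNA genes present?
#' @param n_trna Number of distinct tRNAs found.
#' @return `"high"`, `"medium"` or `"low"` (vectorized).
#' @examples
#' quality_tier(95, 1, TRUE, 20)
#' @export
quality_tier <- function(completeness, contamination, has_rrna, n_trna) {
  dplyr::case_when(
    completeness >= 90 & contamination < 5 & has_rrna & n_trna > 18 ~ "high",
    completeness > 50 & contamination < 5 ~ "medium",
    .default = "low"
  )
}

#' Read a per-genus exclusion-list config
#'
#' Plain-text format: one `[genus]` header per block, one marker id per
#' line, `#` comments ignored. The package ships the curated
#' Parvarchaeales/Jingweiarchaeales lists in
#' `parvarchaeales_exclusions.txt` (blocks `shared`, `Jingweiarchaeum`,
#' `Haiyanarchaeum`, `Rehaiarchaeum`, `Acidifodinimicrobium`,
#' `Parvarchaeum`); see [reveco_extdata()].
#'
#' @param path Path to the config file.
#' @return Named list: block name -> character vector of marker ids.
#' @examples
#' ex <- read_exclusions(reveco_extdata("parvarchaeales_exclusions.txt"))
#' lengths(ex)
#' @export
read_exclusions <- function(path) {
  lines <- stringr::str_trim(readr::read_lines(path))
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  out <- list()
  current <- NULL
  for (ln in lines) {
    if (stringr::str_detect(ln, "^\\[.+\\]$")) {
      current <- stringr::str_sub(ln, 2, -2)
      out[[current]] <- character()
    } else {
      if (is.null(current)) abort("Marker id before any [genus] header.")
      out[[current]] <- c(out[[current]], ln)
    }
  }
  out
}

#' Path to a file shipped with the package
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
reveco_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "reveco")))
  }
  path <- system.file("extdata", file, package = "reveco")
  if (path == "") abort(paste0("No such extdata file: ", file))
  path
}
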
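#' Read protein FASTA files into a proteome table
#'
#' Reads one or more multi-record protein FASTA files (wrapped or
#' unwrapped). Each file becomes one genome; the genome id is the file
#' name without extension unless overridden.
#'
#' @param path A FASTA file, a vector of FASTA files, or a directory
#'   containing `.faa`/`.fasta`/`.fa` files.
#' @param genome_id Optional genome id(s), recycled along files.
#' @return Proteome tibble `genome_id`, `protein_id`, `sequence`.
#' @export
read_proteome <- function(path, genome_id = NULL) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    dir(path, pattern = "\\.(faa|fasta|fa)$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) abort("No FASTA files found.")
  ids <- genome_id %||% stringr::str_remove(basename(files),
                                            "\\.(faa|fasta|fa)$")
  bind_rows(purrr::map2(files, ids, function(f, g) {
    aa <- Biostrings::readAAStringSet(f)
    tibble(
      genome_id = g,
      protein_id = stringr::str_extract(names(aa), "^\\S+"),
      sequence = unname(as.character(aa))
    )
  }))
}

#' Write a proteome table to protein FASTA
#'
#' @param proteome Proteome tibble (single genome or several; all records
#'   go to one file).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_proteome <- function(proteome, file) {
  assert_proteome(proteome)
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence,
                                         proteome$protein_id))
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}

#' Read gene annotations from GFF3 or 4-column TSV
#'
#' GFF3 input is filtered to `CDS` rows. The TSV format is
#' `seq_id`, `start`, `end`, `strand` with a header, 1-based inclusive
#' coordinates.
#'
#' @param path Input file; format guessed from the extension (`.gff`,
#'   `.gff3` vs anything else) unless given.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return Annotation tibble `seq_id`, `start`, `end`, `strand`.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "tsv"
    }
  }
  if (format == "gff3") {
    cols <- c("seq_id", "source", "type", "start", "end", "score",
              "strand", "phase", "attributes")
    gff <- readr::read_tsv(path, comment = "#", col_names = cols,
                           col_types = "cccnncccc", progress = FALSE)
    out <- gff |>
      filter(.data$type == "CDS") |>
      select("seq_id", "start", "end", "strand") |>
      mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  } else {
    out <- readr::read_tsv(path, col_types = "ciic", progress = FALSE)
    stopifnot(all(c("seq_id", "start", "end", "strand") %in% names(out)))
  }
  assert_annotations(out)
  as_tibble(out)
}

#' Write annotations as a 4-column TSV
#'
#' @param ann Annotation tibble.
#' @param file Output path.
#' @export
write_annotations <- function(ann, file) {
  assert_annotations(ann)
  readr::write_tsv(ann, file)
  invisible(file)
}

#' Read a marker hit table
#'
#' TSV with header `genome_id`, `marker_id`, `count`.
#'
#' @param path Input file.
#' @return Tibble `genome_id`, `marker_id`, `count`.
#' @export
read_marker_hits <- function(path) {
  hits <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
  assert_hits(hits)
  as_tibble(hits)
}

#' Read a trait table
#'
#' TSV with a `tip_label` (or `genome_id`) key column and one numeric
#' column per trait.
#'
#' @param path Input file.
#' @return Tibble with the key column first.
#' @export
read_trait_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Extract one trait as a named vector for tree methods
#'
#' @param trait_table Tibble with a key column and trait columns.
#' @param trait Trait column name.
#' @param key Key column; default the first of `tip_label`/`genome_id`.
#' @return Named numeric vector.
#' @export
trait_vector <- function(trait_table, trait,
                         key = intersect(c("tip_label", "genome_id"),
                                         names(trait_table))[1]) {
  if (is.na(key)) abort("No tip_label/genome_id column found.")
  if (!trait %in% names(trait_table)) {
    abort(paste0("No trait column '", trait, "'."))
  }
  setNames(trait_table[[trait]], trait_table[[key]])
}
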
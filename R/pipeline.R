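#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow (proteomes -> traits ->
#' marker QC -> AAI -> ancestral states) into one validated list. Stages
#' whose inputs are absent are skipped.
#'
#' @param proteome_dir Directory of protein FASTA files (one per genome);
#'   required.
#' @param out_dir Output directory; created if missing.
#' @param pka pKa table name or object (see [get_pka()]).
#' @param ogt_slope,ogt_intercept IVYWREL-OGT regression coefficients.
#' @param marker_hits Optional marker-hit TSV path (enables the QC stage).
#' @param marker_set_file Optional marker-set file; defaults to the
#'   shipped synthetic 149-id archaeal set.
#' @param exclusions_file Optional per-genus exclusion config (see
#'   [read_exclusions()]).
#' @param genus_map Optional TSV `genome_id`, `genus`.
#' @param run_aai Compute the all-vs-all AAI matrix? Default `FALSE`
#'   (quadratic in genomes).
#' @param aai Filter settings from [aai_filters()].
#' @param tree Optional Newick path (enables ancestral reconstruction).
#' @param trait_columns Trait columns reconstructed on the tree.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(proteome_dir, out_dir,
                            pka = "ipc",
                            ogt_slope = 937, ogt_intercept = -335,
                            marker_hits = NULL,
                            marker_set_file = NULL,
                            exclusions_file = NULL,
                            genus_map = NULL,
                            run_aai = FALSE,
                            aai = aai_filters(),
                            tree = NULL,
                            trait_columns = c("ogt_ivywrel", "average_pi",
                                              "pi_bias"),
                            seed = 1L) {
  cfg <- list(
    proteome_dir = proteome_dir, out_dir = out_dir, pka = pka,
    ogt_slope = ogt_slope, ogt_intercept = ogt_intercept,
    marker_hits = marker_hits, marker_set_file = marker_set_file,
    exclusions_file = exclusions_file, genus_map = genus_map,
    run_aai = run_aai, aai = aai, tree = tree,
    trait_columns = trait_columns, seed = seed
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!dir.exists(cfg$proteome_dir)) {
    abort(paste0("proteome_dir does not exist: ", cfg$proteome_dir))
  }
  for (f in c("marker_hits", "marker_set_file", "exclusions_file",
              "genus_map", "tree")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0(f, " does not exist: ", cfg[[f]]))
    }
  }
  cfg
}

#' Run the full reverse-ecology pipeline
#'
#' Executes, in order: proteome trait inference, marker-based QC (if a hit
#' table is configured), all-vs-all AAI (if enabled) and ancestral-state
#' reconstruction of the configured trait columns (if a tree is
#' configured). All outputs are TSV files in `out_dir`, plus a JSON
#' manifest recording the package version, the configuration and its
#' hash; a rerun with identical inputs reproduces identical tables.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list of the result tables (`traits`, `qc`,
#'   `aai`, `anc`), with `out_dir` attached.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  results <- list()

  say("stage traits: reading proteomes from ", cfg$proteome_dir)
  proteome <- read_proteome(cfg$proteome_dir)
  traits <- withCallingHandlers(
    proteome_traits(proteome, pka = get_pka(cfg$pka),
                    ogt_slope = cfg$ogt_slope,
                    ogt_intercept = cfg$ogt_intercept),
    warning = function(w) {
      say("  note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  readr::write_tsv(traits, file.path(cfg$out_dir, "proteome_traits.tsv"))
  results$traits <- traits

  if (!is.null(cfg$marker_hits)) {
    say("stage qc: scoring markers")
    hits <- read_marker_hits(cfg$marker_hits)
    set_file <- cfg$marker_set_file %||%
      reveco_extdata("markers_archaea149_synthetic.txt")
    set <- read_marker_set(set_file)
    exclusions <- if (!is.null(cfg$exclusions_file)) {
      read_exclusions(cfg$exclusions_file)
    }
    gmap <- if (!is.null(cfg$genus_map)) {
      readr::read_tsv(cfg$genus_map, col_types = "cc", progress = FALSE)
    }
    qc <- quality_report(hits, set, exclusions, gmap)
    readr::write_tsv(qc, file.path(cfg$out_dir, "quality_report.tsv"))
    results$qc <- qc
  }

  if (isTRUE(cfg$run_aai)) {
    say("stage aai: all-vs-all reciprocal best hits")
    aai <- aai_matrix(proteome, cfg$aai)
    readr::write_tsv(aai$pairs, file.path(cfg$out_dir, "aai_pairs.tsv"))
    mat <- as.data.frame(aai$matrix)
    mat <- cbind(genome_id = rownames(mat), mat)
    readr::write_tsv(mat, file.path(cfg$out_dir, "aai_matrix.tsv"))
    results$aai <- aai
  }

  if (!is.null(cfg$tree)) {
    say("stage anc: ancestral reconstruction")
    tree <- read_newick(cfg$tree)
    missing_tips <- setdiff(tree$tip.label, traits$genome_id)
    if (length(missing_tips) > 0) {
      abort(paste0("stage anc: tips without traits: ",
                   paste(missing_tips, collapse = ", ")))
    }
    anc <- lapply(cfg$trait_columns, function(tr) {
      x <- trait_vector(traits, tr, key = "genome_id")[tree$tip.label]
      recon <- anc_ml(tree, x)
      ann <- annotate_tree(recon)
      readr::write_tsv(
        ann$table,
        file.path(cfg$out_dir, paste0("anc_", tr, ".tsv"))
      )
      write_newick(ann$tree,
                   file.path(cfg$out_dir, paste0("anc_", tr, ".nwk")))
      recon
    })
    names(anc) <- cfg$trait_columns
    results$anc <- anc
  }

  manifest <- list(
    package = "reveco",
    version = as.character(utils::packageVersion("reveco")),
    config = cfg[setdiff(names(cfg), "aai")],
    aai_filters = cfg$aai,
    config_hash = rlang::hash(cfg),
    outputs = dir(cfg$out_dir, pattern = "\\.(tsv|nwk)$")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  say("done: ", cfg$out_dir)
  results$out_dir <- cfg$out_dir
  invisible(results)
}

#' Generate a synthetic demo data set and run the pipeline on it
#'
#' Builds a small fully synthetic study — several genomes with distinct
#' composition profiles, a marker hit table, and a Brownian-motion trait
#' history on a simulated tree — writes the inputs under
#' `dir/inputs/`, then runs [run_pipeline()] on them.
#'
#' @param dir Working directory for inputs and outputs.
#' @param n_genomes Number of synthetic genomes.
#' @param n_proteins Proteins per genome.
#' @param seed Integer seed for all generators.
#' @param quiet Suppress progress messages?
#' @return The [run_pipeline()] result list.
#' @export
run_pipeline_demo <- function(dir = tempfile("reveco_demo"),
                              n_genomes = 6, n_proteins = 60,
                              seed = 1L, quiet = FALSE) {
  inputs <- file.path(dir, "inputs")
  dir.create(file.path(inputs, "faa"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- sprintf("g%02d", seq_len(n_genomes))
  for (i in seq_len(n_genomes)) {
    frac <- 0.3 + 0.4 * (i - 1) / max(n_genomes - 1, 1)
    p <- gen_bimodal_proteome(n_proteins, frac_acidic = frac,
                              seed = seed + i, genome_id = ids[i])
    write_proteome(p, file.path(inputs, "faa", paste0(ids[i], ".faa")))
  }
  set <- read_marker_set(reveco_extdata("markers_archaea149_synthetic.txt"))
  hits <- gen_marker_table(ids, set, completeness = 0.9,
                           contamination = 0.02, seed = seed)
  readr::write_tsv(hits, file.path(inputs, "marker_hits.tsv"))
  tree <- gen_tree(n_genomes, "random-split", seed = seed)
  tree$tip.label <- ids
  write_newick(tree, file.path(inputs, "tree.nwk"))
  cfg <- pipeline_config(
    proteome_dir = file.path(inputs, "faa"),
    out_dir = file.path(dir, "out"),
    marker_hits = file.path(inputs, "marker_hits.tsv"),
    tree = file.path(inputs, "tree.nwk"),
    run_aai = FALSE,
    seed = seed
  )
  run_pipeline(cfg, quiet = quiet)
}

#' Pairwise group comparison of a trait with significance letters
#'
#' Two-sample Wilcoxon rank-sum test for every pair of groups, with
#' Benjamini-Hochberg correction, plus compact letter display at the
#' chosen alpha: groups sharing no letter differ significantly. Genera
#' are independent samples, so the unpaired rank-sum variant is used.
#' Singleton groups are dropped with a warning.
#'
#' @param trait_table Tibble with `genome_id` and the trait column.
#' @param group_map Tibble `genome_id`, `group`.
#' @param trait Trait column name.
#' @param alpha Significance level on adjusted p-values. Default 0.005.
#' @param adjust Method for [stats::p.adjust()]. Default `"BH"`.
#' @return List with `tests` (tibble `group_a`, `group_b`, `p_value`,
#'   `p_adjusted`) and `letters` (tibble `group`, `letters`).
#' @export
group_compare <- function(trait_table, group_map, trait, alpha = 0.005,
                          adjust = "BH") {
  df <- left_join(trait_table, group_map, by = "genome_id") |>
    filter(!is.na(.data$group), !is.na(.data[[trait]]))
  sizes <- count(df, .data$group)
  drop <- sizes$group[sizes$n < 2]
  if (length(drop) > 0) {
    warn(paste0("Dropping singleton group(s): ",
                paste(drop, collapse = ", ")))
    df <- filter(df, !.data$group %in% drop)
  }
  groups <- sort(unique(df$group))
  if (length(groups) < 2) abort("Need at least 2 groups with >= 2 members.")
  combos <- utils::combn(groups, 2, simplify = FALSE)
  tests <- bind_rows(lapply(combos, function(ab) {
    xa <- df[[trait]][df$group == ab[1]]
    xb <- df[[trait]][df$group == ab[2]]
    p <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
    tibble(group_a = ab[1], group_b = ab[2], p_value = p)
  }))
  tests$p_adjusted <- p.adjust(tests$p_value, method = adjust)
  letters_tbl <- cld_letters(groups, tests, alpha)
  list(tests = tests, letters = letters_tbl)
}

# Compact letter display: maximal cliques of the "not significantly
# different" graph each receive one letter.
cld_letters <- function(groups, tests, alpha) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tests))) {
    if (!is.na(tests$p_adjusted[i]) && tests$p_adjusted[i] < alpha) {
      adj[tests$group_a[i], tests$group_b[i]] <- FALSE
      adj[tests$group_b[i], tests$group_a[i]] <- FALSE
    }
  }
  cliques <- max_cliques_bk(adj)
  # stable letter order: by first group member
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  lab <- vapply(seq_along(groups), function(i) {
    paste(letters[which(vapply(cliques, function(cl) i %in% cl,
                               logical(1)))], collapse = "")
  }, character(1))
  tibble(group = groups, letters = lab)
}

# Bron-Kerbosch maximal-clique enumeration; group counts here are tiny.
max_cliques_bk <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      out[[length(out) + 1]] <<- sort(r)
      return()
    }
    for (v in p) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  out
}
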
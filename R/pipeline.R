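# End-to-end orchestration: ingest -> filter -> summarize -> digest/index ->
# (intersect) -> rank -> properties -> specificity -> filters -> shortlists.

#' Build a pipeline configuration
#'
#' Collects every threshold, mode switch and path the pipeline consumes.
#' Defaults follow the conventions of function-based targeted-assay design:
#' top 400 candidates ranked for property calculations, 25% median-length
#' tolerance, peptides of 8-25 residues, specificity threshold 90%,
#' shortlists of 50 peptides, at least one detectability vote, at most
#' three modification-prone sites, no missed cleavages.
#'
#' @param molecule_name Target protein name (required; used for
#'   specificity scoring).
#' @param reference_fasta Path to the reference (UniProt-style) FASTA.
#' @param custom_fasta Path to a custom (e.g. metagenome-derived) FASTA;
#'   when both are given the pipeline runs in intersection mode.
#' @param blast_file Path to BLASTP results (XML or tabular) for the
#'   candidate peptides; `NULL` disables specificity scoring.
#' @param blast_format Passed to [parse_blast_hits()].
#' @param metadata Optional TSV sidecar for [merge_metadata()].
#' @param detectability_file Optional external detectability table.
#' @param detectability_format Passed to [parse_external_detectability()].
#' @param output_dir Directory for all report files.
#' @param top_n Candidates subjected to property calculations (default 400).
#' @param length_tolerance_pct Median-length filter tolerance (default 25).
#' @param min_pep_len,max_pep_len Peptide length bounds (defaults 8, 25).
#' @param specificity_threshold Minimum specificity score, percent
#'   (default 90).
#' @param allowlist Peptides exempt from the specificity filter.
#' @param detectability_votes_required Minimum detectability votes
#'   (default 1).
#' @param external_probability_threshold Minimum external detection
#'   probability when present (default 0.5).
#' @param max_mod_sites Maximum modification-prone sites (default 3).
#' @param shortlist_k Shortlist length (default 50).
#' @param remove_putative Remove putative-annotated records? Default
#'   `FALSE`.
#' @param stats_only Stop after the dataset summary and figures.
#' @param no_bsearch Disable specificity scoring entirely.
#' @param static_ranking Use static (single-sort) coverage ordering instead
#'   of greedy marginal gains.
#' @param missed_cleavages,proline_rule Digestion parameters.
#' @param taxonomy_restriction Recorded taxonomy scope of the input
#'   retrieval (default "Bacteria"); informational.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(molecule_name,
                            reference_fasta = NULL,
                            custom_fasta = NULL,
                            blast_file = NULL,
                            blast_format = "auto",
                            metadata = NULL,
                            detectability_file = NULL,
                            detectability_format = "consequence_table",
                            output_dir = tempfile("pepscout_"),
                            top_n = 400L,
                            length_tolerance_pct = 25,
                            min_pep_len = 8L,
                            max_pep_len = 25L,
                            specificity_threshold = 90,
                            allowlist = character(0),
                            detectability_votes_required = 1L,
                            external_probability_threshold = 0.5,
                            max_mod_sites = 3L,
                            shortlist_k = 50L,
                            remove_putative = FALSE,
                            stats_only = FALSE,
                            no_bsearch = FALSE,
                            static_ranking = FALSE,
                            missed_cleavages = 0L,
                            proline_rule = TRUE,
                            taxonomy_restriction = "Bacteria",
                            seed = 1L) {
  if (missing(molecule_name) || is.null(molecule_name) ||
      !nzchar(molecule_name)) {
    stop("molecule_name (-m) is required and must be non-empty")
  }
  if (is.null(reference_fasta) && is.null(custom_fasta)) {
    stop("at least one of reference_fasta / custom_fasta is required")
  }
  stopifnot(top_n >= 1, length_tolerance_pct >= 0,
            min_pep_len >= 1, max_pep_len >= min_pep_len,
            specificity_threshold >= 0, specificity_threshold <= 100,
            detectability_votes_required >= 0,
            external_probability_threshold >= 0,
            external_probability_threshold <= 1,
            max_mod_sites >= 0, shortlist_k >= 1, missed_cleavages >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

manifest_new <- function() {
  env <- new.env(parent = emptyenv())
  env$files <- character(0)
  env$warnings <- character(0)
  env$notes <- character(0)
  env
}

#' Run the peptide-selection pipeline end to end
#'
#' Executes every stage in order: ingest (+ metadata merge), length and
#' putative filtering, dataset summary and figures (stop here under
#' `stats_only`), in-silico digestion and peptide indexing, intersection
#' with the reference when both datasets are given, ranking of the top-n
#' candidates, modification and detectability properties, specificity
#' scoring (skipped under `no_bsearch` or when no BLAST file is supplied),
#' property filtering, and shortlist generation with all report files.
#' Identical configuration and inputs yield byte-identical text outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results (`summary`,
#'   `index`, `candidates`, `properties`, `specificity`, `filters`,
#'   `selections`) and a `manifest` of written files, notes and warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- manifest_new()
  note <- function(...) man$notes <- c(man$notes, paste0(...))
  wrn <- function(...) man$warnings <- c(man$warnings, paste0(...))
  wrote <- function(path) man$files <- c(man$files, path)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$output_dir, name)
  collect_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      wrn(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # -- ingest ----------------------------------------------------------
  reference <- custom <- NULL
  if (!is.null(config$reference_fasta)) {
    reference <- read_protein_fasta(config$reference_fasta,
                                    dialect = "uniprot")
    if (!is.null(config$metadata)) {
      reference <- collect_warnings(merge_metadata(reference,
                                                   config$metadata))
    }
    note("reference proteins parsed: ", nrow(reference))
  }
  if (!is.null(config$custom_fasta)) {
    custom <- read_protein_fasta(config$custom_fasta, dialect = "custom")
    note("custom proteins parsed: ", nrow(custom))
  }
  intersect_mode <- !is.null(reference) && !is.null(custom)
  primary <- reference %||% custom

  # -- pre-filter + summary (on the primary display set) ---------------
  prefilter <- function(records) {
    lf <- filter_by_length(records, config$length_tolerance_pct)
    pf <- filter_putative(lf$kept, enabled = config$remove_putative)
    list(kept = pf$kept, n_len = nrow(lf$removed),
         n_put = nrow(pf$removed))
  }
  pre_primary <- prefilter(primary)
  summary <- summarize_dataset(primary, pre_primary$kept,
                               n_removed_length = pre_primary$n_len,
                               n_removed_putative = pre_primary$n_put)
  wrote(write_initial_info(summary, outfile("initial_info.txt")))
  retained_name <- if (!is.null(reference)) {
    "UniProt_proteins.faa"
  } else {
    "Custom_proteins.faa"
  }
  wrote(write_protein_fasta(pre_primary$kept, outfile(retained_name)))
  figs <- collect_warnings(plot_summaries(pre_primary$kept, summary,
                                          config$output_dir))
  for (f in figs) wrote(f)
  result <- list(summary = summary, manifest = man, config = config)
  if (config$stats_only) {
    note("stats_only: stopping after dataset summary")
    write_manifest(man, config, outfile("run_manifest.txt"))
    return(invisible(result))
  }

  # -- digest + index --------------------------------------------------
  idx_args <- list(min_len = config$min_pep_len,
                   max_len = config$max_pep_len,
                   missed_cleavages = config$missed_cleavages,
                   proline_rule = config$proline_rule)
  index <- NULL
  if (intersect_mode) {
    ref_kept <- pre_primary$kept
    cus <- prefilter(custom)
    ref_idx <- do.call(build_peptide_index,
                       c(list(ref_kept, provenance = "reference"), idx_args))
    cus_idx <- do.call(build_peptide_index,
                       c(list(cus$kept, provenance = "custom"), idx_args))
    index <- collect_warnings(intersect_with_reference(cus_idx, ref_idx))
    note("intersection mode: ", nrow(index$entries),
         " peptide(s) shared with the reference")
  } else {
    prov <- if (!is.null(reference)) "reference" else "custom"
    index <- do.call(build_peptide_index,
                     c(list(pre_primary$kept, provenance = prov), idx_args))
  }
  result$index <- index

  # -- rank candidates -------------------------------------------------
  candidates <- rank_candidates(index, n = config$top_n)
  note("ranking key: ", attr(candidates, "rank_key"),
       "; candidates for property calculations: ", nrow(candidates))
  wrote(write_candidates(candidates,
                         outfile("peptide_candidates_for_calculations.txt"),
                         outfile("peptide_candidates_for_calculations.faa")))
  wrote(outfile("peptide_candidates_for_calculations.faa"))
  result$candidates <- candidates
  if (nrow(candidates) == 0) {
    wrn("no candidate peptides within the length bounds; stopping")
    write_manifest(man, config, outfile("run_manifest.txt"))
    return(invisible(result))
  }

  # -- properties ------------------------------------------------------
  mods <- count_modification_sites(candidates$sequence)
  wrote(write_modification_report(
    mods, outfile("possible_chemical_modifications.txt")))
  detect <- builtin_detectability_votes(candidates$sequence)
  detect$external_probability <- NA_real_
  if (!is.null(config$detectability_file)) {
    ext <- parse_external_detectability(config$detectability_file,
                                        config$detectability_format)
    m <- match(detect$peptide, ext$peptide)
    hit <- !is.na(m)
    ov <- hit & !is.na(ext$votes[m])
    detect$votes[ov] <- ext$votes[m[ov]]
    detect$external_probability[hit] <- ext$external_probability[m[hit]]
    note("external detectability verdicts applied to ", sum(hit),
         " peptide(s); ", sum(!hit), " kept built-in votes")
  }
  result$properties <- list(modifications = mods, detectability = detect)

  # -- specificity -----------------------------------------------------
  spec_enabled <- !config$no_bsearch && !is.null(config$blast_file)
  if (spec_enabled) {
    hits <- parse_blast_hits(config$blast_file, config$blast_format)
    specificity <- collect_warnings(
      compute_specificity(hits, candidates$sequence, config$molecule_name,
                          allowlist = config$allowlist))
  } else {
    specificity <- compute_specificity(NULL, candidates$sequence,
                                       config$molecule_name,
                                       enabled = FALSE)
    note(if (config$no_bsearch) {
      "no_bsearch: specificity scoring disabled"
    } else {
      "no BLAST file supplied: specificity scoring skipped"
    })
  }
  wrote(write_specificity_report(
    specificity, outfile("peptide_blastp_specificity.txt")))
  result$specificity <- specificity

  # -- property filters ------------------------------------------------
  cand <- candidates
  cand$mod_total <- mods$total_sites[match(cand$sequence, mods$peptide)]
  dm <- match(cand$sequence, detect$peptide)
  cand$votes <- detect$votes[dm]
  cand$external_probability <- detect$external_probability[dm]
  sm <- match(cand$sequence, specificity$peptide)
  cand$spec_score <- specificity$score[sm]
  cand$spec_status <- specificity$status[sm]
  filters <- apply_property_filters(
    cand,
    votes_required = config$detectability_votes_required,
    probability_threshold = config$external_probability_threshold,
    max_mod_sites = config$max_mod_sites,
    specificity_threshold = config$specificity_threshold,
    allowlist = config$allowlist)
  note("peptides passing all filters: ", nrow(filters$passing), " of ",
       nrow(cand), " (rejected: ",
       paste(names(filters$counts), filters$counts, sep = "=",
             collapse = ", "), ")")
  result$filters <- filters

  # -- shortlists ------------------------------------------------------
  selections <- list()
  has_taxonomy <- index$provenance %in% c("reference", "intersected")
  if (nrow(filters$passing) == 0) {
    wrn("Caution: no peptides passed all filters; shortlists are empty")
    empty <- data.frame(peptide = character(0), marginal_gain = integer(0),
                        cumulative_covered = integer(0),
                        cumulative_pct = numeric(0), taxa = character(0))
    for (nm in c("Selected_peptides.genera", "Selected_peptides.species")) {
      wrote(write_tsv_file(empty, outfile(nm)))
    }
  } else if (has_taxonomy) {
    # coverage universes are the taxa of the property-calculated candidates
    genus_universe <- sort(unique(unlist(candidates$genus_set)),
                           method = "radix")
    species_universe <- sort(unique(unlist(candidates$species_set)),
                             method = "radix")
    note("coverage universe (candidates): ", length(genus_universe),
         " genera, ", length(species_universe), " species")
    selections$genera <- greedy_select(
      filters$passing, "genus", k = config$shortlist_k,
      universe = genus_universe, static_ranking = config$static_ranking)
    selections$species <- greedy_select(
      filters$passing, "species", k = config$shortlist_k,
      universe = species_universe, static_ranking = config$static_ranking)
    wrote(collect_warnings(write_selected_list(
      selections$genera, outfile("Selected_peptides.genera"))))
    wrote(collect_warnings(write_selected_list(
      selections$species, outfile("Selected_peptides.species"))))
  } else {
    selections$occurrence <- rank_by_occurrence(filters$passing,
                                                k = config$shortlist_k)
    wrote(collect_warnings(write_selected_list(
      selections$occurrence, outfile("Selected_peptides.occurrence"))))
  }
  result$selections <- selections

  wrote(write_complete_info(index$entries,
                            outfile("Peptides_complete_info.txt"),
                            mod_profile = mods,
                            detectability = detect,
                            specificity = specificity))
  write_manifest(man, config, outfile("run_manifest.txt"))
  invisible(result)
}

write_manifest <- function(man, config, path) {
  params <- unclass(config)
  params <- params[order(names(params))]
  plines <- vapply(names(params), function(k) {
    v <- params[[k]]
    vs <- if (is.null(v)) {
      "NULL"
    } else if (length(v) == 0) {
      ""
    } else {
      paste(format(v), collapse = ",")
    }
    paste0("param\t", k, "=", vs)
  }, character(1))
  lines <- c("# pepscout run manifest",
             plines,
             paste0("file\t", basename(man$files)),
             paste0("note\t", man$notes),
             paste0("warning\t", man$warnings))
  writeLines(lines, path)
  man$files <- c(man$files, path)
  invisible(path)
}
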
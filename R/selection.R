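# Greedy coverage shortlists and the final report files.

#' Greedy maximum-coverage shortlist
#'
#' Classic greedy maximum coverage over the genus or species sets of the
#' passing candidates: at each step the candidate covering the most
#' not-yet-covered taxa is picked (ties broken by occurrence descending,
#' species count descending, then peptide sequence ascending). When every
#' remaining candidate has zero marginal gain, candidates are still
#' appended in tie-break order up to `k` (flagged `marginal_gain = 0`) so
#' the shortlist has a stable, fixed length. `static_ranking = TRUE`
#' instead sorts once by static taxa-set size and reports marginal gains
#' along that fixed order.
#'
#' @param candidates Data frame with list-columns `genus_set`/`species_set`
#'   plus `sequence`, `occurrence`, `n_species`.
#' @param coverage_key `"genus"` or `"species"`.
#' @param k Shortlist size (default 50).
#' @param universe Character vector of taxa forming the coverage
#'   denominator; defaults to the union of the candidates' taxa sets.
#' @param static_ranking Sort once by static set size instead of
#'   recomputing marginal gains (default `FALSE`).
#' @return A `selection_result`: list with `picks` (data.frame of
#'   `peptide`, `marginal_gain`, `cumulative_covered`, `cumulative_pct`,
#'   `taxa`), `coverage_unit`, `universe_size` and `covered_taxa`.
#' @export
greedy_select <- function(candidates, coverage_key = c("genus", "species"),
                          k = 50L, universe = NULL, static_ranking = FALSE) {
  coverage_key <- match.arg(coverage_key)
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no passing candidates to select from")
  }
  if (k < 1) stop("k must be >= 1")
  sets <- candidates[[paste0(coverage_key, "_set")]]
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)), method = "radix")
  }
  seqs <- candidates$sequence
  occ <- candidates$occurrence %||% rep(0, nrow(candidates))
  nsp <- candidates$n_species %||% rep(0L, nrow(candidates))
  n <- length(seqs)
  k_eff <- min(k, n)

  order_of <- integer(0)
  if (static_ranking) {
    ord <- order_radix(-lengths(sets), -occ, -nsp, seqs)
    order_of <- ord[seq_len(k_eff)]
  } else {
    remaining <- seq_len(n)
    covered <- character(0)
    for (step in seq_len(k_eff)) {
      gains <- vapply(remaining,
                      function(i) sum(!(sets[[i]] %in% covered)),
                      integer(1))
      ord <- order_radix(-gains, -occ[remaining], -nsp[remaining],
                         seqs[remaining])
      pick <- remaining[ord[1]]
      order_of <- c(order_of, pick)
      covered <- unique(c(covered, sets[[pick]]))
      remaining <- setdiff(remaining, pick)
    }
  }

  covered <- character(0)
  gain <- integer(k_eff)
  cum <- integer(k_eff)
  for (s in seq_len(k_eff)) {
    i <- order_of[s]
    gain[s] <- sum(!(sets[[i]] %in% covered))
    covered <- unique(c(covered, sets[[i]]))
    cum[s] <- length(covered)
  }
  usize <- length(universe)
  picks <- data.frame(
    peptide = seqs[order_of],
    marginal_gain = gain,
    cumulative_covered = cum,
    cumulative_pct = if (usize > 0) 100 * cum / usize else NA_real_,
    taxa = vapply(sets[order_of],
                  function(s) collapse_set(s) %||% NA_character_,
                  character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(picks = picks, coverage_unit = coverage_key,
                 universe_size = usize,
                 covered_taxa = sort(covered, method = "radix")),
            class = "selection_result")
}

#' Occurrence-ranked shortlist for taxonomy-free datasets
#'
#' For custom (e.g. metagenome-derived) datasets without taxonomy, ranks
#' passing candidates by copy-weighted occurrence among proteins
#' (descending; ties by peptide sequence ascending) and returns the top
#' `k`. Genes with multiple copies in a metagenome are expected to be more
#' highly expressed, so their peptides have a greater chance of LC-MS/MS
#' detection.
#'
#' @param candidates Passing candidates with `sequence` and `occurrence`.
#' @param k Shortlist size (default 50).
#' @return A `selection_result` with `coverage_unit = "protein_occurrence"`;
#'   `marginal_gain` holds each peptide's occurrence and the cumulative
#'   percentage is relative to the summed occurrence of all candidates.
#' @export
rank_by_occurrence <- function(candidates, k = 50L) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no passing candidates to select from")
  }
  ord <- order_radix(-candidates$occurrence, candidates$sequence)
  k_eff <- min(k, nrow(candidates))
  sel <- candidates[ord[seq_len(k_eff)], , drop = FALSE]
  total <- sum(candidates$occurrence)
  cum <- cumsum(sel$occurrence)
  picks <- data.frame(
    peptide = sel$sequence,
    marginal_gain = sel$occurrence,
    cumulative_covered = cum,
    cumulative_pct = if (total > 0) 100 * cum / total else NA_real_,
    taxa = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(list(picks = picks, coverage_unit = "protein_occurrence",
                 universe_size = total, covered_taxa = character(0)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Peptide shortlist (%s coverage): %d picks, universe %s\n",
              x$coverage_unit, nrow(x$picks),
              format(x$universe_size)))
  if (nrow(x$picks) > 0) {
    last <- x$picks[nrow(x$picks), ]
    cat(sprintf("  cumulative coverage: %s / %s (%.1f%%)\n",
                format(last$cumulative_covered), format(x$universe_size),
                last$cumulative_pct))
  }
  invisible(x)
}

#' Write the comprehensive peptide information table
#'
#' Writes the `Peptides_complete_info.txt`-style tab-delimited file with
#' one row per indexed peptide within the length bounds (intersected-only
#' peptides when intersection mode is active): sequence, occurrence among
#' proteins, species count, detectability votes and external probability,
#' specificity score, modification-site count and related taxonomy.
#' Properties not computed for a peptide (e.g. outside the ranked
#' candidates, or blasting disabled) are rendered NA.
#'
#' @param entries Indexed peptide entries (`index$entries`).
#' @param path Output path.
#' @param mod_profile,detectability,specificity Optional property tables
#'   keyed by peptide.
#' @return The path, invisibly.
#' @export
write_complete_info <- function(entries, path, mod_profile = NULL,
                                detectability = NULL, specificity = NULL) {
  lookup <- function(tab, col, key = "peptide") {
    if (is.null(tab)) return(rep(NA, nrow(entries)))
    tab[[col]][match(entries$sequence, tab[[key]])]
  }
  df <- data.frame(
    peptide = entries$sequence,
    length = entries$length,
    n_proteins = entries$n_parents,
    occurrence = entries$occurrence,
    n_species = entries$n_species,
    n_genera = entries$n_genera,
    consequence_votes = lookup(detectability, "votes"),
    peptidesieve_score = lookup(detectability, "external_probability"),
    specificity_score = lookup(specificity, "score"),
    specificity_status = lookup(specificity, "status"),
    n_modification_sites = lookup(mod_profile, "total_sites"),
    has_ambiguous = entries$has_ambiguous,
    species = vapply(entries$species_set, collapse_set, character(1)),
    genera = vapply(entries$genus_set, collapse_set, character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
}

#' Write the selected-peptide shortlist files
#'
#' Writes `Selected_peptides.genera` / `Selected_peptides.species`-style
#' files: one peptide per line with its marginal coverage gain, cumulative
#' coverage percentage, and parent taxa. An empty selection produces an
#' empty (header-only) file with a warning.
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_selected_list <- function(result, path) {
  if (nrow(result$picks) == 0) {
    warning("Caution: no peptides passed all filters; writing empty ",
            "shortlist to ", basename(path))
  }
  df <- result$picks
  df$cumulative_pct <- round(df$cumulative_pct, 4)
  write_tsv_file(df, path)
}
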
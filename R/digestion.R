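# In-silico tryptic digestion and the peptide -> taxa index.

#' Digest one protein sequence in silico with trypsin
#'
#' Cleaves C-terminal to every lysine (K) or arginine (R); when
#' `proline_rule` is on (the default) a site followed by proline is
#' suppressed. With `missed_cleavages = 0` the returned peptides,
#' concatenated in order, reconstruct the input exactly; with
#' `missed_cleavages = m` every run of up to `m + 1` consecutive
#' fully-cleaved fragments is additionally reported.
#'
#' @param sequence A single amino-acid string.
#' @param missed_cleavages Maximum number of internal uncut K/R sites per
#'   reported peptide (default 0).
#' @param proline_rule Suppress cleavage before proline? Default `TRUE`.
#' @return A `data.frame` with columns `peptide` and `missed_cleavages`,
#'   ordered by start position, then span.
#' @examples
#' digest_trypsin("MKTAYIAKQR")           # MK, TAYIAK, QR
#' digest_trypsin("AKRPCK")               # AK, RPCK (R-P suppressed)
#' @export
digest_trypsin <- function(sequence, missed_cleavages = 0L,
                           proline_rule = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      is.na(sequence) || nchar(sequence) == 0) {
    stop("'sequence' must be a single non-empty amino-acid string")
  }
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sites <- which(chars == "K" | chars == "R")
  sites <- sites[sites < n]
  if (proline_rule && length(sites) > 0) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  nfrag <- length(starts)
  max_span <- min(as.integer(missed_cleavages), nfrag - 1L)
  pep <- character(0)
  mc <- integer(0)
  for (i in seq_len(nfrag)) {
    upper <- min(max_span, nfrag - i)
    for (m in 0:upper) {
      pep <- c(pep, substr(sequence, starts[i], ends[i + m]))
      mc <- c(mc, m)
    }
  }
  data.frame(peptide = pep, missed_cleavages = mc, stringsAsFactors = FALSE)
}

#' Build the peptide index from a set of protein records
#'
#' Digests every record with trypsin and accumulates, per unique peptide
#' within the length bounds, the parent protein identifiers, copy-weighted
#' occurrence, and the species/genus sets of the parents. Peptides
#' containing ambiguity codes (B, J, O, U, X, Z) are indexed (so counts
#' stay complete) but flagged for later exclusion from shortlists. A
#' peptide occurring more than once in one protein counts that protein
#' once. Parents of unknown taxonomy contribute to occurrence but not to
#' the species/genus sets.
#'
#' @param records Protein records (see [read_protein_fasta()]).
#' @param min_len,max_len Peptide length bounds in residues (defaults 8
#'   and 25).
#' @param missed_cleavages,proline_rule Passed to [digest_trypsin()].
#' @param provenance One of `"reference"`, `"custom"`; recorded on the
#'   index.
#' @return A `peptide_index`: list with `entries` (a data.frame with
#'   list-columns `parent_ids`, `species_set`, `genus_set`), `provenance`
#'   and `config`.
#' @export
build_peptide_index <- function(records, min_len = 8L, max_len = 25L,
                                missed_cleavages = 0L, proline_rule = TRUE,
                                provenance = c("reference", "custom")) {
  provenance <- match.arg(provenance)
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot build a peptide index from an empty record set")
  }
  if (min_len < 1 || max_len < min_len) {
    stop("require 1 <= min_len <= max_len")
  }
  per <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    d <- digest_trypsin(records$sequence[i], missed_cleavages, proline_rule)
    len <- nchar(d$peptide)
    d <- d[len >= min_len & len <= max_len, , drop = FALSE]
    if (nrow(d) == 0) next
    # one protein counts once per peptide; keep the smallest missed count
    d <- d[order_radix(d$peptide, d$missed_cleavages), , drop = FALSE]
    d <- d[!duplicated(d$peptide), , drop = FALSE]
    per[[i]] <- data.frame(
      peptide = d$peptide,
      mc = d$missed_cleavages,
      record_id = records$record_id[i],
      copy = records$copy_number[i],
      species = records$species[i],
      genus = records$genus[i],
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, per)
  if (is.null(all) || nrow(all) == 0) {
    warning("no peptides within the configured length bounds")
    entries <- empty_index_entries()
  } else {
    grp <- split(seq_len(nrow(all)), all$peptide)
    peps <- names(grp)  # split() orders keys lexicographically
    parent_ids <- lapply(grp, function(ii) {
      sort(unique(all$record_id[ii]), method = "radix")
    })
    species_set <- lapply(grp, function(ii) {
      s <- all$species[ii]
      sort(unique(s[!is.na(s)]), method = "radix")
    })
    genus_set <- lapply(grp, function(ii) {
      g <- all$genus[ii]
      sort(unique(g[!is.na(g)]), method = "radix")
    })
    entries <- data.frame(
      sequence = peps,
      length = nchar(peps),
      occurrence = vapply(grp, function(ii) sum(all$copy[ii]), numeric(1)),
      n_parents = lengths(parent_ids),
      n_species = lengths(species_set),
      n_genera = lengths(genus_set),
      has_ambiguous = has_ambiguous_residue(peps),
      missed_cleavages = vapply(grp, function(ii) min(all$mc[ii]),
                                integer(1)),
      stringsAsFactors = FALSE
    )
    entries$parent_ids <- unname(parent_ids)
    entries$species_set <- unname(species_set)
    entries$genus_set <- unname(genus_set)
    rownames(entries) <- NULL
  }
  structure(list(
    entries = entries,
    provenance = provenance,
    config = list(min_len = as.integer(min_len),
                  max_len = as.integer(max_len),
                  missed_cleavages = as.integer(missed_cleavages),
                  proline_rule = proline_rule)
  ), class = "peptide_index")
}

empty_index_entries <- function() {
  data.frame(
    sequence = character(0), length = integer(0), occurrence = numeric(0),
    n_parents = integer(0), n_species = integer(0), n_genera = integer(0),
    has_ambiguous = logical(0), missed_cleavages = integer(0),
    parent_ids = I(list()), species_set = I(list()), genus_set = I(list()),
    stringsAsFactors = FALSE
  )
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("Peptide index (%s): %d unique peptides, length %d-%d AA, %d missed cleavage(s)\n",
              x$provenance, nrow(x$entries), x$config$min_len,
              x$config$max_len, x$config$missed_cleavages))
  invisible(x)
}

#' Rank indexed peptides and take the top candidates
#'
#' Sorts peptides in descending order of the ranking key and returns the
#' top `n`. For taxonomy-aware indexes (reference or intersected) the key
#' is the number of encoding species; for custom-only indexes it is the
#' copy-weighted occurrence among proteins. Ties are broken by occurrence
#' (descending) then peptide sequence (ascending), so the ranking is a
#' deterministic total order.
#'
#' @param index A `peptide_index`.
#' @param n Number of candidates to retain (default 400); larger than the
#'   index returns all entries.
#' @param key `"auto"` (default; species_count for reference/intersected,
#'   occurrence for custom), `"species_count"` or `"occurrence"`.
#' @return The top-`n` entries data.frame, with attribute `rank_key`.
#' @export
rank_candidates <- function(index, n = 400L,
                            key = c("auto", "species_count", "occurrence")) {
  key <- match.arg(key)
  stopifnot(n >= 1)
  if (key == "auto") {
    key <- if (index$provenance %in% c("reference", "intersected")) {
      "species_count"
    } else {
      "occurrence"
    }
  }
  e <- index$entries
  if (nrow(e) == 0) {
    attr(e, "rank_key") <- key
    return(e)
  }
  k1 <- if (key == "species_count") e$n_species else e$occurrence
  ord <- order_radix(-k1, -e$occurrence, e$sequence)
  e <- e[ord[seq_len(min(n, nrow(e)))], , drop = FALSE]
  rownames(e) <- NULL
  attr(e, "rank_key") <- key
  e
}

#' Intersect a custom peptide index with a reference index
#'
#' Retains exactly the peptide sequences present in both indexes (built
#' with identical length bounds). Each merged entry carries the taxonomy
#' (species/genus sets) of the reference side and the copy-weighted
#' occurrence and parent identifiers of the custom side, so the result
#' reflects site-specific abundance with database-verified taxonomy.
#'
#' @param custom,reference `peptide_index` objects.
#' @return A `peptide_index` with provenance `"intersected"`.
#' @export
intersect_with_reference <- function(custom, reference) {
  if (!identical(custom$config$min_len, reference$config$min_len) ||
      !identical(custom$config$max_len, reference$config$max_len)) {
    stop("indexes were built with different peptide length bounds")
  }
  common <- intersect(custom$entries$sequence, reference$entries$sequence)
  if (length(common) == 0) {
    warning("no peptide sequences shared between custom and reference sets")
  }
  common <- sort(common, method = "radix")
  ci <- match(common, custom$entries$sequence)
  ri <- match(common, reference$entries$sequence)
  ce <- custom$entries[ci, , drop = FALSE]
  re <- reference$entries[ri, , drop = FALSE]
  entries <- data.frame(
    sequence = common,
    length = nchar(common),
    occurrence = ce$occurrence,
    n_parents = ce$n_parents,
    n_species = re$n_species,
    n_genera = re$n_genera,
    has_ambiguous = ce$has_ambiguous,
    missed_cleavages = pmin(ce$missed_cleavages, re$missed_cleavages),
    stringsAsFactors = FALSE
  )
  entries$parent_ids <- ce$parent_ids
  entries$species_set <- re$species_set
  entries$genus_set <- re$genus_set
  rownames(entries) <- NULL
  structure(list(entries = entries, provenance = "intersected",
                 config = custom$config),
            class = "peptide_index")
}

#' Write the candidate peptide table and companion FASTA
#'
#' Writes the ranked candidate list to a tab-delimited
#' `peptide_candidates_for_calculations.txt`-style file and a companion
#' FASTA of the candidate peptides suitable as queries for an external
#' BLASTP run.
#'
#' @param candidates Ranked entries from [rank_candidates()].
#' @param path Output TSV path.
#' @param fasta_path Optional output FASTA path.
#' @return The TSV path, invisibly.
#' @export
write_candidates <- function(candidates, path, fasta_path = NULL) {
  df <- data.frame(
    peptide = candidates$sequence,
    length = candidates$length,
    occurrence = candidates$occurrence,
    n_proteins = candidates$n_parents,
    n_species = candidates$n_species,
    n_genera = candidates$n_genera,
    has_ambiguous = candidates$has_ambiguous,
    species = vapply(candidates$species_set, collapse_set, character(1)),
    genera = vapply(candidates$genus_set, collapse_set, character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
  if (!is.null(fasta_path)) {
    lines <- as.vector(rbind(paste0(">", candidates$sequence),
                             candidates$sequence))
    writeLines(lines, fasta_path)
  }
  invisible(path)
}
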
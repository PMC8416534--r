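# Reading protein datasets, pre-filtering, and summary statistics.

# Organisms whose name starts with one of these tokens carry no usable
# genus/species assignment and are tallied as unknown taxonomy.
UNKNOWN_TAXON_PREFIXES <- c("uncultured", "unidentified", "bacterium")

derive_taxa <- function(organism) {
  if (is.na(organism) || !nzchar(organism)) {
    return(list(organism = NA_character_, genus = NA_character_,
                species = NA_character_))
  }
  first <- tolower(strsplit(trimws(organism), "\\s+")[[1]][1])
  if (first %in% UNKNOWN_TAXON_PREFIXES) {
    return(list(organism = NA_character_, genus = NA_character_,
                species = NA_character_))
  }
  toks <- strsplit(trimws(organism), "\\s+")[[1]]
  list(organism = organism,
       genus = toks[1],
       species = paste(toks[seq_len(min(2L, length(toks)))], collapse = " "))
}

#' Read a protein FASTA file into a table of protein records
#'
#' Parses an amino-acid FASTA file into one row per entry, extracting
#' identity, description and (for UniProt-style headers) taxonomy from the
#' `OS=` field. Genus is the first whitespace token of the organism and
#' species the first two; organisms beginning with "uncultured",
#' "unidentified" or "bacterium" are treated as taxonomy-absent. For
#' `dialect = "custom"` (e.g. metagenome-derived proteins) taxonomy is
#' absent and a copy number is read from either a `copies=<int>` key or a
#' SPAdes-style `_cov_<float>` token (rounded up to at least 1).
#'
#' @param path Path to an amino-acid FASTA file (multi-line sequences
#'   allowed).
#' @param dialect `"uniprot"` for reference sets with `OS=` taxonomy,
#'   `"custom"` for taxonomy-free sets with optional copy-number tokens.
#' @param putative_tokens Character vector of tokens; a record whose
#'   description contains any of them (case-insensitive) is flagged
#'   putative. Default `"putative"`.
#' @return A `data.frame` with columns `record_id`, `description`,
#'   `sequence`, `length`, `organism`, `genus`, `species`, `phylum`,
#'   `copy_number`, `source` and `putative_flag`.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">sp|P00001|CDO_PSEPU Catechol-1,2-dioxygenase OS=Pseudomonas putida OX=303",
#'              "MSEQNNTAVK"), f)
#' read_protein_fasta(f)[, c("record_id", "genus", "species")]
#' @export
read_protein_fasta <- function(path, dialect = c("uniprot", "custom"),
                               putative_tokens = "putative") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("not FASTA format: line ", first, " of '", path,
         "' does not start with '>'")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  headers <- names(seqs)
  seq_chr <- toupper(as.character(seqs))

  if (any(!nzchar(seq_chr))) {
    bad <- headers[!nzchar(seq_chr)]
    stop("FASTA record(s) with empty sequence: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  residues_ok <- !grepl("[^A-Z]", seq_chr)
  if (any(!residues_ok)) {
    offending <- vapply(seq_chr[!residues_ok], function(s) {
      paste(sort(unique(strsplit(gsub("[A-Z]", "", s), "")[[1]])),
            collapse = "")
    }, character(1))
    stop("sequence characters outside the amino-acid alphabet in record(s) ",
         paste(utils::head(headers[!residues_ok], 5), collapse = ", "),
         " (offending characters: ",
         paste(utils::head(offending, 5), collapse = " "), ")")
  }

  n <- length(seqs)
  rec_id <- character(n); descr <- character(n)
  organism <- rep(NA_character_, n)
  copy_number <- rep(1, n)

  for (i in seq_len(n)) {
    h <- headers[i]
    tok1 <- sub("\\s.*$", "", h)
    rest <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    if (dialect == "uniprot") {
      # ">sp|ACC|MNEMO Name OS=Organism OX=123": id is the accession.
      if (grepl("^(sp|tr)\\|", tok1)) {
        rec_id[i] <- strsplit(tok1, "|", fixed = TRUE)[[1]][2]
      } else {
        rec_id[i] <- tok1
      }
      os <- regmatches(rest, regexpr("OS=.*?(?= [A-Z]{2}=|$)", rest,
                                     perl = TRUE))
      if (length(os) == 1) organism[i] <- trimws(sub("^OS=", "", os))
      descr[i] <- trimws(sub("\\s*OS=.*$", "", rest))
    } else {
      rec_id[i] <- tok1
      descr[i] <- trimws(rest)
      cp <- regmatches(h, regexpr("copies=([0-9]+)", h))
      cov <- regmatches(tok1, regexpr("_cov_([0-9.]+)", tok1))
      if (length(cp) == 1) {
        copy_number[i] <- max(1, as.numeric(sub("copies=", "", cp)))
      } else if (length(cov) == 1) {
        copy_number[i] <- max(1, ceiling(as.numeric(sub("_cov_", "", cov))))
      }
    }
  }

  taxa <- lapply(organism, derive_taxa)
  pat <- paste(tolower(putative_tokens), collapse = "|")
  out <- data.frame(
    record_id = rec_id,
    description = descr,
    sequence = seq_chr,
    length = nchar(seq_chr),
    organism = vapply(taxa, `[[`, character(1), "organism"),
    genus = vapply(taxa, `[[`, character(1), "genus"),
    species = vapply(taxa, `[[`, character(1), "species"),
    phylum = NA_character_,
    copy_number = copy_number,
    source = if (dialect == "uniprot") "reference" else "custom",
    putative_flag = nzchar(pat) & grepl(pat, tolower(descr)),
    stringsAsFactors = FALSE
  )
  out
}

#' Merge a tab-delimited metadata sidecar into protein records
#'
#' Joins a TSV table (columns `id`, and optionally `organism`, `phylum`,
#' `protein_name`) onto parsed protein records by record identifier,
#' filling in fields the FASTA headers lack (typically phylum). Existing
#' fields are never overwritten. Table rows that match no record are
#' counted in the `n_unmatched` attribute and reported as a warning.
#'
#' @param records Protein records from [read_protein_fasta()].
#' @param table_path Path to the tab-delimited metadata table.
#' @return `records` with taxonomy fields filled where previously absent;
#'   attribute `n_unmatched` holds the count of non-matching table rows.
#' @export
merge_metadata <- function(records, table_path) {
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"id" %in% names(tab)) {
    stop("metadata table must contain an 'id' column: ", table_path)
  }
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup) > 0) {
    stop("duplicate identifiers in metadata table: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  m <- match(records$record_id, tab$id)
  hit <- !is.na(m)
  if ("phylum" %in% names(tab)) {
    fill <- hit & is.na(records$phylum)
    records$phylum[fill] <- tab$phylum[m[fill]]
  }
  if ("organism" %in% names(tab)) {
    fill <- hit & is.na(records$organism)
    if (any(fill)) {
      taxa <- lapply(tab$organism[m[fill]], derive_taxa)
      records$organism[fill] <- vapply(taxa, `[[`, character(1), "organism")
      records$genus[fill] <- vapply(taxa, `[[`, character(1), "genus")
      records$species[fill] <- vapply(taxa, `[[`, character(1), "species")
    }
  }
  if ("protein_name" %in% names(tab)) {
    fill <- hit & !nzchar(records$description)
    records$description[fill] <- tab$protein_name[m[fill]]
  }
  n_unmatched <- sum(!tab$id %in% records$record_id)
  if (n_unmatched > 0) {
    warning(n_unmatched, " metadata row(s) matched no protein record")
  }
  attr(records, "n_unmatched") <- n_unmatched
  records
}

#' Filter protein records by deviation from the median length
#'
#' Computes the median length over all input records (even-count median is
#' the mean of the two middle values) and removes entries deviating from it
#' by more than `tolerance_pct` percent. The boundary is inclusive: a
#' record is kept iff `|length - m| <= m * tolerance_pct / 100`.
#'
#' @param records Protein records.
#' @param tolerance_pct Maximum allowed deviation from the median length,
#'   in percent (default 25).
#' @return A list with elements `kept`, `removed` (both preserving input
#'   order), `median`, `lower` and `upper`.
#' @export
filter_by_length <- function(records, tolerance_pct = 25) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no protein records to filter")
  }
  if (!is.numeric(tolerance_pct) || tolerance_pct < 0) {
    stop("tolerance_pct must be a non-negative percentage")
  }
  m <- stats::median(records$length)
  lo <- m * (1 - tolerance_pct / 100)
  hi <- m * (1 + tolerance_pct / 100)
  keep <- records$length >= lo & records$length <= hi
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       median = m, lower = lo, upper = hi)
}

#' Remove records flagged as putative
#'
#' When enabled, moves records whose description carried a putative token
#' at parse time into the removed set; disabled (the default) it is the
#' identity.
#'
#' @param records Protein records.
#' @param enabled Apply the filter? Default `FALSE`.
#' @return A list with `kept` and `removed`, preserving input order.
#' @export
filter_putative <- function(records, enabled = FALSE) {
  if (!enabled) {
    return(list(kept = records,
                removed = records[integer(0), , drop = FALSE]))
  }
  keep <- !records$putative_flag
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

length_stats <- function(lengths) {
  list(n = length(lengths),
       median = stats::median(lengths),
       mean = mean(lengths),
       # sample (n-1) standard deviation; NA for a single record
       sd = if (length(lengths) > 1) stats::sd(lengths) else NA_real_,
       min = min(lengths),
       max = max(lengths))
}

sorted_counts <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(integer(0))
  tab <- table(x)
  cnt <- as.integer(tab)
  nm <- names(tab)
  ord <- order_radix(-cnt, nm)
  stats::setNames(cnt[ord], nm[ord])
}

#' Summarize a protein dataset before and after pre-filtering
#'
#' Computes length statistics (median, mean, sample standard deviation)
#' before and after refinement, plus protein counts per phylum, genus and
#' species on the filtered set. Records lacking taxonomy are tallied in
#' `n_unknown_taxonomy`.
#'
#' @param before Records before filtering.
#' @param after Records after filtering (a subset of `before`).
#' @param n_removed_length,n_removed_putative Counts of records removed by
#'   the length and putative filters; by default all removals are
#'   attributed to the length filter.
#' @return An object of class `dataset_summary`.
#' @export
summarize_dataset <- function(before, after,
                              n_removed_length = NULL,
                              n_removed_putative = 0L) {
  if (is.null(before) || nrow(before) == 0) stop("empty input dataset")
  if (is.null(n_removed_length)) {
    n_removed_length <- nrow(before) - nrow(after) - n_removed_putative
  }
  structure(list(
    n_before = nrow(before),
    n_after = nrow(after),
    n_removed_length = as.integer(n_removed_length),
    n_removed_putative = as.integer(n_removed_putative),
    length_before = length_stats(before$length),
    length_after = if (nrow(after) > 0) length_stats(after$length) else NULL,
    counts_by_phylum = sorted_counts(after$phylum),
    counts_by_genus = sorted_counts(after$genus),
    counts_by_species = sorted_counts(after$species),
    n_unknown_taxonomy = sum(is.na(after$species))
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Protein dataset summary\n")
  cat(sprintf("  entries: %d before filtering, %d after (%d removed by length, %d putative)\n",
              x$n_before, x$n_after, x$n_removed_length, x$n_removed_putative))
  lb <- x$length_before
  cat(sprintf("  length before: median %.1f, mean %.1f, sd %.1f (range %d-%d)\n",
              lb$median, lb$mean, ifelse(is.na(lb$sd), 0, lb$sd),
              lb$min, lb$max))
  if (!is.null(x$length_after)) {
    la <- x$length_after
    cat(sprintf("  length after:  median %.1f, mean %.1f, sd %.1f (range %d-%d)\n",
                la$median, la$mean, ifelse(is.na(la$sd), 0, la$sd),
                la$min, la$max))
  }
  cat(sprintf("  taxa after filtering: %d phyla, %d genera, %d species, %d of unknown taxonomy\n",
              length(x$counts_by_phylum), length(x$counts_by_genus),
              length(x$counts_by_species), x$n_unknown_taxonomy))
  invisible(x)
}

#' Write the initial dataset statistics file
#'
#' Writes a tab-delimited `initial_info.txt`-style summary: length
#' statistics before/after refinement (standard deviation uses the sample,
#' n-1, convention) followed by per-phylum/genus/species protein counts.
#'
#' @param summary A `dataset_summary` from [summarize_dataset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_initial_info <- function(summary, path) {
  lines <- c(
    "# initial dataset statistics (length sd: sample, n-1)",
    paste("n_before", summary$n_before, sep = "\t"),
    paste("n_after", summary$n_after, sep = "\t"),
    paste("n_removed_length", summary$n_removed_length, sep = "\t"),
    paste("n_removed_putative", summary$n_removed_putative, sep = "\t"),
    paste("n_unknown_taxonomy", summary$n_unknown_taxonomy, sep = "\t")
  )
  fmt_stats <- function(tag, st) {
    if (is.null(st)) return(character(0))
    sprintf("%s_%s\t%s", tag, c("n", "median", "mean", "sd", "min", "max"),
            vapply(st[c("n", "median", "mean", "sd", "min", "max")],
                   function(v) format(v, digits = 10), character(1)))
  }
  lines <- c(lines, fmt_stats("length_before", summary$length_before),
             fmt_stats("length_after", summary$length_after))
  for (grp in c("phylum", "genus", "species")) {
    cnt <- summary[[paste0("counts_by_", grp)]]
    if (length(cnt) > 0) {
      lines <- c(lines, paste0("# counts by ", grp),
                 paste(names(cnt), cnt, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write protein records back to FASTA
#'
#' Echoes a (typically filtered) protein set to an amino-acid FASTA file,
#' reconstructing a minimal header of identifier, description and, when
#' present, the `OS=` organism field.
#'
#' @param records Protein records.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$record_id[i])
    if (nzchar(records$description[i])) {
      hdr <- paste(hdr, records$description[i])
    }
    if (!is.na(records$organism[i])) {
      hdr <- paste0(hdr, " OS=", records$organism[i])
    }
    lines <- c(lines, hdr, wrap_fasta(records$sequence[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
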
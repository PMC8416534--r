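# Functional-specificity scoring from BLASTP results.

split_deflines <- function(x) {
  # nr records bundle several equivalent deflines, separated by the \x01
  # control character or embedded ">" markers.
  parts <- strsplit(x, "\x01|\\s*>\\s*")[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Parse BLASTP results into a hit table
#'
#' Reads standard NCBI BLAST XML or a tabular dialect with a subject-title
#' column (tab-separated: qseqid, sseqid, nident, length, mismatch, gaps,
#' stitle). Multi-name deflines are split on the defline separator control
#' character and on embedded ">" markers. Only the first HSP of each hit is
#' used (peptide queries align once).
#'
#' @param path Path to the BLAST result file.
#' @param format `"auto"` (by extension), `"blast_xml"` or
#'   `"blast_tabular"`.
#' @return A `data.frame` with columns `query_peptide`, `subject_id`,
#'   `defline`, `identities`, `align_length`, `gaps`, `mismatches`, and a
#'   list-column `deflines` of split names.
#' @export
parse_blast_hits <- function(path, format = c("auto", "blast_xml",
                                              "blast_tabular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) {
      "blast_xml"
    } else {
      "blast_tabular"
    }
  }
  if (format == "blast_xml") {
    doc <- tryCatch(xml2::read_xml(path), error = function(e) {
      stop("malformed BLAST XML '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
    its <- xml2::xml_find_all(doc, ".//Iteration")
    rows <- list()
    for (it in its) {
      q <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
      hits <- xml2::xml_find_all(it, ".//Hit")
      for (h in hits) {
        hsp <- xml2::xml_find_first(h, ".//Hsp")
        if (inherits(hsp, "xml_missing")) {
          stop("malformed BLAST XML: Hit without Hsp under query '", q, "'")
        }
        num <- function(node, tag) {
          v <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", tag)))
          suppressWarnings(as.integer(v))
        }
        ident <- num(hsp, "Hsp_identity")
        alen <- num(hsp, "Hsp_align-len")
        gaps <- num(hsp, "Hsp_gaps")
        if (is.na(gaps)) gaps <- 0L
        if (is.na(ident) || is.na(alen)) {
          stop("malformed BLAST XML: missing Hsp_identity/Hsp_align-len ",
               "under query '", q, "'")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_peptide = q,
          subject_id = xml2::xml_text(xml2::xml_find_first(h, "./Hit_id")),
          defline = xml2::xml_text(xml2::xml_find_first(h, "./Hit_def")),
          identities = ident, align_length = alen, gaps = gaps,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
      query_peptide = character(0), subject_id = character(0),
      defline = character(0), identities = integer(0),
      align_length = integer(0), gaps = integer(0),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- tryCatch(
      utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                        quote = ""),
      error = function(e) stop("malformed BLAST tabular file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(tab) < 7) {
      stop("BLAST tabular file must have 7 columns ",
           "(qseqid, sseqid, nident, length, mismatch, gaps, stitle)")
    }
    out <- data.frame(
      query_peptide = as.character(tab[[1]]),
      subject_id = as.character(tab[[2]]),
      defline = as.character(tab[[7]]),
      identities = as.integer(tab[[3]]),
      align_length = as.integer(tab[[4]]),
      gaps = as.integer(tab[[6]]),
      stringsAsFactors = FALSE
    )
  }
  out$mismatches <- out$align_length - out$identities
  out$deflines <- lapply(out$defline, split_deflines)
  out
}

#' Select exact full-length hits for a peptide
#'
#' A hit is exact iff identities equal both the alignment length and the
#' query peptide length and there are no gaps: full-length, gapless,
#' mismatch-free.
#'
#' @param hits Hit table rows belonging to one query peptide.
#' @param peptide_length Length of the query peptide in residues.
#' @return The subset of exact hits.
#' @export
select_exact_hits <- function(hits, peptide_length) {
  keep <- hits$identities == hits$align_length &
    hits$align_length == peptide_length &
    hits$gaps == 0
  hits[keep, , drop = FALSE]
}

#' Normalize a protein name for comparison
#'
#' Lowercases, strips a leading database tag (e.g. "MULTISPECIES:"),
#' converts commas, hyphens, underscores and slashes to spaces and
#' collapses whitespace, so slightly disparate nr names compare equal.
#'
#' @param name Character vector of protein names.
#' @return Normalized names.
#' @examples
#' normalize_protein_name("Catechol-1,2-dioxygenase")
#' @export
normalize_protein_name <- function(name) {
  x <- tolower(name)
  x <- sub("^\\S+:\\s+", "", x)
  x <- gsub("[-,_/]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

names_match <- function(names, term) {
  # bidirectional substring containment on normalized names: nr entries are
  # often shortened forms of the full target name (or vice versa)
  vapply(names, function(nm) {
    grepl(nm, term, fixed = TRUE) || grepl(term, nm, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

#' Infer protein-name synonyms from BLAST deflines
#'
#' For every hit whose defline bundle contains at least one name matching
#' the normalized target (bidirectional substring containment), every other
#' name in that bundle is added to the synonym set. The target itself is
#' always a member. Inference is single-pass: synonyms discovered in one
#' bundle are not used to expand others, keeping scores reproducible.
#'
#' @param hits Parsed hit table (see [parse_blast_hits()]).
#' @param target_name The target protein name.
#' @return Sorted character vector of normalized names including the
#'   target.
#' @export
build_synonym_set <- function(hits, target_name) {
  if (!nzchar(target_name)) stop("target_name must be non-empty")
  target <- normalize_protein_name(target_name)
  syn <- character(0)
  for (names_i in hits$deflines) {
    nm <- normalize_protein_name(names_i)
    if (any(names_match(nm, target))) {
      syn <- c(syn, nm[!names_match(nm, target)])
    }
  }
  sort(unique(c(target, syn)), method = "radix")
}

#' Compute functional-specificity scores for candidate peptides
#'
#' For each peptide, keeps only exact full-length hits and scores the
#' percentage of them whose defline bundle contains the target name or a
#' synonym. Peptides with zero exact hits get status `no_hits` (a caution
#' listing them is emitted, since their shortlisting cannot be backed by a
#' specificity score); allowlisted peptides get status `skipped`; when
#' `enabled = FALSE` (the `--no-bsearch` analogue) every peptide is
#' skipped.
#'
#' @param hits Parsed hit table (see [parse_blast_hits()]).
#' @param peptides Character vector of candidate peptide sequences.
#' @param target_name Target protein name.
#' @param allowlist Peptides exempted from specificity scoring.
#' @param enabled Compute scores at all? Default `TRUE`.
#' @param synonyms Optional pre-built synonym set; by default inferred from
#'   `hits` with [build_synonym_set()].
#' @return A `data.frame` with `peptide`, `total_exact_hits`,
#'   `matching_hits`, `score` (percent, NA when unscored) and `status`
#'   (`scored`, `no_hits`, `skipped`); attribute `synonyms` carries the
#'   synonym set used.
#' @export
compute_specificity <- function(hits, peptides, target_name,
                                allowlist = character(0), enabled = TRUE,
                                synonyms = NULL) {
  n <- length(peptides)
  rep0 <- data.frame(
    peptide = peptides,
    total_exact_hits = rep(NA_integer_, n),
    matching_hits = rep(NA_integer_, n),
    score = rep(NA_real_, n),
    status = rep("skipped", n),
    stringsAsFactors = FALSE
  )
  if (!enabled) {
    attr(rep0, "synonyms") <- character(0)
    return(rep0)
  }
  if (is.null(synonyms)) synonyms <- build_synonym_set(hits, target_name)
  target <- normalize_protein_name(target_name)
  terms <- unique(c(target, synonyms))

  hit_matches <- function(deflines) {
    nm <- normalize_protein_name(deflines)
    for (t in terms) {
      if (any(names_match(nm, t))) return(TRUE)
    }
    FALSE
  }

  out <- rep0
  for (i in seq_len(n)) {
    p <- peptides[i]
    if (p %in% allowlist) next  # stays "skipped"
    sub <- hits[hits$query_peptide == p, , drop = FALSE]
    exact <- select_exact_hits(sub, nchar(p))
    total <- nrow(exact)
    if (total == 0) {
      out$status[i] <- "no_hits"
      next
    }
    matching <- sum(vapply(exact$deflines, hit_matches, logical(1)))
    out$total_exact_hits[i] <- total
    out$matching_hits[i] <- as.integer(matching)
    out$score[i] <- 100 * matching / total
    out$status[i] <- "scored"
  }
  missing <- out$peptide[out$status == "no_hits"]
  if (length(missing) > 0) {
    warning("Caution: the following peptides are missing specificity ",
            "scores (no exact BLAST hits): ",
            paste(utils::head(missing, 20), collapse = ", "))
  }
  attr(out, "synonyms") <- synonyms
  out
}

#' Write the specificity report file
#'
#' Writes a `peptide_blastp_specificity.txt`-style tab-delimited file:
#' a comment header with the synonym set used (for manual inspection),
#' then one row per peptide with hit tallies and score.
#'
#' @param report Output of [compute_specificity()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_specificity_report <- function(report, path) {
  syn <- attr(report, "synonyms") %||% character(0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# protein synonyms used: ",
                    if (length(syn)) paste(syn, collapse = "; ") else "none"),
             con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
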
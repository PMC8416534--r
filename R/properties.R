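# Chemical-modification proneness, detectability votes, and property filters.

#' Default chemical-modification rule set
#'
#' Residues counted as modification-prone: methionine and tryptophan
#' (oxidation), cysteine (reactivity), asparagine and glutamine
#' (deamidation), plus one extra site when the peptide starts with
#' glutamine (pyro-Glu formation). The rules are data, not code: supply a
#' modified list to [count_modification_sites()] to change them.
#'
#' @return A list with elements `residues` (named character vector mapping
#'   residue -> modification name) and `nterm` (same, applied to the first
#'   residue only).
#' @export
default_modification_rules <- function() {
  list(
    residues = c(M = "Met-oxidation", W = "Trp-oxidation",
                 C = "Cys-reactivity", N = "Asn-deamidation",
                 Q = "Gln-deamidation"),
    nterm = c(Q = "N-terminal-Gln-pyroGlu")
  )
}

#' Count chemical-modification-prone sites in peptides
#'
#' Applies a per-residue rule set (see [default_modification_rules()]) to
#' each peptide and returns per-type and total site counts.
#'
#' @param peptides Character vector of peptide sequences.
#' @param rules Modification rule set.
#' @return A `data.frame` with one row per peptide: `peptide`, one column
#'   per modification type, and `total_sites`.
#' @examples
#' count_modification_sites("SQSDFNLR")  # Q:1, N:1, total 2
#' @export
count_modification_sites <- function(peptides,
                                     rules = default_modification_rules()) {
  if (length(peptides) == 0 || any(!nzchar(peptides))) {
    stop("peptides must be non-empty strings")
  }
  out <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  total <- integer(length(peptides))
  for (res in names(rules$residues)) {
    cnt <- vapply(strsplit(peptides, "", fixed = TRUE),
                  function(ch) sum(ch == res), integer(1))
    out[[rules$residues[[res]]]] <- cnt
    total <- total + cnt
  }
  for (res in names(rules$nterm)) {
    cnt <- as.integer(substr(peptides, 1, 1) == res)
    out[[rules$nterm[[res]]]] <- cnt
    total <- total + cnt
  }
  out$total_sites <- total
  out
}

#' Built-in LC-MS/MS detectability voters
#'
#' Four transparent, deterministic rule voters preserving the four-voter
#' contract of published ensemble detectability predictors (they are NOT
#' equivalent to any trained model):
#' * V1 (length): peptide length in `len_range` (default 8-20 residues);
#' * V2 (hydropathy): mean Kyte-Doolittle hydropathy in `gravy_range`
#'   (default -2.0 to +1.5);
#' * V3 (charge): count of K+R+H in `basic_range` (default 1-3);
#' * V4 (composition): no homopolymer run of `max_homopolymer` (default 4)
#'   or more and proline fraction at most `max_proline_frac` (default 0.3).
#'
#' Peptides containing ambiguity codes make the hydropathy voter abstain;
#' votes are then counted over the non-abstaining voters and the peptide is
#' flagged.
#'
#' @param peptides Character vector of peptide sequences.
#' @param len_range,gravy_range,basic_range,max_homopolymer,max_proline_frac
#'   Voter thresholds (see above).
#' @return A `data.frame` with per-voter verdicts, `votes` (0-4),
#'   `n_voters` and `abstained`.
#' @export
builtin_detectability_votes <- function(peptides,
                                        len_range = c(8L, 20L),
                                        gravy_range = c(-2.0, 1.5),
                                        basic_range = c(1L, 3L),
                                        max_homopolymer = 4L,
                                        max_proline_frac = 0.3) {
  if (length(peptides) == 0 || any(!nzchar(peptides))) {
    stop("peptides must be non-empty strings")
  }
  len <- nchar(peptides)
  amb <- has_ambiguous_residue(peptides)
  chars <- strsplit(peptides, "", fixed = TRUE)

  v1 <- len >= len_range[1] & len <= len_range[2]
  gravy <- vapply(chars, function(ch) {
    h <- KD_HYDROPATHY[ch]
    if (anyNA(h)) NA_real_ else mean(h)
  }, numeric(1))
  v2 <- ifelse(is.na(gravy), NA,
               gravy >= gravy_range[1] & gravy <= gravy_range[2])
  basic <- vapply(chars, function(ch) sum(ch %in% c("K", "R", "H")),
                  integer(1))
  v3 <- basic >= basic_range[1] & basic <= basic_range[2]
  maxrun <- vapply(chars, function(ch) max(rle(ch)$lengths), integer(1))
  pfrac <- vapply(chars, function(ch) mean(ch == "P"), numeric(1))
  v4 <- maxrun < max_homopolymer & pfrac <= max_proline_frac

  vm <- cbind(v1, v2, v3, v4)
  data.frame(
    peptide = peptides,
    length_ok = v1, hydropathy_ok = v2, charge_ok = v3, composition_ok = v4,
    gravy = gravy,
    votes = as.integer(rowSums(vm, na.rm = TRUE)),
    n_voters = as.integer(rowSums(!is.na(vm))),
    abstained = amb,
    stringsAsFactors = FALSE
  )
}

#' Parse an external detectability score table
#'
#' Reads per-peptide detectability verdicts produced by external
#' predictors: `consequence_table` is tab-delimited with a peptide column
#' followed by four binary per-algorithm verdicts; `peptidesieve_table` has
#' a peptide column and a detection probability in \[0, 1\]. An optional
#' header line starting with "peptide" is skipped. Parsed results are meant
#' to override built-in votes for the listed peptides.
#'
#' @param path Path to the table.
#' @param format `"consequence_table"` or `"peptidesieve_table"`.
#' @return A `data.frame` with `peptide`, `votes` (NA for probability
#'   tables) and `external_probability` (NA for vote tables).
#' @export
parse_external_detectability <- function(path,
                                         format = c("consequence_table",
                                                    "peptidesieve_table")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^peptide\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) stop("empty detectability table: ", path)
  peptide <- character(length(lines))
  votes <- rep(NA_integer_, length(lines))
  prob <- rep(NA_real_, length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    if (format == "consequence_table") {
      if (length(f) != 5) {
        stop("malformed detectability row ", i, ": expected peptide + 4 verdicts")
      }
      v <- suppressWarnings(as.integer(f[2:5]))
      if (anyNA(v) || any(!v %in% c(0L, 1L))) {
        stop("malformed detectability row ", i, ": verdicts must be 0 or 1")
      }
      peptide[i] <- f[1]
      votes[i] <- sum(v)
    } else {
      if (length(f) != 2) {
        stop("malformed detectability row ", i, ": expected peptide + probability")
      }
      p <- suppressWarnings(as.numeric(f[2]))
      if (is.na(p)) stop("malformed detectability row ", i)
      if (p < 0 || p > 1) {
        stop("detectability probability outside [0,1] at row ", i, ": ", p)
      }
      peptide[i] <- f[1]
      prob[i] <- p
    }
  }
  data.frame(peptide = peptide, votes = votes,
             external_probability = prob, stringsAsFactors = FALSE)
}

#' Apply the peptide property filters
#'
#' A candidate passes iff it has no ambiguity codes, gathers at least
#' `votes_required` detectability votes (default 1), its external detection
#' probability (when present) is at least `probability_threshold` (default
#' 0.5), it carries at most `max_mod_sites` modification-prone sites
#' (default 3, i.e. only more than three is rejected), and its specificity
#' score passes (score >= `specificity_threshold` when scored; peptides
#' with no exact BLAST hits, skipped peptides and allowlisted peptides are
#' exempt). Rejected peptides are assigned their FIRST failing reason in
#' the fixed order ambiguous -> detectability -> modifications ->
#' specificity, and additionally carry the full set of failing reasons.
#'
#' @param candidates Data frame carrying columns `sequence`,
#'   `has_ambiguous`, `votes`, `external_probability`, `mod_total`,
#'   `spec_score`, `spec_status`.
#' @param votes_required Minimum detectability votes (default 1).
#' @param probability_threshold Minimum external detection probability when
#'   available (default 0.5).
#' @param max_mod_sites Maximum allowed modification-prone sites
#'   (default 3).
#' @param specificity_threshold Minimum specificity score in percent
#'   (default 90).
#' @param allowlist Peptides exempt from the specificity filter.
#' @return A list with `passing` (data.frame), `rejected` (data.frame with
#'   `first_reason` and `all_reasons`), and `counts` (named integer vector
#'   of rejections per reason).
#' @export
apply_property_filters <- function(candidates,
                                   votes_required = 1L,
                                   probability_threshold = 0.5,
                                   max_mod_sites = 3L,
                                   specificity_threshold = 90,
                                   allowlist = character(0)) {
  n <- nrow(candidates)
  ext <- candidates$external_probability %||% rep(NA_real_, n)
  status <- candidates$spec_status %||% rep("skipped", n)
  score <- candidates$spec_score %||% rep(NA_real_, n)

  r_amb <- candidates$has_ambiguous
  r_det <- candidates$votes < votes_required |
    (!is.na(ext) & ext < probability_threshold)
  r_mod <- candidates$mod_total > max_mod_sites
  allow <- candidates$sequence %in% allowlist
  r_spec <- !allow & status == "scored" & !is.na(score) &
    score < specificity_threshold

  reasons <- cbind(ambiguous = r_amb, detectability = r_det,
                   modifications = r_mod, specificity = r_spec)
  fail <- rowSums(reasons) > 0
  first_reason <- rep(NA_character_, n)
  all_reasons <- rep(NA_character_, n)
  for (i in which(fail)) {
    rs <- colnames(reasons)[reasons[i, ]]
    first_reason[i] <- rs[1]
    all_reasons[i] <- paste(rs, collapse = ";")
  }
  rejected <- candidates[fail, , drop = FALSE]
  rejected$first_reason <- first_reason[fail]
  rejected$all_reasons <- all_reasons[fail]
  counts <- vapply(colnames(reasons),
                   function(r) sum(first_reason == r, na.rm = TRUE),
                   integer(1))
  list(passing = candidates[!fail, , drop = FALSE],
       rejected = rejected,
       counts = counts)
}

#' Write the chemical-modification report
#'
#' Writes a tab-delimited `possible_chemical_modifications.txt`-style file
#' with per-type and total modification-site counts for every candidate.
#'
#' @param mod_profile Output of [count_modification_sites()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_modification_report <- function(mod_profile, path) {
  write_tsv_file(mod_profile, path)
}
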
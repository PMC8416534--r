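# Independent oracles and small builders used across tests. The oracles are
# deliberately written with naive character-by-character / exhaustive logic,
# independent of the package implementation paths they check.

# Brute-force tryptic digestion: walk the sequence one residue at a time,
# closing a fragment after each K/R (unless followed by P when the proline
# rule is on), then join runs of up to mc+1 consecutive fragments.
oracle_fragments <- function(seq, proline_rule = TRUE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(ch)) {
    cur <- paste0(cur, ch[i])
    cleave <- (ch[i] == "K" || ch[i] == "R") && i < length(ch)
    if (cleave && proline_rule && ch[i + 1] == "P") cleave <- FALSE
    if (cleave) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  if (nzchar(cur)) frags <- c(frags, cur)
  frags
}

oracle_digest <- function(seq, missed_cleavages = 0, proline_rule = TRUE) {
  frags <- oracle_fragments(seq, proline_rule)
  pep <- character(0)
  mc <- integer(0)
  for (i in seq_along(frags)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > length(frags)) next
      pep <- c(pep, paste(frags[i:j], collapse = ""))
      mc <- c(mc, m)
    }
  }
  data.frame(peptide = pep, missed_cleavages = mc, stringsAsFactors = FALSE)
}

random_aa_sequence <- function(max_len = 200) {
  n <- sample.int(max_len - 1, 1) + 1
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Exhaustive maximum-coverage oracle over taxa bitmasks: for every subset
# size k, the best achievable number of covered taxa.
POPCOUNT12 <- Reduce(`+`, lapply(0:11, function(b) {
  bitwAnd(bitwShiftR(0:4095, b), 1L)
}))

bruteforce_coverage <- function(masks) {
  n <- length(masks)
  stopifnot(n <= 12)
  nsub <- bitwShiftL(1L, n)
  subsets <- 1:(nsub - 1L)
  bit_of <- as.integer(log2(bitwAnd(subsets, -subsets))) + 1L
  rest <- bitwAnd(subsets, subsets - 1L)
  orv <- integer(nsub)
  for (s in subsets) {
    orv[s + 1L] <- bitwOr(orv[rest[s] + 1L], masks[bit_of[s]])
  }
  sizev <- POPCOUNT12[subsets + 1L]
  cov <- POPCOUNT12[orv[subsets + 1L] + 1L]
  best <- vapply(seq_len(n), function(k) max(cov[sizev == k]), integer(1))
  # best coverage for "at most k" picks is nondecreasing in k
  cummax(best)
}

# data.frame of candidate rows with taxa list-columns, as greedy_select
# expects them.
make_candidates <- function(sets, occurrence = NULL, sequences = NULL) {
  n <- length(sets)
  sequences <- sequences %||% sprintf("PEPTIDE%02dK", seq_len(n))
  df <- data.frame(
    sequence = sequences,
    occurrence = occurrence %||% rep(1, n),
    n_species = lengths(sets),
    stringsAsFactors = FALSE
  )
  df$genus_set <- sets
  df$species_set <- sets
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_records <- function(sequences, species = NA, genus = NA,
                         copy_number = 1, phylum = NA,
                         putative = FALSE, ids = NULL) {
  n <- length(sequences)
  data.frame(
    record_id = ids %||% sprintf("R%03d", seq_len(n)),
    description = ifelse(rep_len(putative, n), "Putative test protein",
                         "Test protein"),
    sequence = sequences,
    length = nchar(sequences),
    organism = rep_len(as.character(species), n),
    genus = rep_len(as.character(genus), n),
    species = rep_len(as.character(species), n),
    phylum = rep_len(as.character(phylum), n),
    copy_number = rep_len(copy_number, n),
    source = "reference",
    putative_flag = rep_len(putative, n),
    stringsAsFactors = FALSE
  )
}

write_family_inputs <- function(fam, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  fa <- file.path(dir, "family.faa")
  writeLines(fam$fasta_text, fa)
  md <- file.path(dir, "metadata.tsv")
  utils::write.table(fam$metadata, md, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fa, metadata = md, dir = dir)
}
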
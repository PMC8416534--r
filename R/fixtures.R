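# Synthetic homolog families and BLAST fixtures with known ground truth.
# Every pipeline stage is testable offline against these generators.

# Backbone interior residues deliberately exclude K/R/P (so tryptic peptide
# boundaries coincide exactly with construction blocks) and the
# modification-prone set M/W/C/N/Q (so planted peptides are the only source
# of modification-filter violations and category counts are exact).
AA_BACKBONE <- c("A", "D", "E", "F", "G", "H", "I", "L", "S", "T", "V", "Y")

validate_planted_peptide <- function(p) {
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) stop("planted peptide too short: ", p)
  if (!ch[n] %in% c("K", "R")) {
    stop("planted peptide must end in K or R (tryptic product): ", p)
  }
  if (ch[1] == "P") {
    stop("planted peptide must not start with P ",
         "(would suppress the upstream cleavage): ", p)
  }
  internal <- which(ch[-n] %in% c("K", "R"))
  bad <- internal[ch[internal + 1L] != "P"]
  if (length(bad) > 0) {
    stop("planted peptide contains an internal cleavage site: ", p)
  }
  mutable <- which(!(ch %in% c("K", "R", "P")) & seq_len(n) < n)
  if (length(mutable) == 0) {
    stop("planted peptide has no mutable interior residue: ", p)
  }
  invisible(TRUE)
}

#' Specify a synthetic homolog protein family
#'
#' Describes the study conditions a generated family should emulate: how
#' many proteins, species, genera and phyla, the backbone length, the
#' per-residue substitution rate between species, which tryptic peptides
#' are planted in which fraction of species, and the fractions of length
#' outliers and putative-annotated entries.
#'
#' @param n_proteins,n_species,n_genera,n_phyla Family sizes.
#' @param backbone_length Approximate backbone length in residues.
#' @param mutation_rate Per-residue substitution probability between
#'   species variants, in addition to one forced substitution per
#'   non-planted tryptic block (default 0.02).
#' @param planted_peptides Named numeric vector: names are tryptic peptide
#'   sequences (must end in K/R, contain no internal cleavage site, not
#'   start with P), values the fraction of species carrying each.
#' @param length_outlier_fraction Fraction of proteins lengthened by ~50%
#'   so they exceed the default 25% median-length tolerance (default 0).
#' @param putative_fraction Fraction of proteins whose description is
#'   prefixed "Putative" (default 0; disjoint from the outliers).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `family_spec` object.
#' @export
family_spec <- function(n_proteins = 60L, n_species = 20L, n_genera = 8L,
                        n_phyla = 3L, backbone_length = 300L,
                        mutation_rate = 0.02,
                        planted_peptides = NULL,
                        length_outlier_fraction = 0,
                        putative_fraction = 0,
                        seed = 1L) {
  stopifnot(n_proteins >= 1, n_species >= 1, n_genera >= 1, n_phyla >= 1,
            n_genera <= 26, backbone_length >= 30,
            mutation_rate >= 0, mutation_rate <= 1,
            length_outlier_fraction >= 0, length_outlier_fraction <= 1,
            putative_fraction >= 0, putative_fraction <= 1)
  if (!is.null(planted_peptides)) {
    if (is.null(names(planted_peptides)) ||
        any(!nzchar(names(planted_peptides)))) {
      stop("planted_peptides must be a named numeric vector ",
           "(names = peptides, values = species fractions)")
    }
    stopifnot(all(planted_peptides >= 0), all(planted_peptides <= 1))
    for (p in names(planted_peptides)) validate_planted_peptide(p)
  }
  structure(list(
    n_proteins = as.integer(n_proteins), n_species = as.integer(n_species),
    n_genera = as.integer(n_genera), n_phyla = as.integer(n_phyla),
    backbone_length = as.integer(backbone_length),
    mutation_rate = mutation_rate,
    planted_peptides = planted_peptides,
    length_outlier_fraction = length_outlier_fraction,
    putative_fraction = putative_fraction,
    seed = as.integer(seed)
  ), class = "family_spec")
}

random_block <- function(avoid = character(0)) {
  repeat {
    len <- sample(6:14, 1)
    b <- paste(c(sample(AA_BACKBONE, len - 1, replace = TRUE),
                 sample(c("K", "R"), 1)), collapse = "")
    if (!b %in% avoid) return(b)
  }
}

mutate_block <- function(block, forced, rate, positions = NULL) {
  ch <- strsplit(block, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (is.null(positions)) {
    positions <- which(!(ch %in% c("K", "R", "P")) & seq_len(n) < n)
  }
  if (length(positions) == 0) return(block)
  hit <- positions[stats::runif(length(positions)) < rate]
  if (forced && length(hit) == 0) {
    hit <- positions[sample.int(length(positions), 1)]
  }
  for (pos in hit) {
    ch[pos] <- sample(setdiff(AA_BACKBONE, ch[pos]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic homolog protein family with known ground truth
#'
#' Builds a backbone of tryptic blocks (interior residues drawn from a
#' 12-letter alphabet excluding K/R/P and the modification-prone residues),
#' inserts the planted peptides as intact blocks, then derives one variant
#' per species: every non-planted block receives at least one substitution
#' specific to the species (plus extra substitutions at `mutation_rate`),
#' while planted blocks stay untouched in carrier species and receive a
#' knockout substitution in non-carriers. Proteins are assigned to species
#' round-robin; length outliers gain ~50% extra blocks; putative entries
#' get a "Putative" description prefix. Generation is byte-reproducible
#' for a fixed seed, which is echoed in every FASTA header (`OX=` field).
#'
#' @param spec A [family_spec()].
#' @return A list with `fasta_text` (single string), `metadata` (data.frame
#'   sidecar with id/organism/phylum/protein_name) and `truth`: per-protein
#'   table (record_id, species, genus, phylum, length, is_outlier,
#'   is_putative) and per-planted-peptide carrier protein ids, species set
#'   and genus set.
#' @export
generate_homolog_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  planted <- names(spec$planted_peptides) %||% character(0)

  blocks <- character(0)
  total <- 0L
  while (total < spec$backbone_length) {
    b <- random_block(avoid = planted)
    blocks <- c(blocks, b)
    total <- total + nchar(b)
  }
  is_planted <- rep(FALSE, length(blocks))
  if (length(planted) > 0) {
    nb <- length(blocks)
    anchors <- pmax(1L, floor(seq_along(planted) * nb /
                                (length(planted) + 1L)))
    for (j in seq_along(planted)) {
      at <- anchors[j] + (j - 1L)  # account for prior insertions
      blocks <- append(blocks, planted[j], after = at)
      is_planted <- append(is_planted, TRUE, after = at)
    }
  }
  planted_block_idx <- stats::setNames(which(is_planted), planted)

  genera <- paste0("Genus", LETTERS[seq_len(spec$n_genera)])
  phyla <- paste0("Phylum", seq_len(spec$n_phyla))
  genus_of_species <- genera[((seq_len(spec$n_species) - 1L) %%
                                spec$n_genera) + 1L]
  phylum_of_genus <- stats::setNames(
    phyla[((seq_len(spec$n_genera) - 1L) %% spec$n_phyla) + 1L], genera)
  species_names <- paste0(genus_of_species, " species",
                          sprintf("%02d", seq_len(spec$n_species)))

  carriers <- lapply(spec$planted_peptides, function(f) {
    m <- as.integer(ceiling(f * spec$n_species))
    seq_len(m)
  })

  species_blocks <- vector("list", spec$n_species)
  for (s in seq_len(spec$n_species)) {
    bl <- blocks
    for (j in seq_along(bl)) {
      if (is_planted[j]) {
        pep <- bl[j]
        if (!(s %in% carriers[[pep]])) {
          ch <- strsplit(pep, "", fixed = TRUE)[[1]]
          mutable <- which(!(ch %in% c("K", "R", "P")) &
                             seq_along(ch) < length(ch))
          pos <- mutable[sample.int(length(mutable), 1)]
          ch[pos] <- sample(setdiff(AA_BACKBONE, ch[pos]), 1)
          bl[j] <- paste(ch, collapse = "")
        }
      } else {
        bl[j] <- mutate_block(bl[j], forced = TRUE,
                              rate = spec$mutation_rate)
        # a mutated block must never collide with a planted peptide
        while (bl[j] %in% planted) {
          bl[j] <- mutate_block(blocks[j], forced = TRUE,
                                rate = spec$mutation_rate)
        }
      }
    }
    species_blocks[[s]] <- bl
  }

  np <- spec$n_proteins
  prot_species <- ((seq_len(np) - 1L) %% spec$n_species) + 1L
  n_out <- round(spec$length_outlier_fraction * np)
  outlier_idx <- if (n_out > 0) utils::tail(seq_len(np), n_out) else integer(0)
  n_put <- round(spec$putative_fraction * np)
  putative_idx <- utils::head(setdiff(seq_len(np), outlier_idx), n_put)

  ids <- sprintf("P%05d", seq_len(np))
  fasta <- character(0)
  lengths_out <- integer(np)
  base_desc <- "Synthetic dioxygenase family protein"
  for (i in seq_len(np)) {
    s <- prot_species[i]
    bl <- species_blocks[[s]]
    if (i %in% outlier_idx) {
      extra <- character(0)
      extra_len <- 0L
      target <- ceiling(0.5 * spec$backbone_length)
      while (extra_len < target) {
        b <- random_block(avoid = planted)
        extra <- c(extra, b)
        extra_len <- extra_len + nchar(b)
      }
      bl <- c(bl, extra)
    }
    seq_i <- paste(bl, collapse = "")
    lengths_out[i] <- nchar(seq_i)
    desc <- if (i %in% putative_idx) paste("Putative", base_desc) else base_desc
    hdr <- sprintf(">sp|%s|SYN%d_SP%02d %s OS=%s OX=%d",
                   ids[i], i, s, desc, species_names[s], spec$seed)
    fasta <- c(fasta, hdr, wrap_fasta(seq_i))
  }

  proteins <- data.frame(
    record_id = ids,
    species = species_names[prot_species],
    genus = genus_of_species[prot_species],
    phylum = unname(phylum_of_genus[genus_of_species[prot_species]]),
    length = lengths_out,
    is_outlier = seq_len(np) %in% outlier_idx,
    is_putative = seq_len(np) %in% putative_idx,
    stringsAsFactors = FALSE
  )
  present_species <- unique(prot_species)
  planted_truth <- lapply(planted, function(p) {
    cs <- intersect(carriers[[p]], present_species)
    list(
      peptide = p,
      carrier_proteins = ids[prot_species %in% cs],
      species_set = sort(species_names[cs], method = "radix"),
      genus_set = sort(unique(genus_of_species[cs]), method = "radix")
    )
  })
  names(planted_truth) <- planted

  metadata <- data.frame(
    id = ids,
    organism = species_names[prot_species],
    phylum = proteins$phylum,
    protein_name = base_desc,
    stringsAsFactors = FALSE
  )

  list(
    fasta_text = paste(fasta, collapse = "\n"),
    metadata = metadata,
    truth = list(proteins = proteins, planted = planted_truth,
                 backbone_blocks = blocks, seed = spec$seed,
                 species_names = species_names,
                 genera = genera, phyla = phyla),
    spec = spec
  )
}

#' Re-emit a generated family as a custom (metagenome-style) FASTA
#'
#' Converts selected proteins of a generated family into custom-dialect
#' FASTA text with SPAdes-style coverage tokens in the headers, for
#' exercising the copy-number parsing and intersection modes.
#'
#' @param family Output of [generate_homolog_family()].
#' @param indices Which proteins to emit (default all).
#' @param coverages Numeric coverage token per emitted protein (recycled).
#' @return FASTA text as a single string.
#' @export
custom_fasta_from_family <- function(family, indices = NULL,
                                     coverages = 1) {
  fasta_lines <- strsplit(family$fasta_text, "\n", fixed = TRUE)[[1]]
  hdr_at <- which(startsWith(fasta_lines, ">"))
  ends <- c(hdr_at[-1] - 1L, length(fasta_lines))
  indices <- indices %||% seq_along(hdr_at)
  coverages <- rep_len(coverages, length(indices))
  out <- character(0)
  for (j in seq_along(indices)) {
    i <- indices[j]
    seq_i <- paste(fasta_lines[(hdr_at[i] + 1L):ends[i]], collapse = "")
    out <- c(out,
             sprintf(">NODE_%d_length_%d_cov_%s synthetic dioxygenase contig",
                     j, nchar(seq_i), format(coverages[j])),
             wrap_fasta(seq_i))
  }
  paste(out, collapse = "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a BLAST XML fixture with known specificity ground truth
#'
#' Emits standard-schema BLAST XML in which each query peptide receives
#' `n_hits` exact full-length hits, a chosen fraction of which carry the
#' target protein name (the rest carry `off_target_name`), plus
#' `n_partial` near-miss hits (one mismatch) that exact-hit selection must
#' discard. When `synonym_aliases` are given, the first on-target hit
#' bundles the target name with each alias and subsequent even-numbered
#' on-target hits carry the alias alone, so scoring those hits as matching
#' requires synonym inference to succeed.
#'
#' @param peptides Character vector of query peptides.
#' @param on_target_fraction Fraction of exact hits that are on-target
#'   (recycled over peptides).
#' @param n_hits Exact hits per peptide (recycled); 0 yields a query with
#'   no hits (expected status `no_hits`).
#' @param target_name Target protein name written on on-target deflines.
#' @param synonym_aliases Alias names to plant via bundled deflines.
#' @param off_target_name Name used for off-target hits.
#' @param n_partial Near-miss (non-exact) hits per peptide (default 1).
#' @return A list with `xml_text` and `expected`, a data.frame of the
#'   constructed per-peptide `total_exact_hits`, `matching_hits`, `score`
#'   and `status`.
#' @export
generate_blast_fixture <- function(peptides, on_target_fraction = 1,
                                   n_hits = 10L,
                                   target_name = "synthetic dioxygenase",
                                   synonym_aliases = character(0),
                                   off_target_name = "hypothetical protein",
                                   n_partial = 1L) {
  stopifnot(all(on_target_fraction >= 0), all(on_target_fraction <= 1),
            all(n_hits >= 0))
  frac <- rep_len(on_target_fraction, length(peptides))
  nh <- rep_len(as.integer(n_hits), length(peptides))

  xml <- c('<?xml version="1.0"?>',
           "<BlastOutput>",
           "  <BlastOutput_program>blastp</BlastOutput_program>",
           "  <BlastOutput_version>synthetic fixture</BlastOutput_version>",
           "  <BlastOutput_iterations>")
  exp_total <- integer(length(peptides))
  exp_match <- integer(length(peptides))
  hit_counter <- 0L
  for (i in seq_along(peptides)) {
    p <- peptides[i]
    len <- nchar(p)
    n_on <- as.integer(round(frac[i] * nh[i]))
    exp_total[i] <- nh[i]
    exp_match[i] <- n_on
    xml <- c(xml,
             "    <Iteration>",
             sprintf("      <Iteration_iter-num>%d</Iteration_iter-num>", i),
             sprintf("      <Iteration_query-def>%s</Iteration_query-def>", p),
             sprintf("      <Iteration_query-len>%d</Iteration_query-len>", len),
             "      <Iteration_hits>")
    emit_hit <- function(defline, identities, align_len) {
      hit_counter <<- hit_counter + 1L
      c("        <Hit>",
        sprintf("          <Hit_num>%d</Hit_num>", hit_counter),
        sprintf("          <Hit_id>gnl|syn|%d</Hit_id>", hit_counter),
        sprintf("          <Hit_def>%s</Hit_def>", defline),
        sprintf("          <Hit_len>%d</Hit_len>", 300L),
        "          <Hit_hsps>",
        "            <Hsp>",
        "              <Hsp_num>1</Hsp_num>",
        sprintf("              <Hsp_identity>%d</Hsp_identity>", identities),
        sprintf("              <Hsp_align-len>%d</Hsp_align-len>", align_len),
        "              <Hsp_gaps>0</Hsp_gaps>",
        "            </Hsp>",
        "          </Hit_hsps>",
        "        </Hit>")
    }
    for (j in seq_len(nh[i])) {
      if (j <= n_on) {
        defline <- if (length(synonym_aliases) > 0 && j == 1) {
          paste(c(xml_escape(target_name),
                  xml_escape(synonym_aliases)), collapse = " &gt;")
        } else if (length(synonym_aliases) > 0 && j %% 2 == 0) {
          xml_escape(synonym_aliases[((j / 2 - 1) %%
                                        length(synonym_aliases)) + 1])
        } else {
          xml_escape(target_name)
        }
      } else {
        defline <- xml_escape(off_target_name)
      }
      xml <- c(xml, emit_hit(defline, len, len))
    }
    if (len > 1) {
      for (j in seq_len(n_partial)) {
        xml <- c(xml, emit_hit(xml_escape(target_name), len - 1L, len))
      }
    }
    xml <- c(xml, "      </Iteration_hits>", "    </Iteration>")
  }
  xml <- c(xml, "  </BlastOutput_iterations>", "</BlastOutput>")

  expected <- data.frame(
    peptide = peptides,
    total_exact_hits = ifelse(exp_total > 0, exp_total, NA_integer_),
    matching_hits = ifelse(exp_total > 0, exp_match, NA_integer_),
    score = ifelse(exp_total > 0, 100 * exp_match / pmax(exp_total, 1),
                   NA_real_),
    status = ifelse(exp_total > 0, "scored", "no_hits"),
    stringsAsFactors = FALSE
  )
  list(xml_text = paste(xml, collapse = "\n"), expected = expected)
}

#' Generate an external detectability table fixture
#'
#' Emits a tab-delimited four-voter verdict table assigning a chosen number
#' of detectability votes to each peptide (votes fill from the first voter).
#'
#' @param peptides Character vector of peptides.
#' @param votes Integer votes (0-4) per peptide (recycled).
#' @return The table text as a single string.
#' @export
generate_detectability_fixture <- function(peptides, votes) {
  votes <- rep_len(as.integer(votes), length(peptides))
  stopifnot(all(votes >= 0), all(votes <= 4))
  rows <- vapply(seq_along(peptides), function(i) {
    v <- as.integer(seq_len(4) <= votes[i])
    paste(c(peptides[i], v), collapse = "\t")
  }, character(1))
  paste(c("peptide\tv1\tv2\tv3\tv4", rows), collapse = "\n")
}
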
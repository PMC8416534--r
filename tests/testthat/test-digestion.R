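# Tryptic digestion and the peptide -> taxa index.

test_that("digestion follows the K/R rule with proline suppression", {
  expect_equal(digest_trypsin("MKTAYIAKQR")$peptide, c("MK", "TAYIAK", "QR"))
  expect_equal(digest_trypsin("AKRPCK")$peptide, c("AK", "RPCK"))
  expect_equal(digest_trypsin("AAAA")$peptide, "AAAA")
  expect_equal(digest_trypsin("AAAA", missed_cleavages = 3)$peptide, "AAAA")
  # proline rule off restores the suppressed site
  expect_equal(digest_trypsin("AKRPCK", proline_rule = FALSE)$peptide,
               c("AK", "R", "PCK"))
  expect_error(digest_trypsin(""), "non-empty")
})

test_that("missed cleavages add every run of adjacent fragments", {
  d <- digest_trypsin("MKTAYIAKQR", missed_cleavages = 1)
  expect_setequal(d$peptide[d$missed_cleavages == 0],
                  c("MK", "TAYIAK", "QR"))
  expect_setequal(d$peptide[d$missed_cleavages == 1],
                  c("MKTAYIAK", "TAYIAKQR"))
  d2 <- digest_trypsin("MKTAYIAKQR", missed_cleavages = 5)
  expect_true("MKTAYIAKQR" %in% d2$peptide)
  expect_equal(max(d2$missed_cleavages), 2)
})

test_that("digestion equals the brute-force oracle on seeded random sequences", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_aa_sequence(120)
    for (mc in 0:2) {
      for (pr in c(TRUE, FALSE)) {
        got <- digest_trypsin(s, mc, pr)
        want <- oracle_digest(s, mc, pr)
        got <- got[order(got$peptide, got$missed_cleavages), ]
        want <- want[order(want$peptide, want$missed_cleavages), ]
        expect_equal(got$peptide, want$peptide)
        expect_equal(got$missed_cleavages, want$missed_cleavages)
      }
    }
    # mc=0 concatenation reconstructs the input
    base <- digest_trypsin(s, 0, TRUE)
    expect_equal(paste(base$peptide, collapse = ""), s)
    # terminal rule: every non-C-terminal fragment ends in K or R and no
    # internal K/R except before P
    peps <- base$peptide
    if (length(peps) > 1) {
      expect_true(all(grepl("[KR]$", peps[-length(peps)])))
    }
    expect_false(any(grepl("[KR](?!P)", substr(peps, 1, nchar(peps) - 1),
                           perl = TRUE)))
  }
})

test_that("peptide index accumulates parents, copy-weighted occurrence and taxa", {
  recs <- make_records(
    c("MMMMMMMKTAYIAKQQQQQQR",   # peptides TAYIAK shared
      "MMMMMMMKTAYIAKWWWWWWR"),
    ids = c("A1", "B1"))
  recs$species <- c("Alpha one", "Beta two")
  recs$genus <- c("Alpha", "Beta")
  idx <- build_peptide_index(recs, min_len = 6, max_len = 10)
  e <- idx$entries
  shared <- e[e$sequence == "TAYIAK", ]
  expect_equal(shared$n_parents, 2)
  expect_equal(shared$occurrence, 2)
  expect_equal(shared$species_set[[1]], c("Alpha one", "Beta two"))
  expect_equal(shared$genus_set[[1]], c("Alpha", "Beta"))
  # SQSDFNLR (8 residues) is retained under the default 8-25 bounds
  r2 <- make_records("MMMMMMMKSQSDFNLRTTTTTTTTTK")
  idx2 <- build_peptide_index(r2)
  expect_true("SQSDFNLR" %in% idx2$entries$sequence)

  # copy weighting: a repeated peptide in one protein counts once, but
  # copy numbers multiply
  r3 <- make_records("MMMMMMMKTAYIAKTAYIAKQQQQQQR", copy_number = 5)
  idx3 <- build_peptide_index(r3, min_len = 6, max_len = 10)
  expect_equal(idx3$entries$occurrence[idx3$entries$sequence == "TAYIAK"], 5)

  # ambiguity codes are indexed but flagged
  r4 <- make_records("MMMMMMMKAXNDLLKQQQQQQR")
  idx4 <- build_peptide_index(r4, min_len = 6, max_len = 10)
  ax <- idx4$entries[idx4$entries$sequence == "AXNDLLK", ]
  expect_true(ax$has_ambiguous)

  # unknown-taxonomy parents count toward occurrence, not species
  r5 <- make_records(c("MMMMMMMKTAYIAKQQQQQQR", "MMMMMMMKTAYIAKQQQQQQR"),
                     ids = c("A1", "B1"))
  r5$species <- c("Alpha one", NA)
  idx5 <- build_peptide_index(r5, min_len = 6, max_len = 10)
  t5 <- idx5$entries[idx5$entries$sequence == "TAYIAK", ]
  expect_equal(t5$occurrence, 2)
  expect_equal(t5$n_species, 1)

  expect_error(build_peptide_index(recs[0, ]), "empty")
})

test_that("candidate ranking is a deterministic total order", {
  sets <- list(paste0("s", 1:5), paste0("s", 1:4), paste0("s", 1))
  recs <- make_records(c("MMMMMMMKTAYIAKQQQQQQR"))
  idx <- build_peptide_index(recs, min_len = 6, max_len = 10)
  # construct an index by hand to control counts precisely
  e <- idx$entries[rep(1, 3), ]
  e$sequence <- c("PEPB", "PEPA", "PEPC")
  e$n_species <- c(73L, 68L, 68L)
  e$occurrence <- c(199, 357, 357)
  idx$entries <- e
  top2 <- rank_candidates(idx, n = 2, key = "species_count")
  expect_equal(top2$sequence, c("PEPB", "PEPA"))

  # all-equal key: lexicographic tie-break
  e$n_species <- 5L
  e$occurrence <- 1
  idx$entries <- e
  top <- rank_candidates(idx, n = 3, key = "species_count")
  expect_equal(top$sequence, c("PEPA", "PEPB", "PEPC"))

  # occurrence key for copy-weighted custom data
  e$occurrence <- c(2, 13, 2)
  idx$entries <- e
  idx$provenance <- "custom"
  expect_equal(rank_candidates(idx, n = 1)$sequence, "PEPA")
  expect_equal(attr(rank_candidates(idx, n = 1), "rank_key"), "occurrence")

  # stability under permutation of the input rows
  idx2 <- idx
  idx2$entries <- e[c(3, 1, 2), ]
  expect_equal(rank_candidates(idx, n = 3)$sequence,
               rank_candidates(idx2, n = 3)$sequence)
  # n beyond the index size returns everything
  expect_equal(nrow(rank_candidates(idx, n = 100)), 3)
})

test_that("intersection keeps shared peptides with reference taxonomy and custom weights", {
  ref <- make_records("MMMMMMMRIAAFLSCSNKTEVTIYCIAPK", ids = "U1")
  ref$species <- "Pseudomonas xanthomarina"
  ref$genus <- "Pseudomonas"
  cus <- make_records("GGGGGGGRIAAFLSCSNKLWAAWMHR", ids = "N1")
  cus$species <- NA
  cus$genus <- NA
  cus$source <- "custom"
  cus$copy_number <- 4
  ridx <- build_peptide_index(ref, provenance = "reference")
  cidx <- build_peptide_index(cus, provenance = "custom")
  both <- intersect_with_reference(cidx, ridx)
  expect_equal(both$entries$sequence, "IAAFLSCSNK")
  expect_equal(both$entries$species_set[[1]], "Pseudomonas xanthomarina")
  expect_equal(both$entries$occurrence, 4)
  expect_equal(both$provenance, "intersected")
  # intersection is a subset of each input and commutative in key set
  expect_true(all(both$entries$sequence %in% ridx$entries$sequence))
  expect_true(all(both$entries$sequence %in% cidx$entries$sequence))

  # identical indexes intersect to themselves
  self <- intersect_with_reference(ridx, ridx)
  expect_setequal(self$entries$sequence, ridx$entries$sequence)

  # disjoint indexes yield an empty index with a warning
  other <- make_records("MMMMMMMKGGGGGGGGGK")
  oidx <- build_peptide_index(other, provenance = "custom")
  expect_warning(empty <- intersect_with_reference(oidx, ridx), "no peptide")
  expect_equal(nrow(empty$entries), 0)

  # mismatched length bounds are an error
  short <- build_peptide_index(cus, min_len = 6, provenance = "custom")
  expect_error(intersect_with_reference(short, ridx), "length bounds")
})
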
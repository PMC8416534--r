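# BLAST parsing, name normalization, synonym inference and specificity scores.

test_that("protein-name normalization collapses punctuation and database tags", {
  expect_equal(normalize_protein_name("Catechol-1,2-dioxygenase"),
               "catechol 1 2 dioxygenase")
  n <- "catechol 1 2 dioxygenase"
  expect_equal(normalize_protein_name(n), n)  # idempotent
  expect_equal(normalize_protein_name("MULTISPECIES: benzoate 1,2-dioxygenase"),
               "benzoate 1 2 dioxygenase")
  expect_equal(normalize_protein_name("catechol_1/2-dioxygenase,  extra"),
               "catechol 1 2 dioxygenase extra")
})

test_that("BLAST XML fixtures parse with numeric fields and split deflines", {
  fix <- generate_blast_fixture(c("SQSDFNLR", "TEVTIYCIAPK"),
                                on_target_fraction = c(0.5, 1),
                                n_hits = c(4L, 3L),
                                target_name = "catechol-1,2-dioxygenase",
                                synonym_aliases = "CatA")
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(fix$xml_text, xml)
  hits <- parse_blast_hits(xml)
  expect_setequal(unique(hits$query_peptide), c("SQSDFNLR", "TEVTIYCIAPK"))
  expect_true(all(hits$identities <= hits$align_length))
  expect_true(all(hits$gaps == 0))
  # the bundled defline splits into target + alias
  bundled <- hits$deflines[[which(vapply(hits$deflines, length,
                                         integer(1)) > 1)[1]]]
  expect_equal(bundled, c("catechol-1,2-dioxygenase", "CatA"))

  trunc <- withr::local_tempfile(fileext = ".xml")
  writeLines(substr(fix$xml_text, 1, 300), trunc)
  expect_error(parse_blast_hits(trunc), "malformed BLAST XML")
})

test_that("tabular BLAST results with subject titles parse equivalently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SQSDFNLR\tsbj1\t8\t8\t0\t0\tcatechol-1,2-dioxygenase",
    "SQSDFNLR\tsbj2\t7\t8\t1\t0\thypothetical protein"
  ), f)
  hits <- parse_blast_hits(f, "blast_tabular")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$identities, c(8L, 7L))
  expect_equal(hits$mismatches, c(0L, 1L))
  exact <- select_exact_hits(hits, 8)
  expect_equal(exact$subject_id, "sbj1")
})

test_that("exact-hit selection requires full-length gapless identity", {
  hits <- data.frame(
    query_peptide = "Q", subject_id = c("a", "b", "c", "d"),
    defline = "x", identities = c(10L, 9L, 8L, 10L),
    align_length = c(10L, 10L, 8L, 10L), gaps = c(0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  keep <- select_exact_hits(hits, 10)
  expect_equal(keep$subject_id, "a")  # partial 8/8 on a 10-mer is dropped
})

test_that("synonym inference recovers aliases from bundled deflines", {
  fix <- generate_blast_fixture("SQSDFNLR", 1, 4L,
                                target_name = "catechol-1,2-dioxygenase",
                                synonym_aliases = "CatA")
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(fix$xml_text, xml)
  hits <- parse_blast_hits(xml)
  syn <- build_synonym_set(hits, "catechol-1,2-dioxygenase")
  expect_true("cata" %in% syn)
  expect_true("catechol 1 2 dioxygenase" %in% syn)

  # no bundle contains the target -> synonym set is just the target
  off <- generate_blast_fixture("SQSDFNLR", 0, 4L,
                                target_name = "catechol-1,2-dioxygenase")
  xml2f <- withr::local_tempfile(fileext = ".xml")
  writeLines(off$xml_text, xml2f)
  syn2 <- build_synonym_set(parse_blast_hits(xml2f),
                            "catechol-1,2-dioxygenase")
  expect_equal(syn2, "catechol 1 2 dioxygenase")
})

test_that("specificity scores equal their constructed values exactly", {
  peps <- c("SQSDFNLR", "TEVTIYCIAPK", "LGQDGEAALLAAGLGLEK", "GHOSTPEPK")
  fix <- generate_blast_fixture(peps,
                                on_target_fraction = c(0.9, 1, 0.5, 0),
                                n_hits = c(10L, 4L, 8L, 0L),
                                target_name = "catechol-1,2-dioxygenase",
                                synonym_aliases = c("CatA"))
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(fix$xml_text, xml)
  hits <- parse_blast_hits(xml)
  expect_warning(
    rep <- compute_specificity(hits, peps, "catechol-1,2-dioxygenase"),
    "missing specificity")
  expect_equal(rep$score, fix$expected$score)
  expect_equal(rep$total_exact_hits, fix$expected$total_exact_hits)
  expect_equal(rep$matching_hits, fix$expected$matching_hits)
  expect_equal(rep$status, fix$expected$status)
  # 90% passes the default threshold under >= semantics
  flt <- apply_property_filters(data.frame(
    sequence = "SQSDFNLR", has_ambiguous = FALSE, votes = 1L,
    external_probability = NA_real_, mod_total = 0L,
    spec_score = rep$score[1], spec_status = "scored",
    stringsAsFactors = FALSE))
  expect_equal(nrow(flt$passing), 1)

  # allowlisted peptides are skipped; disabling scoring skips everything
  repa <- suppressWarnings(
    compute_specificity(hits, peps, "catechol-1,2-dioxygenase",
                        allowlist = "SQSDFNLR"))
  expect_equal(repa$status[repa$peptide == "SQSDFNLR"], "skipped")
  repoff <- compute_specificity(hits, peps, "catechol-1,2-dioxygenase",
                                enabled = FALSE)
  expect_true(all(repoff$status == "skipped"))
})

test_that("score monotonicity: matching hits raise, non-matching lower, synonyms never hurt", {
  base_hits <- function(n_on, n_off) {
    fix <- generate_blast_fixture("SQSDFNLR", n_on / (n_on + n_off),
                                  n_hits = n_on + n_off,
                                  target_name = "target enzyme")
    xml <- withr::local_tempfile(fileext = ".xml",
                                 .local_envir = parent.frame())
    writeLines(fix$xml_text, xml)
    parse_blast_hits(xml)
  }
  score_of <- function(h, syn = NULL) {
    suppressWarnings(compute_specificity(h, "SQSDFNLR", "target enzyme",
                                         synonyms = syn))$score
  }
  s1 <- score_of(base_hits(4, 4))
  s2 <- score_of(base_hits(5, 4))   # one more matching hit
  s3 <- score_of(base_hits(4, 5))   # one more non-matching hit
  expect_gt(s2, s1)
  expect_lt(s3, s1)
  # enlarging the synonym set can only raise the score
  h <- base_hits(4, 4)
  s_syn <- score_of(h, syn = c("target enzyme", "hypothetical protein"))
  expect_gte(s_syn, s1)
  expect_equal(s_syn, 100)
})

test_that("the short-name failure mode depresses scores until the threshold is lowered", {
  # most nr hits carry an unrelated short name; scores sit between 70 and 90
  target <- "benzoate-1,2-dioxygenase, alpha subunit"
  peps <- sprintf("BENZOPEP%02dK", 1:10)
  fix <- generate_blast_fixture(
    peps, on_target_fraction = c(rep(0.8, 8), 1, 1), n_hits = 10L,
    target_name = target,
    off_target_name = "Rieske 2Fe 2S domain containing protein")
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(fix$xml_text, xml)
  rep <- compute_specificity(parse_blast_hits(xml), peps, target)
  expect_true(mean(rep$score < 90) > 0.5)  # majority fail at 90
  cand <- data.frame(
    sequence = peps, has_ambiguous = FALSE, votes = 1L,
    external_probability = NA_real_, mod_total = 0L,
    spec_score = rep$score, spec_status = rep$status,
    stringsAsFactors = FALSE)
  at90 <- apply_property_filters(cand, specificity_threshold = 90)
  at70 <- apply_property_filters(cand, specificity_threshold = 70)
  expect_lt(nrow(at90$passing), nrow(cand) / 2)
  expect_equal(nrow(at70$passing), nrow(cand))
})
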
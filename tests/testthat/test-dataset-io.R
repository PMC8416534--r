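# Parsing, metadata merging, pre-filters and dataset summaries.

write_fasta_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".faa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("UniProt headers yield organism, genus and species from OS=", {
  f <- write_fasta_tmp(c(
    ">sp|P00001|CDO_PSEPU Catechol-1,2-dioxygenase OS=Pseudomonas putida OX=303",
    "MSEQKNNTAVK",
    ">tr|Q9ABC1|Q9ABC1_ACIBA Catechol-1,2-dioxygenase OS=Acinetobacter baumannii ATCC 17978 OX=400667 GN=catA",
    "MTTHKSNNAVR"
  ))
  rec <- read_protein_fasta(f, dialect = "uniprot")
  expect_equal(rec$record_id, c("P00001", "Q9ABC1"))
  expect_equal(rec$organism[1], "Pseudomonas putida")
  expect_equal(rec$genus, c("Pseudomonas", "Acinetobacter"))
  expect_equal(rec$species,
               c("Pseudomonas putida", "Acinetobacter baumannii"))
  expect_equal(rec$description[1], "Catechol-1,2-dioxygenase")
  expect_equal(rec$length, nchar(rec$sequence))
  expect_equal(rec$copy_number, c(1, 1))
  expect_false(any(rec$putative_flag))
})

test_that("organisms without a usable binomial are taxonomy-absent", {
  f <- write_fasta_tmp(c(
    ">sp|P00002|X_UNC uncharacterized protein OS=uncultured bacterium OX=77133",
    "MKTAYIAKQR"
  ))
  rec <- read_protein_fasta(f, dialect = "uniprot")
  expect_true(is.na(rec$organism))
  expect_true(is.na(rec$genus))
  expect_true(is.na(rec$species))
})

test_that("custom dialect parses copy-number tokens and flags putative", {
  f <- write_fasta_tmp(c(
    ">NODE_7_length_900_cov_12.5 catechol-2,3-dioxygenase",
    "MKTAYIAKQR",
    ">contig_2 copies=4 Putative ring-cleaving dioxygenase",
    "MTTHKSNNAVR",
    ">contig_3 plain protein",
    "MAAAGGGK"
  ))
  rec <- read_protein_fasta(f, dialect = "custom")
  expect_equal(rec$copy_number, c(13, 4, 1))  # ceiling(12.5) = 13
  expect_true(all(is.na(rec$species)))
  expect_equal(rec$putative_flag, c(FALSE, TRUE, FALSE))
  expect_equal(rec$source, rep("custom", 3))
})

test_that("malformed FASTA inputs raise informative errors", {
  notfasta <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("this is not", "a fasta file"), notfasta)
  expect_error(read_protein_fasta(notfasta), "not FASTA")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), empty)
  expect_error(read_protein_fasta(empty), "empty")

  emptyseq <- write_fasta_tmp(c(">a protein", ">b other", "MKTAYIAK"))
  expect_error(read_protein_fasta(emptyseq), "empty sequence")

  badchar <- write_fasta_tmp(c(">a protein", "MKTA*YIAK"))
  expect_error(read_protein_fasta(badchar), "offending characters: \\*")
})

test_that("metadata merging fills phylum without touching existing fields", {
  f <- write_fasta_tmp(c(
    ">sp|P00001|A_B Catechol-1,2-dioxygenase OS=Pseudomonas putida OX=303",
    "MKTAYIAKQR"
  ))
  rec <- read_protein_fasta(f)
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tphylum\torganism",
               "P00001\tProteobacteria\tWrongis organismus",
               "P99999\tFirmicutes\tAbsentis entirely"), tab)
  expect_warning(out <- merge_metadata(rec, tab), "1 metadata row")
  expect_equal(out$phylum, "Proteobacteria")
  expect_equal(out$organism, "Pseudomonas putida")  # not overwritten
  expect_equal(attr(out, "n_unmatched"), 1)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tphylum", "P00001\tA", "P00001\tB"), dup)
  expect_error(merge_metadata(rec, dup), "duplicate")

  noid <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("acc\tphylum", "P00001\tA"), noid)
  expect_error(merge_metadata(rec, noid), "'id' column")
})

test_that("length filter keeps records within the median interval, boundary inclusive", {
  lens <- c(100, rep(300, 10), 380)
  recs <- make_records(vapply(lens, function(n) {
    paste(rep("A", n), collapse = "")
  }, character(1)))
  out <- filter_by_length(recs, tolerance_pct = 25)
  expect_equal(out$median, 300)
  expect_equal(sort(out$kept$length), rep(300, 10))
  expect_equal(sort(out$removed$length), c(100, 380))
  # partition preserves input order
  expect_equal(c(out$kept$record_id, out$removed$record_id)[
    order(match(c(out$kept$record_id, out$removed$record_id),
                recs$record_id))], recs$record_id)

  # boundary: with median 305 and 25% tolerance a 229-residue protein stays
  lens2 <- c(229, 305, 305, 305, 371)
  recs2 <- make_records(strrep("A", lens2))
  out2 <- filter_by_length(recs2, 25)
  expect_equal(out2$median, 305)
  expect_true(229 %in% out2$kept$length)
  expect_true(371 %in% out2$kept$length)

  expect_error(filter_by_length(recs[0, ]), "no protein records")
  expect_error(filter_by_length(recs, -5), "non-negative")
})

test_that("length filter is a permutation-stable partition for random inputs", {
  set.seed(11)
  for (rep_i in 1:20) {
    lens <- sample(50:500, sample(3:40, 1), replace = TRUE)
    recs <- make_records(strrep("A", lens))
    tol <- sample(c(0, 10, 25, 50), 1)
    out <- filter_by_length(recs, tol)
    expect_equal(nrow(out$kept) + nrow(out$removed), nrow(recs))
    m <- median(lens)
    expect_true(all(abs(out$kept$length - m) <= m * tol / 100))
    expect_true(all(abs(out$removed$length - m) > m * tol / 100))
  }
})

test_that("putative filter moves flagged records only when enabled", {
  recs <- make_records(c("MKTAYIAKQR", "MTTHKSNNAVR"),
                       putative = c(TRUE, FALSE))
  off <- filter_putative(recs, enabled = FALSE)
  expect_equal(nrow(off$kept), 2)
  on <- filter_putative(recs, enabled = TRUE)
  expect_equal(nrow(on$removed), 1)
  expect_true(on$removed$putative_flag)
  none <- filter_putative(recs[!recs$putative_flag, ], enabled = TRUE)
  expect_equal(nrow(none$removed), 0)
})

test_that("dataset summary reports lengths, taxa counts and conservation", {
  recs <- make_records(strrep("A", c(10, 20, 30, 40)))
  recs$phylum <- c("A", "A", "A", "B")
  recs$species <- c("s1", "s1", "s2", NA)
  recs$genus <- c("g1", "g1", "g2", NA)
  s <- summarize_dataset(recs, recs)
  expect_equal(s$length_before$median, 25)
  expect_equal(s$length_before$mean, 25)
  expect_equal(s$counts_by_phylum, c(A = 3L, B = 1L))
  expect_equal(s$n_unknown_taxonomy, 1)
  # species counts plus unknowns account for every record
  expect_equal(sum(s$counts_by_species) + s$n_unknown_taxonomy, s$n_after)

  # sample (n-1) standard-deviation convention
  two <- make_records(strrep("A", c(2, 4)))
  s2 <- summarize_dataset(two, two)
  expect_equal(s2$length_before$sd, sqrt(2), tolerance = 1e-12)

  expect_error(summarize_dataset(recs[0, ], recs[0, ]), "empty")
})

test_that("initial_info and FASTA echo round-trip the retained set", {
  recs <- make_records(c("MKTAYIAKQR", "MTTHKSNNAVR"))
  recs$organism <- c("Pseudomonas putida", "Acinetobacter baumannii")
  dir <- withr::local_tempdir()
  s <- summarize_dataset(recs, recs)
  info <- write_initial_info(s, file.path(dir, "initial_info.txt"))
  lines <- readLines(info)
  expect_true(any(grepl("^n_after\t2$", lines)))
  fa <- write_protein_fasta(recs, file.path(dir, "echo.faa"))
  back <- read_protein_fasta(fa, dialect = "uniprot")
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$organism, recs$organism)
})
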
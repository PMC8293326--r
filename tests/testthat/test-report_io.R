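test_that("accession normalization strips groups, pipe forms and isoforms", {
  expect_equal(normalize_accession("P04637-2"), "P04637")
  expect_equal(normalize_accession("sp|P68871|HBB_HUMAN"), "P68871")
  expect_equal(normalize_accession("Q9Y6K9;Q9Y6K9-2;A0A024R3C2"), "Q9Y6K9")
  expect_equal(normalize_accession("tr|A0A024R3C2|A0A024R3C2_HUMAN"), "A0A024R3C2")
  expect_equal(normalize_accession("  P12345 "), "P12345")
  # case preserved
  expect_equal(normalize_accession("p12345"), "p12345")
})

test_that("normalization is idempotent and errors on empty input", {
  forms <- c(
    "P04637-2", "sp|P68871|HBB_HUMAN", "Q9Y6K9;Q9Y6K9-2", "A0A024R3C2",
    "tr|Q99880|H2B1L_HUMAN;Q99880-3", "P62805"
  )
  once <- normalize_accession(forms)
  expect_identical(normalize_accession(once), once)
  expect_error(normalize_accession(""), class = "rulerbench_malformed_id")
  expect_error(normalize_accession("   "), class = "rulerbench_malformed_id")
  expect_error(
    normalize_accession(c("P12345", "")),
    regexp = "position\\(s\\) 2"
  )
})

test_that("maxquant parsing drops flagged rows and collapses groups", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maxquant_fixture(
    path,
    ids = c("P04637-2;P04637", "sp|P68871|HBB_HUMAN", "REV__Q00001"),
    reverse = c("", "", "+")
  )
  rep <- parse_maxquant_report(path, name = "mq")
  expect_s3_class(rep, "experiment_report")
  expect_equal(length(rep$raw_ids), 2L)
  expect_setequal(rep$accessions, c("P04637", "P68871"))

  # two rows normalizing to the same accession count once
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_maxquant_fixture(path2, ids = c("P04637-2", "P04637", "Q9Y6K9"))
  rep2 <- parse_maxquant_report(path2)
  expect_equal(length(rep2$accessions), length(rep2$raw_ids) - 1L)

  # contaminant and site-only flags also drop rows
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_maxquant_fixture(
    path3,
    ids = c("P1", "P2", "P3"),
    contaminant = c("+", "", ""),
    site_only = c("", "+", "")
  )
  expect_equal(parse_maxquant_report(path3)$accessions, "P3")
})

test_that("maxquant parsing reports a dialect error listing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(Wrong = "x", Other = "y"), path)
  expect_error(
    parse_maxquant_report(path),
    class = "rulerbench_dialect_error", regexp = "Wrong, Other"
  )
})

test_that("pd parsing honors the optional master-protein filter", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pd_fixture(path, accessions = sprintf("Q%05d", 1:5))
  expect_equal(length(parse_pd_report(path)$accessions), 5L)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pd_fixture(
    path2,
    accessions = c("P1", "P2", "P3"),
    master = c("IsMasterProtein", "IsMasterProteinCandidate", "IsMasterProtein")
  )
  expect_setequal(parse_pd_report(path2)$accessions, c("P1", "P3"))
  expect_equal(length(parse_pd_report(path2, master_only = FALSE)$accessions), 3L)

  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(NotAccession = "x"), path3)
  expect_error(parse_pd_report(path3), class = "rulerbench_dialect_error")
})

test_that("plain lists skip blanks and comments and deduplicate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("P1X2Y3", "", "# comment", "P1X2Y3"), path)
  rep <- parse_plain_list(path, name = "plain")
  expect_equal(rep$accessions, "P1X2Y3")

  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("sp|P0TEST|X_Y", path2)
  expect_equal(parse_plain_list(path2)$accessions, "P0TEST")

  # a SomaScan-1300-sized synthetic list keeps all unique targets
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("T%05d", 1:1308), path3)
  expect_equal(length(parse_plain_list(path3)$accessions), 1308L)

  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("", "# only comments"), path4)
  expect_error(parse_plain_list(path4), class = "rulerbench_empty_report")
})

test_that("parsers never invent accessions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ids <- c("P04637-2;Q9Y6K9", "sp|P68871|HBB_HUMAN", "A0A024R3C2")
  write_maxquant_fixture(path, ids = ids)
  rep <- parse_maxquant_report(path)
  for (acc in rep$accessions) {
    expect_true(any(grepl(acc, rep$raw_ids, fixed = TRUE)))
  }
  expect_lte(length(rep$accessions), length(rep$raw_ids))
})

test_that("reference tables round-trip through TSV losslessly", {
  ref <- tiny_reference(n = 100L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(ref, path)
  back <- read_reference_table(path, name = attr(ref, "name"))
  expect_equal(back$accession, ref$accession)
  expect_equal(back$copies_per_cell, ref$copies_per_cell, tolerance = 1e-12)
  expect_equal(back$log10_copies, ref$log10_copies, tolerance = 1e-12)
})

test_that("reference tables recompute log10 and reject bad copies", {
  ref <- reference_table(
    data.frame(accession = "A1", copies_per_cell = 1e5)
  )
  expect_equal(ref$log10_copies, 5.0)

  expect_error(
    reference_table(data.frame(accession = "A1", copies_per_cell = 0)),
    class = "rulerbench_reference_error"
  )
  expect_error(
    reference_table(
      data.frame(accession = c("A1", "A1-2"), copies_per_cell = c(1, 2))
    ),
    class = "rulerbench_reference_error", regexp = "duplicate"
  )

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tcopies_per_cell", "A1\t100", "A2\t0"), path)
  expect_error(
    read_reference_table(path),
    class = "rulerbench_reference_error", regexp = "line\\(s\\) 3"
  )
})
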
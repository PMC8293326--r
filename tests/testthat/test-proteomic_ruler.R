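test_that("tryptic digestion counts peptides per the cleavage rule", {
  expect_equal(digest_count("AAAA"), 0L) # lone peptide too short
  # cleaves after K2 ("MK" excluded, 17-mer counted); terminal R yields no
  # extra fragment
  expect_equal(digest_count("MKWVTFISLLFLFSSAYSR"), 1L)
  # proline blocks cleavage
  expect_equal(digest_count("AAAKPAAAA"), 1L)
  expect_equal(digest_count("AAAKAAAA", min_len = 4L, max_len = 4L), 2L)
  expect_error(digest_count("AAZB"), class = "rulerbench_sequence_error")
  expect_error(
    digest_count("AAXA"),
    regexp = "position 3"
  )
})

test_that("digestion agrees with the brute-force cleavage oracle", {
  withr::with_seed(11, {
    for (i in 1:200) {
      s <- random_sequence(sample(10:400, 1))
      expect_equal(digest_count(s), oracle_digest(s), info = s)
    }
  })
})

test_that("average molecular weight sums residue masses plus water", {
  expect_equal(average_mw("G"), 75.07, tolerance = 0.01 / 75)
  expect_equal(average_mw("GG"), 132.12, tolerance = 0.01 / 132)
  expect_error(average_mw(""), class = "rulerbench_sequence_error")
  # additivity: mw(AB) = mw(A) + mw(B) - water
  a <- average_mw("ACDEF")
  b <- average_mw("KLMNP")
  expect_equal(average_mw("ACDEFKLMNP"), a + b - 18.01528, tolerance = 1e-12)
})

test_that("iBAQ divides intensity by theoretical peptide count", {
  expect_equal(compute_ibaq(10, 5), 2)
  expect_equal(compute_ibaq(0, 7), 0)
  expect_equal(compute_ibaq(3.7, 1), 3.7)
  expect_error(compute_ibaq(10, 0), class = "rulerbench_ibaq_error")
  expect_error(compute_ibaq(-1, 2), class = "rulerbench_ibaq_error")
})

test_that("the ruler scaling factor follows the histone/DNA anchor", {
  # config chosen so m_DNA * N_A = 2.0e12; one histone, signal 2, MW 1e4
  cfg <- ruler_config(
    mode = "ibaq", genome_size_bp = 2e12, ploidy = 1,
    avg_bp_mass_g = 1 / 6.02214076e23, histone_accessions = "H0001"
  )
  records <- tibble::tibble(
    accession = c("H0001", "X0001", "Z0001"),
    signal = c(2, 5, 0),
    mw_da = c(1e4, 2e4, 3e4)
  )
  res <- run_ruler(records, cfg)
  expect_equal(res$scaling_factor, 1e8)
  expect_equal(res$copies$copies_per_cell, c(2e8, 5e8, 0))
  expect_equal(res$n_histones_used, 1L)
  # zero signal gives zero copies, and only then
  expect_identical(res$copies$copies_per_cell == 0, records$signal == 0)
})

test_that("intensity mode divides by protein molecular weight", {
  cfg <- ruler_config(
    mode = "intensity", genome_size_bp = 2e12, ploidy = 1,
    avg_bp_mass_g = 1 / 6.02214076e23, histone_accessions = "H0001"
  )
  records <- tibble::tibble(
    accession = c("H0001", "X0001"),
    signal = c(4, 1),
    mw_da = c(1e4, 5e4)
  )
  res <- run_ruler(records, cfg)
  # copies_i = signal_i / total_histone_signal * m_DNA * N_A / MW_i
  expect_equal(res$copies$copies_per_cell[1], 4 / 4 * 2e12 / 1e4)
  expect_equal(res$copies$copies_per_cell[2], 1 / 4 * 2e12 / 5e4)
  # histone self-consistency: histone mass equals the assumed DNA mass
  h_mass <- res$copies$copies_per_cell[1] * 1e4 / cfg$avogadro
  expect_equal(h_mass, cfg$m_dna_g, tolerance = 1e-9)
})

test_that("ruler output is invariant to a global signal rescaling", {
  ref <- generate_reference(sim_config(n_proteins = 200L, seed = 5L))
  for (mode in c("ibaq", "intensity")) {
    cfg <- sim_ruler_config(ref, mode)
    rec <- generate_quant_records(ref, mode, noise_cv = 0.3, seed = 9L)
    rec2 <- rec
    rec2$signal <- rec2$signal * 7
    expect_equal(
      run_ruler(rec, cfg)$copies$copies_per_cell,
      run_ruler(rec2, cfg)$copies$copies_per_cell,
      tolerance = 1e-12
    )
  }
})

test_that("ruler errors are specific", {
  cfg <- ruler_config(mode = "ibaq", histone_accessions = "H0001")
  no_hist <- tibble::tibble(accession = "X1", signal = 1, mw_da = 1e4)
  expect_error(run_ruler(no_hist, cfg), class = "rulerbench_ruler_error")
  cfg_int <- ruler_config(mode = "intensity", histone_accessions = "H0001")
  missing_mw <- tibble::tibble(
    accession = c("H0001", "X1"), signal = c(1, 1), mw_da = c(1e4, NA)
  )
  expect_error(run_ruler(missing_mw, cfg_int), class = "rulerbench_record_error")
})

test_that("built references keep positive-copy entries and round-trip", {
  ref <- generate_reference(sim_config(n_proteins = 50L, seed = 2L))
  cfg <- sim_ruler_config(ref, "ibaq")
  rec <- generate_quant_records(ref, "ibaq", noise_cv = 0, seed = 2L)
  rec$signal[30] <- 0 # drop one non-histone protein from the built table
  built <- build_reference(rec, cfg, name = "round trip")
  expect_equal(nrow(built), 49L)
  keep <- ref$accession %in% built$accession
  expect_equal(
    built$copies_per_cell,
    ref$copies_per_cell[keep],
    tolerance = 1e-9
  )
  expect_false("SYN00030" %in% built$accession)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(built, path)
  back <- read_reference_table(path)
  expect_equal(back$copies_per_cell, built$copies_per_cell, tolerance = 1e-9)
})

test_that("FASTA annotation fills MW and peptide counts by accession", {
  fasta <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c("MKWVTFISLLFLFSSAYSR", "GGGGGGGG")
  write_fasta_fixture(fasta, c("P11111", "P22222"), seqs)
  prot <- read_fasta_proteins(fasta)
  expect_equal(prot$accession, c("P11111", "P22222"))

  quant <- tibble::tibble(
    accession = c("P22222", "P11111"), signal = c(10, 4)
  )
  ann <- annotate_quant_records(quant, prot)
  expect_equal(ann$mw_da, vapply(rev(seqs), average_mw, 1, USE.NAMES = FALSE))
  expect_equal(ann$n_theoretical_peptides, c(1L, 1L))
  ib <- annotate_quant_records(quant, prot, compute_ibaq_signal = TRUE)
  expect_equal(ib$signal, c(10, 4))

  expect_error(
    annotate_quant_records(
      tibble::tibble(accession = "NOPE1", signal = 1), prot
    ),
    class = "rulerbench_record_error"
  )
})
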
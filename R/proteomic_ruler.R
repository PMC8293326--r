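# Average (not monoisotopic) residue masses in g/mol; protein MW is the sum
# of residue masses plus one water. Average masses match protein-scale
# quantity conventions.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    rlang::abort("sequence must be a single non-empty string",
      class = "rulerbench_sequence_error"
    )
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf(
        "illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]
      ),
      class = "rulerbench_sequence_error"
    )
  }
  sequence
}

#' Count theoretical fully tryptic peptides
#'
#' Performs an in-silico tryptic digestion — cleavage C-terminal of K or R,
#' blocked when the next residue is P, zero missed cleavages — and counts the
#' resulting peptides whose length falls in `[min_len, max_len]`. This is the
#' theoretical peptide count used by the iBAQ normalization.
#'
#' @param sequence Amino-acid sequence (20-letter alphabet, case-insensitive).
#' @param min_len,max_len Inclusive peptide-length bounds; defaults 7 and 30,
#'   the common iBAQ convention.
#' @return Integer count of peptides in range.
#' @examples
#' digest_count("MKWVTFISLLFLFSSAYSR") # "MK" too short; one peptide counted
#' @export
digest_count <- function(sequence, min_len = 7L, max_len = 30L) {
  sequence <- check_sequence(sequence)
  stopifnot(min_len > 0L, min_len <= max_len)
  n <- nchar(sequence)
  cuts <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1L]]
  cuts <- as.integer(cuts[cuts > 0L])
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  lens <- ends - starts + 1L
  lens <- lens[lens > 0L]
  sum(lens >= min_len & lens <= max_len)
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water mass, in g/mol.
#'
#' @inheritParams digest_count
#' @return Molecular weight in g/mol.
#' @examples
#' average_mw("G") # glycine residue + water, ~75.07
#' @export
average_mw <- function(sequence) {
  sequence <- check_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Divides a protein's summed MS intensity by its number of theoretical
#' tryptic peptides, yielding a proxy for molar amount.
#'
#' @param intensity Non-negative summed intensity.
#' @param n_theoretical_peptides Positive integer peptide count.
#' @return `intensity / n_theoretical_peptides`.
#' @export
compute_ibaq <- function(intensity, n_theoretical_peptides) {
  if (any(n_theoretical_peptides < 1)) {
    rlang::abort("iBAQ undefined: theoretical peptide count must be >= 1",
      class = "rulerbench_ibaq_error"
    )
  }
  if (any(intensity < 0)) {
    rlang::abort("intensity must be non-negative",
      class = "rulerbench_ibaq_error"
    )
  }
  intensity / n_theoretical_peptides
}

#' Default human histone accessions
#'
#' Canonical UniProt accessions of human core (H2A, H2B, H3, H4) and linker
#' (H1) histones, used to designate the histone subset when quantitative
#' records carry no explicit histone flag. An explicit accession set keeps the
#' designation deterministic and auditable.
#'
#' @return Character vector of accessions.
#' @export
default_histones <- function() {
  c(
    # linker H1
    "P07305", "Q02539", "P16403", "P16402", "P10412", "P16401", "Q92522",
    # H2A
    "P0C0S8", "Q96KK5", "P04908", "P20671", "P0C0S5", "P16104", "Q71UI9",
    "Q96QV6", "P28001",
    # H2B
    "P62807", "O60814", "P58876", "Q93079", "P06899", "P33778", "Q99880",
    "Q16778",
    # H3
    "P68431", "Q71DI3", "P84243", "Q16695",
    # H4
    "P62805"
  )
}

#' Configure the proteomic ruler
#'
#' The ruler converts relative MS signal to absolute copies per cell by
#' anchoring total histone signal to the cell's DNA mass: histones are
#' maintained in near-constant proportion to DNA, and DNA mass per cell is
#' itself constant, `m_DNA = genome_size_bp * ploidy * avg_bp_mass_g`.
#'
#' @param mode `"ibaq"` (signal is already a molar proxy) or `"intensity"`
#'   (raw intensity; copies divide by the protein's molecular weight).
#' @param genome_size_bp Haploid genome size in base pairs.
#' @param ploidy Genome copies per cell. The default of 2 assumes a diploid
#'   cell; note HeLa and many cancer lines are aneuploid, so set this (or the
#'   genome size) to match the cell line when absolute accuracy matters.
#' @param avg_bp_mass_g Average mass of one base pair in grams.
#' @param avogadro Avogadro constant in 1/mol.
#' @param histone_accessions Accessions designating the histone subset when
#'   records carry no `is_histone` flag.
#' @return A `ruler_config` list; `m_dna_g` is the derived DNA mass per cell.
#' @export
ruler_config <- function(mode = c("ibaq", "intensity"),
                         genome_size_bp = 3.1e9,
                         ploidy = 2,
                         avg_bp_mass_g = 615.8771 / 6.02214076e23,
                         avogadro = 6.02214076e23,
                         histone_accessions = default_histones()) {
  mode <- match.arg(mode)
  stopifnot(genome_size_bp > 0, ploidy > 0, avg_bp_mass_g > 0, avogadro > 0)
  structure(
    list(
      mode = mode,
      genome_size_bp = genome_size_bp,
      ploidy = ploidy,
      avg_bp_mass_g = avg_bp_mass_g,
      avogadro = avogadro,
      histone_accessions = histone_accessions,
      m_dna_g = genome_size_bp * ploidy * avg_bp_mass_g
    ),
    class = "ruler_config"
  )
}

validate_quant_records <- function(records, config) {
  records <- tibble::as_tibble(records)
  req <- c("accession", "signal")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    rlang::abort(
      sprintf("quant records missing column(s): %s", paste(miss, collapse = ", ")),
      class = "rulerbench_record_error"
    )
  }
  if (any(is.na(records$signal) | records$signal < 0)) {
    rlang::abort("signals must be non-negative and non-missing",
      class = "rulerbench_record_error"
    )
  }
  if (!"is_histone" %in% names(records)) {
    records$is_histone <-
      normalize_accession(records$accession) %in% config$histone_accessions
  }
  need_mw <- if (config$mode == "intensity") {
    rep(TRUE, nrow(records))
  } else {
    records$is_histone # ibaq mode only weighs histone signal by MW
  }
  if (!"mw_da" %in% names(records)) records$mw_da <- NA_real_
  bad_mw <- need_mw & (is.na(records$mw_da) | records$mw_da <= 0)
  if (any(bad_mw)) {
    rlang::abort(
      sprintf(
        "missing or non-positive mw_da for record(s): %s",
        paste(utils::head(records$accession[bad_mw], 5L), collapse = ", ")
      ),
      class = "rulerbench_record_error"
    )
  }
  records
}

#' Estimate absolute copies per cell with the histone ruler
#'
#' With `m_DNA` the DNA mass per cell and `N_A` the Avogadro constant:
#' in `ibaq` mode the scaling factor is
#' `c = m_DNA * N_A / sum_histones(signal_h * MW_h)` and
#' `copies_i = c * signal_i`; in `intensity` mode
#' `copies_i = signal_i / sum_histones(signal_h) * m_DNA * N_A / MW_i`.
#' Both modes are invariant to a global rescaling of all signals.
#'
#' @param records Data frame of quantitative records with columns `accession`,
#'   `signal`, and (where required) `mw_da`; optional logical `is_histone`
#'   (otherwise the config's histone accession set is used).
#' @param config A [ruler_config()].
#' @return A `ruler_result`: `copies` (tibble of `accession`,
#'   `copies_per_cell` in input order), `scaling_factor` (ibaq mode, else NA),
#'   `total_histone_signal`, `n_histones_used`, and the config.
#' @export
run_ruler <- function(records, config = ruler_config()) {
  stopifnot(inherits(config, "ruler_config"))
  records <- validate_quant_records(records, config)
  hist_idx <- which(records$is_histone & records$signal > 0)
  if (length(hist_idx) == 0L) {
    rlang::abort(
      "ruler undefined: no histone record with positive signal",
      class = "rulerbench_ruler_error"
    )
  }
  m_dna_mol <- config$m_dna_g * config$avogadro # g * mol^-1 scale factor
  if (config$mode == "ibaq") {
    denom <- sum(records$signal[hist_idx] * records$mw_da[hist_idx])
    scaling <- m_dna_mol / denom
    copies <- scaling * records$signal
  } else {
    total_h <- sum(records$signal[hist_idx])
    scaling <- NA_real_
    copies <- records$signal / total_h * m_dna_mol / records$mw_da
  }
  structure(
    list(
      copies = tibble::tibble(
        accession = records$accession,
        copies_per_cell = copies
      ),
      scaling_factor = scaling,
      total_histone_signal = sum(records$signal[records$is_histone]),
      n_histones_used = length(hist_idx),
      config = config
    ),
    class = "ruler_result"
  )
}

#' @export
print.ruler_result <- function(x, ...) {
  cat(sprintf(
    "<ruler_result> %d proteins, %d histones used, mode '%s'\n",
    nrow(x$copies), x$n_histones_used, x$config$mode
  ))
  invisible(x)
}

#' Build a reference table from quantitative records
#'
#' Runs the histone ruler and keeps the positive-copy results as a
#' [reference_table()] with `log10_copies` populated; records with zero
#' signal (zero estimated copies) are excluded since reference entries must
#' be positive.
#'
#' @inheritParams run_ruler
#' @param name Label for the resulting table.
#' @return A [reference_table()].
#' @export
build_reference <- function(records, config = ruler_config(),
                            name = "ruler reference") {
  res <- run_ruler(records, config)
  entries <- res$copies[res$copies$copies_per_cell > 0, ]
  records <- tibble::as_tibble(records)
  if ("mw_da" %in% names(records)) {
    entries$mw_da <- records$mw_da[match(entries$accession, records$accession)]
  }
  if ("gene" %in% names(records)) {
    entries$gene <- records$gene[match(entries$accession, records$accession)]
  }
  reference_table(entries, name = name)
}

#' Read protein sequences from a UniProt-style FASTA file
#'
#' Headers of the form `db|ACC|NAME` are reduced to `ACC`; other headers are
#' taken up to the first whitespace and normalized.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Tibble with columns `accession` and `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(seqs))
  tibble::tibble(
    accession = normalize_accession(headers),
    sequence = as.character(seqs)
  )
}

#' Read a quantitative protein table from TSV
#'
#' Expects columns `accession` and `signal` (raw intensity or iBAQ); an
#' optional `sequence` column is kept for molecular-weight and peptide-count
#' annotation.
#'
#' @param path Path to the TSV file.
#' @return Tibble of quantitative records.
#' @export
read_quant_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("accession", "signal"), names(tab))
  if (length(miss) > 0L) dialect_error(paste(miss, collapse = "/"), names(tab))
  tab$accession <- normalize_accession(tab$accession)
  tab
}

#' Annotate quantitative records with MW and theoretical peptide counts
#'
#' Fills `mw_da` ([average_mw()]) and `n_theoretical_peptides`
#' ([digest_count()]) from sequences, taken either from the records'
#' `sequence` column or from a FASTA table read with [read_fasta_proteins()].
#' When `compute_ibaq_signal = TRUE` the `signal` column is replaced by
#' `signal / n_theoretical_peptides`, converting raw intensity to iBAQ.
#'
#' @param records Quantitative records (tibble with `accession`, `signal`).
#' @param fasta Optional tibble from [read_fasta_proteins()].
#' @param min_len,max_len Peptide-length bounds for [digest_count()].
#' @param compute_ibaq_signal Convert `signal` from intensity to iBAQ.
#' @return The records with `mw_da` and `n_theoretical_peptides` filled.
#' @export
annotate_quant_records <- function(records, fasta = NULL,
                                   min_len = 7L, max_len = 30L,
                                   compute_ibaq_signal = FALSE) {
  records <- tibble::as_tibble(records)
  if (!is.null(fasta)) {
    records$sequence <-
      fasta$sequence[match(records$accession, fasta$accession)]
  }
  if (!"sequence" %in% names(records) || anyNA(records$sequence)) {
    rlang::abort(
      "no sequence available for one or more records; supply a FASTA",
      class = "rulerbench_record_error"
    )
  }
  records$mw_da <- vapply(records$sequence, average_mw, numeric(1),
    USE.NAMES = FALSE
  )
  records$n_theoretical_peptides <- vapply(
    records$sequence,
    function(s) as.integer(digest_count(s, min_len, max_len)),
    integer(1),
    USE.NAMES = FALSE
  )
  if (compute_ibaq_signal) {
    records$signal <- compute_ibaq(records$signal, records$n_theoretical_peptides)
  }
  records
}
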
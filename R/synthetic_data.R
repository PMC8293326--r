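#' Configure a synthetic proteome
#'
#' Describes a simulated reference proteome: log10 copies per cell drawn from
#' a normal distribution (the observed copy-number distribution of a deeply
#' fractionated human cell line is unimodal and spans ~6-7 decades),
#' log-normal molecular weights, and a designated histone subset whose summed
#' protein mass is pinned to a set fraction of total protein mass.
#'
#' @param n_proteins Number of proteins in the reference.
#' @param log_mu Mean log10 copies per cell (default 4.2, matching a deep
#'   HeLa-scale reference).
#' @param log_sigma SD of log10 copies (default 1.1, ~6-7 decades of dynamic
#'   range at +/- 3 sigma).
#' @param histone_fraction_of_mass Fraction of total protein mass carried by
#'   histones (default 0.04).
#' @param mw_log_mu,mw_log_sigma Mean and SD of log10 molecular weight in Da
#'   (defaults give a ~45 kDa median protein).
#' @param n_histones Size of the designated histone subset.
#' @param histone_log_sigma SD of log10 copies within the histone subset
#'   (default 0.15): histones are maintained in tightly conserved
#'   stoichiometry, so their relative abundances are far narrower than the
#'   bulk proteome's.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 14179L,
                       log_mu = 4.2,
                       log_sigma = 1.1,
                       histone_fraction_of_mass = 0.04,
                       mw_log_mu = 4.65,
                       mw_log_sigma = 0.25,
                       n_histones = 11L,
                       histone_log_sigma = 0.15,
                       seed = 1L) {
  stopifnot(
    n_proteins >= 2L, log_sigma > 0, mw_log_sigma > 0,
    histone_fraction_of_mass > 0, histone_fraction_of_mass < 1,
    n_histones >= 1L, n_histones < n_proteins, histone_log_sigma > 0
  )
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      log_mu = log_mu,
      log_sigma = log_sigma,
      histone_fraction_of_mass = histone_fraction_of_mass,
      mw_log_mu = mw_log_mu,
      mw_log_sigma = mw_log_sigma,
      n_histones = as.integer(n_histones),
      histone_log_sigma = histone_log_sigma,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

AVOGADRO <- 6.02214076e23

#' Generate a synthetic reference proteome
#'
#' Draws copies per cell as `10^Normal(log_mu, log_sigma)` and molecular
#' weights as `10^Normal(mw_log_mu, mw_log_sigma)`, then rescales the copies
#' of the designated histone subset so that histone mass
#' (`sum(copies * MW) / N_A`) is exactly `histone_fraction_of_mass` of total
#' protein mass. Bit-reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A [reference_table()] with columns `accession`, `copies_per_cell`,
#'   `log10_copies`, `mw_da`, `is_histone`, and attributes `histone_mass_g`
#'   (summed histone protein mass per cell) and `sim_config`.
#' @export
generate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  dat <- withr::with_seed(config$seed, {
    d <- tibble::tibble(
      accession = sprintf("SYN%05d", seq_len(n)),
      copies_per_cell = 10^stats::rnorm(n, config$log_mu, config$log_sigma),
      mw_da = 10^stats::rnorm(n, config$mw_log_mu, config$mw_log_sigma),
      is_histone = seq_len(n) <= config$n_histones
    )
    # histones sit in tightly conserved stoichiometry: redraw their relative
    # abundances with a narrow spread (the absolute level is set by the mass
    # rescaling below)
    d$copies_per_cell[d$is_histone] <-
      10^stats::rnorm(config$n_histones, config$log_mu, config$histone_log_sigma)
    d
  })
  # pin histone mass to the configured fraction of total protein mass:
  # mass_h = f / (1 - f) * mass_other
  mass <- dat$copies_per_cell * dat$mw_da / AVOGADRO
  f <- config$histone_fraction_of_mass
  target <- f / (1 - f) * sum(mass[!dat$is_histone])
  dat$copies_per_cell[dat$is_histone] <-
    dat$copies_per_cell[dat$is_histone] * target / sum(mass[dat$is_histone])
  ref <- reference_table(dat, name = sprintf("synthetic (seed %d)", config$seed))
  attr(ref, "histone_mass_g") <-
    sum(ref$copies_per_cell[ref$is_histone] * ref$mw_da[ref$is_histone]) /
      AVOGADRO
  attr(ref, "sim_config") <- config
  ref
}

#' Ruler configuration matched to a synthetic reference
#'
#' The ruler's central assumption is that histone protein mass equals the
#' cell's DNA mass. For a simulated proteome the ground-truth histone mass is
#' known, so the matching configuration sets the genome size such that
#' `m_DNA` equals it (keeping ploidy and per-bp mass at their defaults); with
#' that config, signals generated by [generate_quant_records()] at zero noise
#' invert exactly to the reference copies.
#'
#' @param reference A [generate_reference()] result.
#' @param mode `"ibaq"` or `"intensity"`.
#' @return A [ruler_config()].
#' @export
sim_ruler_config <- function(reference, mode = c("ibaq", "intensity")) {
  mode <- match.arg(mode)
  m_dna <- attr(reference, "histone_mass_g")
  if (is.null(m_dna)) {
    rlang::abort("reference carries no histone_mass_g attribute",
      class = "rulerbench_config_error"
    )
  }
  base <- ruler_config(mode = mode)
  ruler_config(
    mode = mode,
    genome_size_bp = m_dna / (base$ploidy * base$avg_bp_mass_g),
    ploidy = base$ploidy,
    avg_bp_mass_g = base$avg_bp_mass_g,
    avogadro = base$avogadro,
    histone_accessions = reference$accession[reference$is_histone]
  )
}

#' Generate quantitative records consistent with a reference
#'
#' Constructs MS-like signals that invert to the reference copies under the
#' histone ruler: in `ibaq` mode `signal_i` is proportional to `copies_i`, in
#' `intensity` mode to `copies_i * MW_i`. With `noise_cv = 0` the ruler (run
#' with [sim_ruler_config()]) recovers every copy number exactly; a positive
#' `noise_cv` applies multiplicative log-normal noise with that coefficient of
#' variation (unit mean).
#'
#' @param reference A [generate_reference()] result (molecular weights and
#'   histone flags present).
#' @param mode `"ibaq"` or `"intensity"`.
#' @param noise_cv Coefficient of variation of multiplicative noise, >= 0.
#' @param seed Integer seed for the noise draws.
#' @param scale Arbitrary global signal scale (the ruler is invariant to it).
#' @return Tibble of quantitative records: `accession`, `signal`, `mw_da`,
#'   `is_histone`.
#' @export
generate_quant_records <- function(reference, mode = c("ibaq", "intensity"),
                                   noise_cv = 0, seed = 1L, scale = 1e-2) {
  mode <- match.arg(mode)
  stopifnot(noise_cv >= 0)
  if (!"mw_da" %in% names(reference)) {
    rlang::abort("reference has no mw_da column",
      class = "rulerbench_record_error"
    )
  }
  signal <- if (mode == "ibaq") {
    reference$copies_per_cell
  } else {
    reference$copies_per_cell * reference$mw_da
  }
  signal <- signal * scale
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- withr::with_seed(
      seed,
      stats::rlnorm(length(signal), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    )
    signal <- signal * noise
  }
  tibble::tibble(
    accession = reference$accession,
    signal = signal,
    mw_da = reference$mw_da,
    is_histone = reference$is_histone
  )
}

#' Logistic detection model
#'
#' Detection probability increasing in log10 copies per cell:
#' `P(detect | x) = 1 / (1 + exp(-a * (x - t)))`. Deeper methods are emulated
#' by lowering the midpoint `t`; the model is the simplest monotone account of
#' the empirical pattern that added identifications come predominantly from
#' lower copy-number proteins.
#'
#' @param midpoint_t Log10 copies at 50% detection probability.
#' @param slope_a Positive logistic slope (default 2).
#' @return A `detection_model` list.
#' @export
detection_model <- function(midpoint_t, slope_a = 2) {
  stopifnot(is.finite(midpoint_t), slope_a > 0)
  structure(
    list(midpoint_t = midpoint_t, slope_a = slope_a),
    class = "detection_model"
  )
}

#' Detection probabilities under a logistic model
#'
#' @param model A [detection_model()].
#' @param log10_copies Numeric vector of log10 copies per cell.
#' @return Detection probabilities in (0, 1).
#' @export
detection_prob <- function(model, log10_copies) {
  stopifnot(inherits(model, "detection_model"))
  stats::plogis(model$slope_a * (log10_copies - model$midpoint_t))
}

#' Simulate an experiment's identification list
#'
#' Includes each reference protein independently with its logistic detection
#' probability; deterministic per seed. The result is a plain-dialect
#' experiment report, indistinguishable from a parsed identifier list.
#'
#' @param reference A [reference_table()].
#' @param model A [detection_model()].
#' @param name Label for the simulated experiment.
#' @param seed Integer seed.
#' @return An [experiment_report()].
#' @export
simulate_experiment <- function(reference, model, name = "simulated",
                                seed = 1L) {
  p <- detection_prob(model, reference$log10_copies)
  hit <- withr::with_seed(seed, stats::runif(length(p)) < p)
  experiment_report(name, "plain", reference$accession[hit])
}
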
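#' Map an experiment onto a reference copy-number table
#'
#' Intersects the experiment's normalized accession set with the reference:
#' every experiment accession lands in exactly one of matched (with its copies
#' per cell) or unmatched.
#'
#' @param experiment An [experiment_report()].
#' @param reference A [reference_table()].
#' @return A `mapped_experiment`: `name`, `matched` (named numeric vector of
#'   copies per cell keyed by accession), `unmatched` (character vector),
#'   `n_matched`, `n_unmatched`.
#' @export
map_to_reference <- function(experiment, reference) {
  stopifnot(inherits(experiment, "experiment_report"))
  stopifnot(inherits(reference, "reference_table"))
  if (nrow(reference) == 0L) {
    rlang::abort("reference table is empty",
      class = "rulerbench_config_error"
    )
  }
  acc <- experiment$accessions
  if (length(acc) == 0L) {
    rlang::abort("experiment has no accessions",
      class = "rulerbench_config_error"
    )
  }
  idx <- match(acc, reference$accession)
  hit <- !is.na(idx)
  matched <- stats::setNames(reference$copies_per_cell[idx[hit]], acc[hit])
  structure(
    list(
      name = experiment$name,
      matched = matched,
      unmatched = acc[!hit],
      n_matched = sum(hit),
      n_unmatched = sum(!hit)
    ),
    class = "mapped_experiment"
  )
}

#' @export
print.mapped_experiment <- function(x, ...) {
  cat(sprintf(
    "<mapped_experiment> %s: %d matched, %d unmatched\n",
    x$name, x$n_matched, x$n_unmatched
  ))
  invisible(x)
}

#' Fraction of a reference proteome covered
#'
#' @param n_matched Number of experiment proteins matched to the reference.
#' @param n_reference Number of proteins in the reference table.
#' @return `n_matched / n_reference`.
#' @export
coverage_fraction <- function(n_matched, n_reference) {
  stopifnot(n_reference > 0)
  n_matched / n_reference
}

#' Summarize a mapped experiment against its reference
#'
#' Computes the headline comparison metrics for one experiment: matched
#' protein count, arithmetic mean and median of log10 copies per cell over the
#' matched proteins (unmatched proteins are excluded, never imputed), coverage
#' of the reference, and the unmatched fraction of the experiment (so
#' reference-coverage bias stays visible).
#'
#' @param mapped A [map_to_reference()] result.
#' @param reference The [reference_table()] used for mapping.
#' @return One-row tibble: `name`, `n_proteins`, `mean_log_copy`,
#'   `median_log_copy`, `coverage_fraction`, `unmatched_fraction`.
#' @export
summarize_experiment <- function(mapped, reference) {
  stopifnot(inherits(mapped, "mapped_experiment"))
  stopifnot(inherits(reference, "reference_table"))
  if (mapped$n_matched == 0L) {
    rlang::abort(
      sprintf("metrics undefined for '%s': no matched proteins", mapped$name),
      class = "rulerbench_undefined_metric"
    )
  }
  lg <- log10(mapped$matched)
  n_exp <- mapped$n_matched + mapped$n_unmatched
  tibble::tibble(
    name = mapped$name,
    n_proteins = mapped$n_matched,
    mean_log_copy = mean(lg),
    median_log_copy = stats::median(lg),
    coverage_fraction = coverage_fraction(mapped$n_matched, nrow(reference)),
    unmatched_fraction = mapped$n_unmatched / n_exp
  )
}

#' Compare experiments against a reference
#'
#' Maps and summarizes each experiment, returning one row per experiment in
#' input order — the tabular analogue of a per-method comparison table. A
#' failing experiment (for example one sharing nothing with the reference)
#' yields a row of NA metrics and a warning rather than aborting the batch.
#'
#' @param experiments List of [experiment_report()] objects.
#' @param reference A [reference_table()].
#' @return Tibble with the columns of [summarize_experiment()].
#' @export
compare_experiments <- function(experiments, reference) {
  if (inherits(experiments, "experiment_report")) {
    experiments <- list(experiments)
  }
  stopifnot(length(experiments) >= 1L)
  rows <- lapply(experiments, function(exp) {
    tryCatch(
      summarize_experiment(map_to_reference(exp, reference), reference),
      error = function(e) {
        warning(sprintf("experiment '%s' skipped: %s", exp$name, conditionMessage(e)),
          call. = FALSE
        )
        tibble::tibble(
          name = exp$name, n_proteins = NA_integer_,
          mean_log_copy = NA_real_, median_log_copy = NA_real_,
          coverage_fraction = NA_real_, unmatched_fraction = NA_real_
        )
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a comparison table to TSV
#'
#' @param comparison Tibble from [compare_experiments()].
#' @param path Output path.
#' @export
write_comparison <- function(comparison, path) {
  readr::write_tsv(comparison, path, progress = FALSE)
  invisible(path)
}

#' Protein gain per unit gradient time
#'
#' Quantifies diminishing returns from gradient extension: for consecutive
#' pairs of (gradient time, protein count) it reports the protein gain and the
#' gain rate per minute, plus the cumulative proteins-per-minute at each
#' point.
#'
#' @param times Strictly increasing gradient times in minutes.
#' @param counts Protein counts at each time, same length.
#' @return A `gain_per_time` list: `$intervals` (tibble `from_min`, `to_min`,
#'   `delta_proteins`, `delta_per_min`) and `$cumulative` (tibble `time_min`,
#'   `n_proteins`, `proteins_per_min`).
#' @examples
#' gain_per_time(c(60, 90), c(4435, 4770))
#' @export
gain_per_time <- function(times, counts) {
  if (length(times) != length(counts) || length(times) < 2L) {
    rlang::abort("times and counts must have equal length >= 2",
      class = "rulerbench_input_error"
    )
  }
  if (any(diff(times) <= 0)) {
    rlang::abort("times must be strictly increasing",
      class = "rulerbench_input_error"
    )
  }
  structure(
    list(
      intervals = tibble::tibble(
        from_min = times[-length(times)],
        to_min = times[-1L],
        delta_proteins = diff(counts),
        delta_per_min = diff(counts) / diff(times)
      ),
      cumulative = tibble::tibble(
        time_min = times,
        n_proteins = counts,
        proteins_per_min = counts / times
      )
    ),
    class = "gain_per_time"
  )
}

#' @export
print.gain_per_time <- function(x, ...) {
  cat("<gain_per_time>\n")
  print(x$intervals)
  invisible(x)
}
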
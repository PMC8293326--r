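#' Normalize protein-group identifiers to bare UniProt accessions
#'
#' Protein-group reports name a group by a representative identifier that may
#' be a `;`-separated compound ("Q9Y6K9;Q9Y6K9-2"), a FASTA pipe form
#' ("sp|P68871|HBB_HUMAN"), or carry an isoform suffix ("P04637-2"). Reference
#' copy-number tables are keyed by canonical accession, so all of these are
#' reduced to the bare accession of the first listed (representative) protein:
#' the first `;` token, the middle field of a `sp|ACC|NAME` / `tr|ACC|NAME`
#' form, with any trailing `-<digits>` isoform suffix stripped. Case is
#' preserved. The operation is idempotent.
#'
#' @param raw Character vector of raw identifier strings.
#' @return Character vector of normalized accessions, same length as `raw`.
#' @examples
#' normalize_accession("P04637-2")
#' normalize_accession("sp|P68871|HBB_HUMAN")
#' normalize_accession("Q9Y6K9;Q9Y6K9-2;A0A024R3C2")
#' @export
normalize_accession <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- trimws(raw)
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "malformed identifier: empty or missing at position(s) %s",
        paste(which(bad), collapse = ", ")
      ),
      class = "rulerbench_malformed_id"
    )
  }
  # first token of a ";"-separated protein group
  out <- sub(";.*$", "", out)
  # sp|ACC|NAME / tr|ACC|NAME -> ACC
  piped <- grepl("^(sp|tr)\\|", out)
  out[piped] <- vapply(
    strsplit(out[piped], "|", fixed = TRUE),
    function(x) if (length(x) >= 2L) x[[2L]] else x[[1L]],
    character(1)
  )
  # isoform suffix
  out <- sub("-[0-9]+$", "", out)
  trimws(out)
}

#' Construct an experiment report
#'
#' An experiment report holds the raw protein-group identifiers read from one
#' identification report together with the normalized, deduplicated accession
#' set used for mapping onto a reference table.
#'
#' @param name Free-text label for the experiment.
#' @param source_dialect One of `"maxquant"`, `"pd"`, `"plain"`.
#' @param raw_ids Character vector of raw group-identifier strings, in file
#'   order.
#' @return An object of class `experiment_report` with fields `name`,
#'   `source_dialect`, `raw_ids` and `accessions` (unique normalized
#'   accessions).
#' @export
experiment_report <- function(name, source_dialect, raw_ids) {
  source_dialect <- match.arg(source_dialect, c("maxquant", "pd", "plain"))
  raw_ids <- as.character(raw_ids)
  accessions <- unique(normalize_accession(raw_ids))
  structure(
    list(
      name = name,
      source_dialect = source_dialect,
      raw_ids = raw_ids,
      accessions = accessions
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "<experiment_report> %s [%s]: %d raw ids, %d accessions\n",
    x$name, x$source_dialect, length(x$raw_ids), length(x$accessions)
  ))
  invisible(x)
}

# Locate a column by case-insensitive alias list; NULL if absent.
find_column <- function(cols, aliases) {
  hit <- match(tolower(aliases), tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NULL else cols[[hit[[1L]]]]
}

dialect_error <- function(what, cols) {
  rlang::abort(
    sprintf(
      "could not find %s column; available columns: %s",
      what, paste(cols, collapse = ", ")
    ),
    class = "rulerbench_dialect_error"
  )
}

#' Parse a MaxQuant proteinGroups report
#'
#' Reads a tab-separated proteinGroups-style file and returns an experiment
#' report built from the majority-protein identifier column. Rows flagged as
#' reversed decoys, potential contaminants, or identified only by a modified
#' site (flag value `"+"`) are dropped, matching the semantics of the upstream
#' processed outputs.
#'
#' @param path Path to the tab-separated report.
#' @param name Label for the experiment (defaults to the file name).
#' @param id_aliases Case-insensitive candidate names for the identifier
#'   column.
#' @return An [experiment_report()].
#' @export
parse_maxquant_report <- function(path, name = basename(path),
                                  id_aliases = c(
                                    "Majority protein IDs",
                                    "Majority protein ID"
                                  )) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  id_col <- find_column(names(tab), id_aliases)
  if (is.null(id_col)) dialect_error("majority-protein identifier", names(tab))
  keep <- rep(TRUE, nrow(tab))
  for (flag in c(
    "Reverse", "Potential contaminant", "Contaminant",
    "Only identified by site"
  )) {
    col <- find_column(names(tab), flag)
    if (!is.null(col)) {
      v <- as.character(tab[[col]])
      keep <- keep & (is.na(v) | trimws(v) != "+")
    }
  }
  experiment_report(name, "maxquant", tab[[id_col]][keep])
}

#' Parse a Proteome Discoverer protein export
#'
#' Reads a tab-separated protein export and returns an experiment report built
#' from the accession column. When a master-protein column is present and
#' `master_only = TRUE`, only rows whose value is `IsMasterProtein`
#' (case-insensitive) are retained.
#'
#' @inheritParams parse_maxquant_report
#' @param accession_aliases Case-insensitive candidate names for the accession
#'   column.
#' @param master_only Apply the master-protein filter when the column exists.
#' @return An [experiment_report()].
#' @export
parse_pd_report <- function(path, name = basename(path),
                            accession_aliases = c("Accession", "Accessions"),
                            master_only = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  acc_col <- find_column(names(tab), accession_aliases)
  if (is.null(acc_col)) dialect_error("accession", names(tab))
  keep <- rep(TRUE, nrow(tab))
  master_col <- find_column(names(tab), c("Master", "Protein Group Master"))
  if (master_only && !is.null(master_col)) {
    v <- tolower(trimws(as.character(tab[[master_col]])))
    keep <- keep & !is.na(v) & v == "ismasterprotein"
  }
  experiment_report(name, "pd", tab[[acc_col]][keep])
}

#' Parse a plain one-identifier-per-line list
#'
#' Blank lines and lines starting with `#` are ignored; remaining lines are
#' normalized and deduplicated.
#'
#' @inheritParams parse_maxquant_report
#' @return An [experiment_report()].
#' @export
parse_plain_list <- function(path, name = basename(path)) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    rlang::abort(
      sprintf("no identifiers found in '%s' after filtering", path),
      class = "rulerbench_empty_report"
    )
  }
  experiment_report(name, "plain", lines)
}

#' Write a plain accession list
#'
#' Writes the normalized accession set of an experiment report (or a character
#' vector) one accession per line, the same format [parse_plain_list()] reads.
#'
#' @param x An [experiment_report()] or character vector of accessions.
#' @param path Output path.
#' @export
write_plain_list <- function(x, path) {
  acc <- if (inherits(x, "experiment_report")) x$accessions else as.character(x)
  readr::write_lines(acc, path)
  invisible(path)
}

#' Construct a reference copy-number table
#'
#' A reference table maps canonical accessions to absolute copies per cell;
#' it is the base dataset against which experiments are scored. Accessions are
#' normalized and must be unique afterwards; copy numbers must be positive.
#' `log10_copies` is recomputed from `copies_per_cell` when absent or when it
#' disagrees beyond 1e-9.
#'
#' @param entries Data frame with columns `accession` and `copies_per_cell`;
#'   optional columns `log10_copies`, `gene`, `mw_da`.
#' @param name Label for the table.
#' @return A tibble of class `reference_table` with attribute `name`.
#' @export
reference_table <- function(entries, name = "reference") {
  entries <- tibble::as_tibble(entries)
  req <- c("accession", "copies_per_cell")
  if (!all(req %in% names(entries))) {
    rlang::abort(
      sprintf(
        "reference table needs columns %s; got: %s",
        paste(req, collapse = ", "), paste(names(entries), collapse = ", ")
      ),
      class = "rulerbench_reference_error"
    )
  }
  copies <- suppressWarnings(as.numeric(entries$copies_per_cell))
  bad <- is.na(copies) | copies <= 0
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "non-positive or non-numeric copies_per_cell at row(s) %s",
        paste(which(bad), collapse = ", ")
      ),
      class = "rulerbench_reference_error"
    )
  }
  entries$accession <- normalize_accession(entries$accession)
  if (anyDuplicated(entries$accession)) {
    dup <- unique(entries$accession[duplicated(entries$accession)])
    rlang::abort(
      sprintf(
        "duplicate accessions after normalization: %s",
        paste(utils::head(dup, 5L), collapse = ", ")
      ),
      class = "rulerbench_reference_error"
    )
  }
  entries$copies_per_cell <- copies
  if (!"log10_copies" %in% names(entries) ||
      any(abs(entries$log10_copies - log10(copies)) >= 1e-9, na.rm = TRUE) ||
      anyNA(entries$log10_copies)) {
    entries$log10_copies <- log10(copies)
  }
  lead <- intersect(
    c("accession", "copies_per_cell", "log10_copies", "gene", "mw_da"),
    names(entries)
  )
  entries <- entries[, c(lead, setdiff(names(entries), lead))]
  structure(
    entries,
    name = name,
    class = c("reference_table", class(tibble::tibble()))
  )
}

#' Read a reference copy-number table from TSV
#'
#' Expects header columns `accession` and `copies_per_cell`; `log10_copies`,
#' `gene` and `mw_da` are kept when present and `log10_copies` is recomputed
#' if absent. Rows with non-positive or non-numeric copy numbers are rejected
#' with their line number.
#'
#' @param path Path to the TSV file.
#' @param name Label for the table (defaults to the file name).
#' @return A [reference_table()].
#' @export
read_reference_table <- function(path, name = basename(path)) {
  tab <- readr::read_tsv(
    path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  req <- c("accession", "copies_per_cell")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) dialect_error(paste(miss, collapse = "/"), names(tab))
  copies <- suppressWarnings(as.numeric(tab$copies_per_cell))
  bad <- which(is.na(copies) | copies <= 0)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf(
        "invalid copies_per_cell in '%s' at line(s) %s (1 header line + row)",
        path, paste(bad + 1L, collapse = ", ")
      ),
      class = "rulerbench_reference_error"
    )
  }
  reference_table(tab, name = name)
}

#' Write a reference copy-number table to TSV
#'
#' The written file round-trips through [read_reference_table()] losslessly
#' (numeric fields within 1e-9 relative).
#'
#' @param table A [reference_table()].
#' @param path Output path.
#' @export
write_reference_table <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
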
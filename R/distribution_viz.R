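#' Specify histogram bins over log10 copies per cell
#'
#' Exact equal-width bins over a stated range. This deliberately deviates
#' from base R's "pretty" break selection, which treats the bin count as a
#' suggestion: a fixed bin count and range make overlays and companion tables
#' reproducible and comparable across experiments.
#'
#' @param n_bins Number of bins (default 30; overlays often use 60 for
#'   granularity).
#' @param range Length-2 numeric `(lo, hi)` in log10 copies. Typically the
#'   reference table's min/max so every experiment bins on shared edges.
#' @return A `bins_spec` list with `n_bins`, `range`, `edges`, `width`.
#' @export
bins_spec <- function(n_bins = 30L, range) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, length(range) == 2L, range[2L] > range[1L])
  structure(
    list(
      n_bins = n_bins,
      range = as.numeric(range),
      edges = seq(range[1L], range[2L], length.out = n_bins + 1L),
      width = (range[2L] - range[1L]) / n_bins
    ),
    class = "bins_spec"
  )
}

#' Default bins for a reference table
#'
#' @param reference A [reference_table()].
#' @param n_bins Number of bins.
#' @return A [bins_spec()] spanning the reference's log10-copies range.
#' @export
reference_bins <- function(reference, n_bins = 30L) {
  stopifnot(inherits(reference, "reference_table"))
  bins_spec(n_bins, range(reference$log10_copies))
}

#' Bin log10 copy numbers into a histogram
#'
#' Equal-width bins over the spec's range with half-open `[lo_i, hi_i)`
#' intervals, last bin closed; values outside the range are clamped into the
#' end bins so every value is counted. Densities are
#' `counts / (n_total * bin width)`, integrating to 1.
#'
#' @param values Non-empty numeric vector of log10 copies per cell.
#' @param spec A [bins_spec()].
#' @return A `log_histogram`: `edges`, `mids`, `counts`, `densities`,
#'   `n_total`, `apex_bin` (index of the maximal bin, ties broken toward the
#'   lower-copy bin).
#' @export
bin_log_copies <- function(values, spec) {
  stopifnot(inherits(spec, "bins_spec"))
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    rlang::abort("cannot bin an empty set of values",
      class = "rulerbench_histogram_error"
    )
  }
  lo <- spec$range[1L]
  idx <- floor((values - lo) / spec$width) + 1L
  idx <- pmin(pmax(idx, 1L), spec$n_bins) # clamp out-of-range and hi edge
  counts <- tabulate(idx, nbins = spec$n_bins)
  n_total <- length(values)
  structure(
    list(
      edges = spec$edges,
      mids = (spec$edges[-1L] + spec$edges[-length(spec$edges)]) / 2,
      counts = counts,
      densities = counts / (n_total * spec$width),
      n_total = n_total,
      apex_bin = which.max(counts) # first max = lower-copy bin on ties
    ),
    class = "log_histogram"
  )
}

#' @export
print.log_histogram <- function(x, ...) {
  cat(sprintf(
    "<log_histogram> %d bins over [%.3g, %.3g], n = %d, apex bin %d\n",
    length(x$counts), x$edges[1L], x$edges[length(x$edges)],
    x$n_total, x$apex_bin
  ))
  invisible(x)
}

#' Apex of a copy-number histogram
#'
#' The midpoint of the modal bin — the vertical reference line used to
#' visualize how a method's copy-number distribution shifts relative to
#' another's. Ties break toward the lower-copy bin, the conservative choice
#' for sensitivity claims.
#'
#' @param hist A [bin_log_copies()] result.
#' @return The apex bin midpoint in log10 copies.
#' @export
find_apex <- function(hist) {
  stopifnot(inherits(hist, "log_histogram"))
  if (hist$n_total == 0L) {
    rlang::abort("apex undefined for an empty histogram",
      class = "rulerbench_histogram_error"
    )
  }
  hist$mids[hist$apex_bin]
}

shared_edges <- function(hists) {
  edges <- hists[[1L]]$edges
  for (h in hists[-1L]) {
    if (length(h$edges) != length(edges) ||
        max(abs(h$edges - edges)) > 1e-9) {
      rlang::abort("histograms do not share bin edges",
        class = "rulerbench_alignment_error"
      )
    }
  }
  edges
}

histogram_table <- function(reference_hist, experiment_hists) {
  edges <- shared_edges(c(list(reference_hist), unname(experiment_hists)))
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1L],
    reference_count = reference_hist$counts,
    reference_density = reference_hist$densities
  )
  for (nm in names(experiment_hists)) {
    out[[paste0(nm, "_count")]] <- experiment_hists[[nm]]$counts
    out[[paste0(nm, "_density")]] <- experiment_hists[[nm]]$densities
  }
  out
}

#' Render copy-number distributions with a reference backdrop
#'
#' Draws the reference distribution in grey with experiment distributions
#' overlaid in color, by protein counts or density-normalized, optionally with
#' a vertical apex reference line. Alongside each image a companion TSV of
#' the plotted bins, counts and densities is written so every figure is
#' numerically reproducible; output is deterministic for fixed inputs.
#'
#' @param reference_hist [bin_log_copies()] result for the reference.
#' @param experiment_hists Named list of histograms sharing the reference's
#'   edges (may be empty).
#' @param style `"counts"` or `"density"`.
#' @param apex_line Optional x position (log10 copies) for a vertical
#'   reference line.
#' @param out Output path stem; `<out>.tsv` plus one image per device.
#' @param devices Image formats, any of `"png"`, `"svg"`.
#' @param width,height Image size in inches.
#' @return Invisibly, list with `tsv`, `images`, and the companion `table`.
#' @export
render_distribution <- function(reference_hist, experiment_hists = list(),
                                style = c("counts", "density"),
                                apex_line = NULL, out,
                                devices = "png",
                                width = 7, height = 5) {
  style <- match.arg(style)
  devices <- match.arg(devices, c("png", "svg"), several.ok = TRUE)
  tab <- histogram_table(reference_hist, experiment_hists)
  tsv_path <- paste0(out, ".tsv")
  readr::write_tsv(tab, tsv_path, progress = FALSE)

  value_of <- function(h) if (style == "counts") h$counts else h$densities
  mids <- reference_hist$mids
  w <- mids[2L] - mids[1L]
  plot_dat <- tibble::tibble(
    mid = mids, value = value_of(reference_hist), set = "reference"
  )
  for (nm in names(experiment_hists)) {
    plot_dat <- dplyr::bind_rows(
      plot_dat,
      tibble::tibble(
        mid = mids, value = value_of(experiment_hists[[nm]]), set = nm
      )
    )
  }
  plot_dat$set <- factor(
    plot_dat$set,
    levels = c("reference", names(experiment_hists))
  )
  pal <- c("grey70", grDevices::hcl.colors(
    max(1L, length(experiment_hists)),
    palette = "Dark 3"
  )[seq_along(experiment_hists)])
  p <- ggplot2::ggplot(
    plot_dat,
    ggplot2::aes(x = .data$mid, y = .data$value, fill = .data$set)
  ) +
    ggplot2::geom_col(
      data = function(d) d[d$set == "reference", ],
      width = w, alpha = 0.9
    ) +
    ggplot2::geom_col(
      data = function(d) d[d$set != "reference", ],
      width = w, alpha = 0.55, position = "identity"
    ) +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::labs(
      x = "log10 copies per cell",
      y = if (style == "counts") "protein count" else "density"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(apex_line)) {
    p <- p + ggplot2::geom_vline(xintercept = apex_line, linetype = "dashed")
  }
  images <- character(0)
  for (dev in devices) {
    img <- paste0(out, ".", dev)
    if (dev == "png") {
      ggplot2::ggsave(img, p,
        width = width, height = height, dpi = 150,
        device = grDevices::png, type = "cairo"
      )
    } else {
      ggplot2::ggsave(img, p,
        width = width, height = height,
        device = grDevices::svg
      )
    }
    images <- c(images, img)
  }
  invisible(list(tsv = tsv_path, images = images, table = tab))
}
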
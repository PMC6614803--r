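# Headline lane statistics and the waterfall summary.

#' Quantify a smear curve
#'
#' The two headline shearing-QC statistics: the signal-weighted mean fragment
#' size over the full calibrated grid, and the fraction of signal falling
#' inside a target size window (default 200-600 bp, the usual ChIP shearing
#' target).  Both use plain sums over the uniform bp grid:
#' `mean_bp = sum(d_i * bp_i) / sum(d_i)` and
#' `frac = sum(d_i over lo <= bp_i <= hi) / sum(d_i)`; the denominator is the
#' calibrated region, not the whole lane.
#'
#' @param curve a `smear_curve` (normalization does not affect the results).
#' @param range_lo,range_hi size window in bp, `range_lo < range_hi`.
#' @return object of class `lane_quant`: `mean_bp`, `frac_in_range`,
#'   `range_lo`, `range_hi`, `total_signal` (sum of density times grid step),
#'   `lane_label`, `flags` (character vector; `"undefined"` for an all-zero
#'   curve, in which case `mean_bp` and `frac_in_range` are `NA`).
#' @export
quantify_lane <- function(curve, range_lo = 200, range_hi = 600) {
  stopifnot(inherits(curve, "smear_curve"))
  stopifnot_scalar_number(range_lo, "range_lo")
  stopifnot_scalar_number(range_hi, "range_hi")
  if (range_lo >= range_hi)
    gq_validation_error("`range_lo` must be < `range_hi`")
  if (!length(curve$bp_grid)) gq_validation_error("empty smear curve")
  d <- curve$density
  bp <- curve$bp_grid
  step <- if (length(bp) > 1) bp[2] - bp[1] else 1
  tot <- sum(d)
  flags <- character()
  if (tot <= 0) {
    mean_bp <- NA_real_
    frac <- NA_real_
    flags <- "undefined"
  } else {
    mean_bp <- sum(d * bp) / tot
    inr <- bp >= range_lo & bp <= range_hi
    frac <- sum(d[inr]) / tot
  }
  structure(
    list(mean_bp = mean_bp, frac_in_range = frac,
         range_lo = range_lo, range_hi = range_hi,
         total_signal = tot * step, lane_label = curve$lane_label,
         flags = flags),
    class = "lane_quant")
}

#' @export
print.lane_quant <- function(x, ...) {
  cat(sprintf("<lane_quant> %s: mean %.1f bp, %.1f%% in [%g, %g] bp\n",
              x$lane_label, x$mean_bp, 100 * x$frac_in_range,
              x$range_lo, x$range_hi))
  invisible(x)
}

#' Assemble (and optionally render) a waterfall summary across lanes
#'
#' Collects per-lane best-fit smear curves in run order together with their
#' quantifications.  All curves must share one bp grid; curves on a compatible
#' but unequal grid are linearly resampled onto the first curve's grid.  When
#' `out_path` is given the stacked curves are drawn to a PNG or SVG file, each
#' trace offset along a depth axis and labelled with its mean size and
#' in-window fraction.
#'
#' @param curves list of `smear_curve` (lane 1 first).
#' @param quants matching list of `lane_quant`.
#' @param out_path optional `.png` or `.svg` output file.
#' @return object of class `waterfall_data` with `curves` and `quants`.
#' @export
build_waterfall <- function(curves, quants, out_path = NULL) {
  if (!length(curves)) gq_validation_error("no curves supplied")
  if (length(curves) != length(quants))
    gq_validation_error("`curves` and `quants` must have the same length")
  lapply(curves, function(s) stopifnot(inherits(s, "smear_curve")))
  lapply(quants, function(q) stopifnot(inherits(q, "lane_quant")))

  ref <- curves[[1]]$bp_grid
  curves <- lapply(curves, function(s) {
    if (length(s$bp_grid) == length(ref) && all(s$bp_grid == ref)) return(s)
    rng_ok <- max(min(s$bp_grid), min(ref)) < min(max(s$bp_grid), max(ref))
    if (!rng_ok)
      gq_validation_error("smear curves lie on disjoint bp grids")
    s$density <- stats::approx(s$bp_grid, s$density, xout = ref, rule = 2)$y
    s$bp_grid <- ref
    s
  })

  wf <- structure(list(curves = curves, quants = quants),
                  class = "waterfall_data")
  if (!is.null(out_path)) plot_waterfall(wf, out_path)
  wf
}

plot_waterfall <- function(wf, out_path, width = 900, height = 600) {
  ext <- tolower(tools::file_ext(out_path))
  open_dev <- switch(ext,
    png = function(p) grDevices::png(p, width = width, height = height),
    svg = function(p) grDevices::svg(p, width = width / 100,
                                     height = height / 100),
    gq_io_error(sprintf("unsupported waterfall format '.%s'", ext)))
  atomic_write(out_path, function(tmp) {
    open_dev(tmp)
    on.exit(grDevices::dev.off(), add = TRUE)
    n <- length(wf$curves)
    offset <- 0.75
    bp <- wf$curves[[1]]$bp_grid
    graphics::plot(NA, xlim = range(bp), ylim = c(0, 1 + offset * n),
                   xlab = "Size (bp)", ylab = "Lane", yaxt = "n",
                   main = "Smear waterfall")
    graphics::axis(2, at = offset * (seq_len(n) - 1) + 0.5,
                   labels = vapply(wf$curves, `[[`, "", "lane_label"),
                   las = 1, cex.axis = 0.7)
    for (i in rev(seq_len(n))) {
      y0 <- offset * (i - 1)
      d <- wf$curves[[i]]$density
      graphics::polygon(c(bp, rev(bp)), c(y0 + d, rep(y0, length(bp))),
                        col = grDevices::adjustcolor("steelblue", 0.5),
                        border = "grey25")
      q <- wf$quants[[i]]
      lbl <- if (is.na(q$mean_bp)) "empty" else
        sprintf("%.0f bp, %.0f%%", q$mean_bp, 100 * q$frac_in_range)
      graphics::text(max(bp), y0 + 0.45, lbl, adj = c(1, 0), cex = 0.6)
    }
  })
  invisible(out_path)
}

#' Run the full gel quantification pipeline on one image
#'
#' Convenience wrapper: lane detection, ladder calibration, per-lane profile
#' extraction, bp re-indexing, smoothing and quantification for every sample
#' lane (all lanes except the ladder).
#'
#' @param img a [gel_image].
#' @param ladder a [ladder_spec].
#' @param n_lanes total lane count including the ladder.
#' @param ladder_lane ladder lane index.
#' @param range_lo,range_hi quantification window in bp.
#' @param grid_step bp grid spacing.
#' @param jacobian apply the density Jacobian when re-indexing.
#' @param model calibration model.
#' @return list with `geometry`, `calibration`, `bands`, `waterfall`
#'   (a `waterfall_data` over the sample lanes) and `table` (a data.frame of
#'   per-lane statistics).
#' @export
analyze_gel <- function(img, ladder, n_lanes, ladder_lane = 1L,
                        range_lo = 200, range_hi = 600, grid_step = 5,
                        jacobian = FALSE, model = "semilog_linear") {
  geom <- detect_lanes(img, n_lanes, ladder_lane)
  lad_prof <- extract_profile(img, geom, geom$ladder_lane_index)
  bands <- detect_ladder_bands(lad_prof, ladder)
  cal <- fit_calibration(bands, model = model)

  sample_lanes <- setdiff(seq_len(n_lanes), geom$ladder_lane_index)
  curves <- list(); quants <- list()
  for (k in seq_along(sample_lanes)) {
    li <- sample_lanes[k]
    prof <- extract_profile(img, geom, li)
    raw <- rescale_to_bp(prof, cal, grid_step = grid_step,
                         jacobian = jacobian,
                         lane_label = sprintf("lane %d", k))
    sm <- fit_smear_curve(raw)
    curves[[k]] <- sm
    quants[[k]] <- quantify_lane(sm, range_lo, range_hi)
  }
  wf <- build_waterfall(curves, quants)
  tab <- data.frame(
    lane_label = vapply(quants, `[[`, "", "lane_label"),
    mean_bp = vapply(quants, `[[`, 0, "mean_bp"),
    frac_in_range = vapply(quants, `[[`, 0, "frac_in_range"),
    range_lo = range_lo, range_hi = range_hi,
    total_signal = vapply(quants, `[[`, 0, "total_signal"),
    flags = vapply(quants, function(q)
      paste(q$flags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  if (img$n_saturated > 0)
    warning(sprintf("%d saturated pixels in image; quantification proceeds",
                    img$n_saturated), call. = FALSE)
  list(geometry = geom, calibration = cal, bands = bands,
       waterfall = wf, table = tab)
}
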
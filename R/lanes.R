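# Lane detection and per-lane migration profiles.

#' Detect lane positions on a gel image
#'
#' Projects the image onto the lateral axis (column sums), smooths the
#' projection with a moving average (window = image width / (4 * n_lanes),
#' at least 3 px) and takes the `n_lanes` highest-prominence local maxima as
#' lane centers, sorted left to right.  Equal-prominence ties are broken by
#' the leftmost column so the result is deterministic.  When fewer maxima are
#' found than lanes requested, lanes are placed at equal spacing across the
#' occupied span (columns whose smoothed projection exceeds 10% of its
#' maximum, or the full width for a blank image) and `low_confidence` is set.
#'
#' @param img a [gel_image].
#' @param n_lanes total number of lanes, ladder included.
#' @param ladder_lane 1-based index (left to right) of the ladder lane.
#' @return object of class `lane_geometry`: `lane_centers` (column indices),
#'   `lane_half_width` (px), `ladder_lane_index`, `low_confidence` flag.
#' @export
detect_lanes <- function(img, n_lanes, ladder_lane = 1L) {
  stopifnot(inherits(img, "gel_image"))
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 1L) gq_validation_error("`n_lanes` must be >= 1")
  nc <- ncol(img$pixels)
  if (n_lanes > nc / 4)
    gq_validation_error(sprintf(
      "n_lanes = %d exceeds image width / 4 = %.0f", n_lanes, nc / 4))
  if (ladder_lane < 1L || ladder_lane > n_lanes)
    gq_validation_error("`ladder_lane` must be in [1, n_lanes]")

  proj <- colSums(img$pixels)
  win <- max(3L, floor(nc / (4L * n_lanes)))
  sm <- running_mean(proj, win)
  peaks <- local_maxima(sm)
  low_confidence <- FALSE

  # greedy non-maximum suppression: accept peaks by descending prominence
  # (ties -> leftmost column), skipping any candidate closer than half the
  # expected lane pitch to an accepted one
  min_sep <- max(win, floor(nc / (2L * n_lanes)))
  ord <- order(-peaks$prominence, peaks$index)
  accepted <- integer()
  for (i in ord) {
    idx <- peaks$index[i]
    if (!length(accepted) || all(abs(accepted - idx) >= min_sep))
      accepted <- c(accepted, idx)
    if (length(accepted) == n_lanes) break
  }

  if (length(accepted) == n_lanes) {
    centers <- sort(accepted)
    # flat-topped lanes leave the raw maximum at the plateau edge; refine
    # each center to the local background-subtracted intensity centroid
    w <- if (n_lanes > 1L) max(win, floor(stats::median(diff(centers)) * 0.4))
         else max(win, floor(nc * 0.1))
    centers <- vapply(centers, function(ctr) {
      lo <- max(1L, ctr - w); hi <- min(nc, ctr + w)
      seg <- sm[lo:hi] - min(sm[lo:hi])
      if (sum(seg) <= 0) return(as.integer(ctr))
      as.integer(round(sum(seq(lo, hi) * seg) / sum(seg)))
    }, integer(1))
    centers <- sort(centers)
  } else {
    low_confidence <- TRUE
    occupied <- which(sm > 0.1 * max(sm))
    if (!length(occupied) || max(sm) <= 0) occupied <- seq_len(nc)
    span <- range(occupied)
    centers <- round(seq(span[1], span[2], length.out = n_lanes + 2L))
    centers <- centers[-c(1L, n_lanes + 2L)]
    if (n_lanes == 1L) centers <- round(mean(span))
  }

  half_width <- if (n_lanes > 1L)
    max(1L, floor(stats::median(diff(centers)) * 0.4))
  else
    max(1L, floor(nc * 0.1))

  structure(
    list(lane_centers = as.integer(centers),
         lane_half_width = as.integer(half_width),
         ladder_lane_index = as.integer(ladder_lane),
         low_confidence = low_confidence),
    class = "lane_geometry")
}

#' @export
print.lane_geometry <- function(x, ...) {
  cat(sprintf("<lane_geometry> %d lanes (ladder = %d), half width %d px%s\n",
              length(x$lane_centers), x$ladder_lane_index, x$lane_half_width,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Extract a background-subtracted migration profile for one lane
#'
#' Sums intensities across the lane window (center +/- half width, clipped to
#' the image) for every row, estimates the baseline as a rolling minimum with
#' a window of 10% of the rows (evaluated at half-window anchors and linearly
#' interpolated) and subtracts it, clamping negatives to zero.
#'
#' @param img a [gel_image].
#' @param geom a `lane_geometry` from [detect_lanes()].
#' @param lane_index 1-based lane index.
#' @param subtract_background set `FALSE` to keep the raw row sums.
#' @return object of class `lane_profile`: `intensity_by_row` (length =
#'   nrow(img)), `row_offset` (0; reserved for future cropping), `lane_index`.
#' @export
extract_profile <- function(img, geom, lane_index,
                            subtract_background = TRUE) {
  stopifnot(inherits(img, "gel_image"), inherits(geom, "lane_geometry"))
  lane_index <- as.integer(lane_index)
  if (lane_index < 1L || lane_index > length(geom$lane_centers))
    gq_validation_error(sprintf("lane_index %d out of range [1, %d]",
                                lane_index, length(geom$lane_centers)))
  ctr <- geom$lane_centers[lane_index]
  lo <- max(1L, ctr - geom$lane_half_width)
  hi <- min(ncol(img$pixels), ctr + geom$lane_half_width)
  prof <- rowSums(img$pixels[, lo:hi, drop = FALSE])
  if (subtract_background) {
    base <- rolling_min_baseline(prof)
    prof <- pmax(prof - base, 0)
    # suppress the clamped-noise pedestal: rows below 3x the robust per-row
    # noise scale (MAD of first differences) carry no resolvable signal and
    # would otherwise bias the size statistics toward the grid midpoint
    noise <- stats::mad(diff(prof)) / sqrt(2)
    prof[prof < 3 * noise] <- 0
  }
  structure(
    list(intensity_by_row = prof, row_offset = 0L, lane_index = lane_index),
    class = "lane_profile")
}
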
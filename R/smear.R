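# Re-indexing of lane profiles onto a linear bp axis and smear-curve smoothing.

#' Re-index a lane profile onto a uniform bp grid
#'
#' Maps each row of the profile to its calibrated fragment size and linearly
#' interpolates the intensity onto a uniform bp grid covering the calibrated
#' range.  By default no density Jacobian is applied: the signal is treated as
#' a curve re-indexed by size, so a flat profile stays flat.  With
#' `jacobian = TRUE` intensities are multiplied by `|d row / d bp|`
#' (`= b / (bp ln 10)` for the semi-log model), converting the curve into a
#' true mass density per bp.
#'
#' @param profile a `lane_profile`.
#' @param cal a `migration_calibration`.
#' @param grid_step bp spacing of the output grid.
#' @param jacobian apply the row-to-bp density correction.
#' @param lane_label label carried into the result.
#' @return object of class `smear_curve`: `bp_grid` (increasing, uniform),
#'   `density` (non-negative, not yet normalized), `lane_label`, `normalized`
#'   flag (FALSE).
#' @export
rescale_to_bp <- function(profile, cal, grid_step = 5, jacobian = FALSE,
                          lane_label = sprintf("lane %d",
                                               profile$lane_index %||% NA)) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(cal, "migration_calibration"))
  stopifnot_scalar_number(grid_step, "grid_step", positive = TRUE)
  nr <- length(profile$intensity_by_row)
  rows <- seq_len(nr)
  rng <- cal$valid_row_range
  inside <- rows >= rng[1] & rows <= rng[2]
  if (sum(inside) < 2L)
    gq_validation_error("calibrated row range does not overlap the profile")
  rows <- rows[inside]
  vals <- profile$intensity_by_row[inside]
  bp_at_rows <- calibration_bp(cal, rows)

  bp_lo <- min(bp_at_rows)
  bp_hi <- max(bp_at_rows)
  if ((bp_hi - bp_lo) < 2 * grid_step)
    gq_validation_error(sprintf(
      "calibrated bp range [%.1f, %.1f] spans fewer than 2 grid steps of %g",
      bp_lo, bp_hi, grid_step))
  grid <- seq(bp_lo, bp_hi, by = grid_step)

  ord <- order(bp_at_rows)
  dens <- stats::approx(bp_at_rows[ord], vals[ord], xout = grid, rule = 2)$y
  if (jacobian) {
    if (cal$model == "semilog_linear") {
      dens <- dens * (cal$b / (grid * log(10)))
    } else {
      eps <- grid_step / 10
      drow <- abs(calibration_row(cal, grid + eps) -
                  calibration_row(cal, grid - eps)) / (2 * eps)
      dens <- dens * drow
    }
  }
  structure(
    list(bp_grid = grid, density = pmax(dens, 0), lane_label = lane_label,
         normalized = FALSE),
    class = "smear_curve")
}

#' Smooth and peak-normalize a smear curve
#'
#' Applies locally weighted quadratic (loess, degree 2) smoothing with a
#' window of 5% of the grid points (at least 5 points), clamps negatives and
#' rescales so the maximum equals 1.  An all-zero curve is returned unchanged
#' (still all-zero), avoiding a divide-by-zero.
#'
#' @param curve a `smear_curve`.
#' @param window_frac smoothing window as a fraction of the grid length.
#' @return a `smear_curve` with `normalized = TRUE` and `max(density) == 1`
#'   (or all-zero).
#' @export
fit_smear_curve <- function(curve, window_frac = 0.05) {
  stopifnot(inherits(curve, "smear_curve"))
  n <- length(curve$bp_grid)
  if (n == 0L) gq_validation_error("empty smear curve")
  y <- curve$density
  if (max(y) <= 0) {
    curve$density <- rep(0, n)
    curve$normalized <- TRUE
    return(curve)
  }
  k <- max(5L, ceiling(window_frac * n))
  if (n > k) {
    span <- min(1, k / n)
    sm <- tryCatch(
      stats::predict(stats::loess(y ~ x, data.frame(x = curve$bp_grid, y = y),
                                  span = span, degree = 2,
                                  family = "gaussian",
                                  control = stats::loess.control(
                                    surface = "direct"))),
      error = function(e) y)
    y <- pmax(sm, 0)
  }
  mx <- max(y)
  curve$density <- if (mx > 0) y / mx else rep(0, n)
  curve$normalized <- TRUE
  curve
}

#' @export
print.smear_curve <- function(x, ...) {
  cat(sprintf("<smear_curve> %s: %d points over [%.0f, %.0f] bp%s\n",
              x$lane_label, length(x$bp_grid), min(x$bp_grid), max(x$bp_grid),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}
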
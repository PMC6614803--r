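# Ladder band assignment and migration calibration.
#
# DNA fragments migrate a distance approximately linear in log10(size):
#   d = a - b * log10(bp),  b > 0.
# The ladder lane carries K fragments of known size; matching its K brightest
# consistent bands to those sizes calibrates the whole gel.

#' Ladder specification
#'
#' @param sizes_bp fragment sizes in bp, largest first (i.e. in order of
#'   increasing migration distance). Must be strictly decreasing, >= 3 sizes.
#' @param name label.
#' @return object of class `ladder_spec`.
#' @export
ladder_spec <- function(sizes_bp, name = "ladder") {
  sizes_bp <- as.numeric(sizes_bp)
  if (length(sizes_bp) < 3L)
    gq_validation_error("a ladder needs at least 3 sizes")
  if (any(!is.finite(sizes_bp)) || any(sizes_bp <= 0))
    gq_validation_error("ladder sizes must be finite and > 0")
  if (any(diff(sizes_bp) >= 0))
    gq_validation_error("ladder sizes must be strictly decreasing (largest first)")
  structure(list(sizes_bp = sizes_bp, name = name), class = "ladder_spec")
}

#' Match ladder bands to known sizes
#'
#' Finds local maxima of the ladder-lane profile, keeps the most prominent
#' candidates, and selects the monotone assignment of K candidate rows to the
#' K ladder sizes (largest size at the smallest row) that minimizes the
#' residual sum of squares of a semi-log line `row ~ log10(bp)`.  Searching
#' over monotone assignments (rows strictly increasing) makes the matcher
#' robust to spurious bright specks, which are skipped when they break the
#' semi-log trend.
#'
#' @param profile a `lane_profile` from the ladder lane.
#' @param ladder a [ladder_spec].
#' @param max_candidates cap on the number of peak candidates considered
#'   (most prominent kept); bounds the assignment search.
#' @return data.frame with columns `row`, `bp`, rows strictly increasing and
#'   bp strictly decreasing.
#' @export
detect_ladder_bands <- function(profile, ladder, max_candidates = NULL) {
  stopifnot(inherits(profile, "lane_profile"), inherits(ladder, "ladder_spec"))
  sizes <- ladder$sizes_bp
  K <- length(sizes)
  peaks <- local_maxima(profile$intensity_by_row)
  # ignore near-noise maxima
  if (nrow(peaks))
    peaks <- peaks[peaks$prominence > 0.01 * max(peaks$height), , drop = FALSE]
  if (nrow(peaks) < K)
    gq_calibration_error(sprintf(
      "ladder has %d sizes but only %d candidate bands were found",
      K, nrow(peaks)))
  max_candidates <- max_candidates %||% (K + 8L)
  if (nrow(peaks) > max_candidates) {
    keep <- order(-peaks$prominence, peaks$index)[seq_len(max_candidates)]
    peaks <- peaks[sort(keep), , drop = FALSE]
  }
  rows <- peaks$index          # increasing by construction
  M <- length(rows)
  lx <- log10(sizes)           # decreasing

  if (M == K) {
    sel <- seq_len(K)
  } else {
    combos <- utils::combn(M, K)
    x <- lx
    sxx <- sum((x - mean(x))^2)
    best <- Inf; sel <- combos[, 1]
    for (j in seq_len(ncol(combos))) {
      y <- rows[combos[, j]]
      # RSS of y ~ x in closed form
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      rss <- sum((y - mean(y))^2) - sxy^2 / sxx
      slope <- sxy / sxx
      if (slope >= 0) next     # migration must decrease with size
      if (rss < best - 1e-12) { best <- rss; sel <- combos[, j] }
    }
    if (!is.finite(best))
      gq_calibration_error(
        "no monotone semi-log-consistent assignment of bands to ladder sizes")
  }
  sel_rows <- rows[sel]
  # sub-pixel refinement: log-parabolic interpolation through the peak and
  # its neighbours, exact for a Gaussian band profile
  y <- profile$intensity_by_row
  n <- length(y)
  refined <- vapply(sel_rows, function(i) {
    if (i <= 1L || i >= n) return(as.numeric(i))
    y3 <- y[(i - 1L):(i + 1L)]
    if (any(y3 <= 0)) return(as.numeric(i))
    l <- log(y3)
    den <- l[1] - 2 * l[2] + l[3]
    if (den >= 0) return(as.numeric(i))
    delta <- 0.5 * (l[1] - l[3]) / den
    i + max(-0.5, min(0.5, delta))
  }, numeric(1))
  if (any(diff(refined) <= 0)) refined <- as.numeric(sel_rows)
  data.frame(row = refined, bp = sizes)
}

#' Fit a migration-distance-to-size calibration
#'
#' Two models: `semilog_linear`, an ordinary least-squares fit of
#' `row = a - b * log10(bp)` with its r-squared; and
#' `monotone_interpolation`, piecewise-linear interpolation of row versus
#' log10(bp) through the band knots.  For both models extrapolation beyond the
#' outermost bands is limited to half of the ladder's end gaps; `valid_row_range`
#' records the usable row span.
#'
#' @param bands data.frame with columns `row` (strictly increasing) and `bp`
#'   (strictly decreasing), e.g. from [detect_ladder_bands()].
#' @param model `"semilog_linear"` or `"monotone_interpolation"`.
#' @return object of class `migration_calibration` with elements `model`,
#'   `a`, `b` (semi-log coefficients; for the interpolation model those of an
#'   auxiliary global fit), `knots`, `valid_row_range`, `fit_r2`.
#' @export
fit_calibration <- function(bands,
                            model = c("semilog_linear",
                                      "monotone_interpolation")) {
  model <- match.arg(model)
  if (!is.data.frame(bands) || !all(c("row", "bp") %in% names(bands)))
    gq_validation_error("`bands` must be a data.frame with columns row, bp")
  if (nrow(bands) < 3L)
    gq_validation_error("calibration needs at least 3 bands")
  if (any(diff(bands$row) <= 0) || any(diff(bands$bp) >= 0))
    gq_validation_error(
      "band rows must be strictly increasing and bp strictly decreasing")

  x <- log10(bands$bp)
  y <- bands$row
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  b <- -slope
  if (b <= 0)
    gq_calibration_error("fitted migration slope b <= 0: not a valid gel")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0

  gaps <- diff(y)
  row_min <- y[1] - gaps[1] / 2
  row_max <- y[length(y)] + gaps[length(gaps)] / 2

  structure(
    list(model = model, a = a, b = b,
         knots = bands,
         valid_row_range = c(row_min, row_max),
         fit_r2 = r2),
    class = "migration_calibration")
}

#' @export
print.migration_calibration <- function(x, ...) {
  cat(sprintf(
    "<migration_calibration> %s: row = %.2f - %.2f log10(bp), r2 = %.4f\n",
    x$model, x$a, x$b, x$fit_r2))
  cat(sprintf("  valid rows [%.1f, %.1f] -> bp [%.0f, %.0f]\n",
              x$valid_row_range[1], x$valid_row_range[2],
              calibration_bp(x, x$valid_row_range[2]),
              calibration_bp(x, x$valid_row_range[1])))
  invisible(x)
}

#' Fragment size at a migration row
#'
#' Inverse of the calibration map; strictly decreasing in `row` over the valid
#' range.  Rows outside `valid_row_range` return `NA` unless `clip = TRUE`,
#' which evaluates at the nearest valid row.
#'
#' @param cal a `migration_calibration`.
#' @param row numeric vector of (possibly fractional) row positions.
#' @param clip clamp rows into the valid range instead of returning `NA`.
#' @return bp values.
#' @export
calibration_bp <- function(cal, row, clip = FALSE) {
  stopifnot(inherits(cal, "migration_calibration"))
  rng <- cal$valid_row_range
  out_of <- row < rng[1] | row > rng[2]
  if (clip) row <- pmin(pmax(row, rng[1]), rng[2])
  bp <- if (cal$model == "semilog_linear") {
    10^((cal$a - row) / cal$b)
  } else {
    lx <- stats::approx(cal$knots$row, log10(cal$knots$bp), xout = row,
                        rule = 2)$y
    # linear extrapolation in (row, log10 bp) within the allowed margin
    k <- cal$knots
    n <- nrow(k)
    sl_lo <- (log10(k$bp[2]) - log10(k$bp[1])) / (k$row[2] - k$row[1])
    sl_hi <- (log10(k$bp[n]) - log10(k$bp[n - 1])) / (k$row[n] - k$row[n - 1])
    below <- row < k$row[1]
    above <- row > k$row[n]
    lx[below] <- log10(k$bp[1]) + sl_lo * (row[below] - k$row[1])
    lx[above] <- log10(k$bp[n]) + sl_hi * (row[above] - k$row[n])
    10^lx
  }
  if (!clip) bp[out_of] <- NA_real_
  bp
}

#' Migration row for a fragment size (forward map)
#'
#' @param cal a `migration_calibration`.
#' @param bp fragment sizes.
#' @return row positions (fractional).
#' @export
calibration_row <- function(cal, bp) {
  stopifnot(inherits(cal, "migration_calibration"))
  if (cal$model == "semilog_linear") {
    cal$a - cal$b * log10(bp)
  } else {
    k <- cal$knots
    n <- nrow(k)
    # invert the piecewise-linear (log10 bp -> row) map; log10 bp decreasing
    lx <- log10(bp)
    kx <- rev(log10(k$bp)); ky <- rev(k$row)
    y <- stats::approx(kx, ky, xout = lx, rule = 2)$y
    sl_lo <- (ky[2] - ky[1]) / (kx[2] - kx[1])
    sl_hi <- (ky[n] - ky[n - 1]) / (kx[n] - kx[n - 1])
    below <- lx < kx[1]; above <- lx > kx[n]
    y[below] <- ky[1] + sl_lo * (lx[below] - kx[1])
    y[above] <- ky[n] + sl_hi * (lx[above] - kx[n])
    y
  }
}
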
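# Synthetic gel-image generator.
#
# A lane's stained signal is modelled as the mass distribution of sheared
# fragments over log10(size): since migration distance is linear in
# log10(size), that distribution *is* (up to the constant 1/b) the physical
# intensity per row.  Each smear is a mixture of log-normal components
# parameterized by mass weight, median size and sigma on the log10 scale;
# with sigma -> 0 a component degenerates to a sharp band.  The ladder is
# rendered as discrete equal-mass bands at its semi-log rows.  Band spread is
# a Gaussian point-spread along the migration axis; the camera adds a linear
# vertical background gradient and iid Gaussian noise.

#' Log-normal mixture describing a sheared-fragment smear
#'
#' @param medians_bp median sizes of the components (bp).
#' @param sigmas_log10 standard deviations on the log10(size) scale.
#' @param weights mass weights, summing to 1 (recycled/normalized input is
#'   rejected: weights must already sum to 1 within 1e-9).
#' @return object of class `fragment_distribution`.
#' @export
fragment_distribution <- function(medians_bp, sigmas_log10,
                                  weights = rep(1 / length(medians_bp),
                                                length(medians_bp))) {
  medians_bp <- as.numeric(medians_bp)
  sigmas_log10 <- rep_len(as.numeric(sigmas_log10), length(medians_bp))
  weights <- as.numeric(weights)
  if (length(weights) != length(medians_bp))
    gq_validation_error("one weight per component required")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9)
    gq_validation_error("weights must be > 0 and sum to 1 (tolerance 1e-9)")
  if (any(medians_bp <= 0) || any(sigmas_log10 <= 0))
    gq_validation_error("medians and sigmas must be > 0")
  structure(list(components = data.frame(weight = weights,
                                         median_bp = medians_bp,
                                         sigma_log10 = sigmas_log10)),
            class = "fragment_distribution")
}

# Mass density per unit log10(size), evaluated at x = log10(bp).
dist_density_log10 <- function(dist, x) {
  cmp <- dist$components
  rowSums(vapply(seq_len(nrow(cmp)), function(k)
    cmp$weight[k] * stats::dnorm(x, log10(cmp$median_bp[k]),
                                 cmp$sigma_log10[k]),
    numeric(length(x))))
}

#' True smear statistics of a fragment distribution
#'
#' Computes the mean fragment size and in-window signal fraction that a
#' perfect, noise-free analysis of the distribution would report, evaluating
#' the truncated log-normal mixture moments in closed form (exact, and stable
#' even for near-delta components where adaptive quadrature fails).  Under the
#' default `"gel"` convention (no Jacobian: the lane signal re-indexed onto a
#' uniform bp axis, exactly what the analysis pipeline measures) the curve at
#' size s is the mass density per log10(size), g(log10 s), so
#' `mean = int s g ds / int g ds` and
#' `frac = int_[lo,hi] g ds / int g ds`, integrals over the calibrated size
#' range.  Under `"mass"` the proper mass density per bp,
#' `g(log10 s) / (s ln 10)`, is used instead.
#'
#' @param dist a [fragment_distribution].
#' @param range_lo,range_hi size window in bp.
#' @param convention `"gel"` (no Jacobian, default) or `"mass"`.
#' @param cal_range length-2 numeric, the calibrated size range over which the
#'   analysis integrates; defaults to effectively unbounded.
#' @return list with `mean_bp` and `frac_in_range`.
#' @export
true_stats <- function(dist, range_lo = 200, range_hi = 600,
                       convention = c("gel", "mass"),
                       cal_range = c(1e-3, Inf)) {
  stopifnot(inherits(dist, "fragment_distribution"))
  convention <- match.arg(convention)
  if (range_lo >= range_hi) gq_validation_error("range_lo must be < range_hi")
  cmp <- dist$components
  ln10 <- log(10)
  # truncated log10-normal moment: int_{a}^{b} 10^(k x) dnorm(x; mu, sg) dx
  # (a, b on the log10 scale), exact via the shifted normal CDF -- robust
  # where adaptive quadrature loses near-delta components
  tmom <- function(k, mu, sg, a, b) {
    if (a >= b) return(rep(0, length(mu)))
    shift <- k * sg * ln10
    10^(k * mu) * exp((shift)^2 / 2) *
      (stats::pnorm((b - mu) / sg - shift) -
         stats::pnorm((a - mu) / sg - shift))
  }
  xlo <- log10(max(cal_range[1], 1e-12))
  xhi <- if (is.finite(cal_range[2])) log10(cal_range[2]) else Inf
  wlo <- max(xlo, log10(max(range_lo, 1e-12)))
  whi <- min(xhi, log10(range_hi))
  mix <- function(k, a, b)
    sum(cmp$weight * tmom(k, log10(cmp$median_bp), cmp$sigma_log10, a, b))
  # gel convention: the re-indexed curve c(s) = g(log10 s), so every
  # integral in s picks up one power of s relative to the log10 density;
  # mass convention: proper density per bp, one power fewer
  k0 <- if (convention == "gel") 1 else 0
  total <- mix(k0, xlo, xhi)
  if (total <= 0)
    return(list(mean_bp = NA_real_, frac_in_range = NA_real_))
  list(mean_bp = mix(k0 + 1, xlo, xhi) / total,
       frac_in_range = mix(k0, wlo, whi) / total)
}

#' Simulator configuration
#'
#' @param a,b semi-log migration coefficients: row = a - b * log10(bp).
#' @param psf_sigma Gaussian band point-spread along the migration axis (px).
#' @param background_base,background_gradient background level at row 1 and
#'   its increment per row (fractions of full scale).
#' @param noise_sigma iid Gaussian camera noise, as a fraction of the peak
#'   signal amplitude (`exposure`).
#' @param shape image (rows, cols).
#' @param lane_centers column indices of all lanes (ladder included).
#' @param lane_half_width half width of each lane in px.
#' @param ladder_lane index (into `lane_centers`) of the ladder lane.
#' @param exposure peak signal amplitude on the [0, 1] intensity scale.
#' @param seed RNG seed used by [simulate_gel()].
#' @return object of class `gel_sim_config`.
#' @export
gel_sim_config <- function(a = 950, b = 300, psf_sigma = 3,
                           background_base = 0.05,
                           background_gradient = 5e-5,
                           noise_sigma = 0.02,
                           shape = c(480, 520),
                           lane_centers = NULL, lane_half_width = NULL,
                           ladder_lane = 1L, exposure = 0.7, seed = 1L) {
  stopifnot_scalar_number(b, "b", positive = TRUE)
  stopifnot_scalar_number(psf_sigma, "psf_sigma", positive = TRUE)
  if (noise_sigma < 0) gq_validation_error("noise_sigma must be >= 0")
  shape <- as.integer(shape)
  if (is.null(lane_centers)) {
    n <- 13L
    lane_centers <- round(seq(0.06, 0.94, length.out = n) * shape[2])
  }
  lane_centers <- as.integer(lane_centers)
  if (is.null(lane_half_width))
    lane_half_width <- max(2L, floor(stats::median(diff(lane_centers)) * 0.35))
  if (min(lane_centers) - lane_half_width < 1 ||
      max(lane_centers) + lane_half_width > shape[2])
    gq_validation_error("lane layout does not fit inside the image")
  structure(
    list(a = a, b = b, psf_sigma = psf_sigma,
         background_base = background_base,
         background_gradient = background_gradient,
         noise_sigma = noise_sigma, shape = shape,
         lane_centers = lane_centers,
         lane_half_width = as.integer(lane_half_width),
         ladder_lane = as.integer(ladder_lane),
         exposure = exposure, seed = as.integer(seed)),
    class = "gel_sim_config")
}

# Lateral lane cross-section: flat top with cosine-tapered edges.
lane_lateral_weights <- function(half_width) {
  w <- 2L * half_width + 1L
  edge <- max(1L, round(half_width * 0.3))
  prof <- rep(1, w)
  ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / (edge + 1)))
  prof[seq_len(edge)] <- ramp
  prof[w + 1L - seq_len(edge)] <- ramp
  prof
}

#' Simulate a gel image with known ground truth
#'
#' Renders one ladder lane and one sample lane per supplied distribution.
#' Sample-lane intensity at row r is the mixture mass density per log10(size)
#' evaluated at the size migrating to r, convolved with the Gaussian
#' point-spread; ladder bands are equal-mass Gaussian bumps at their semi-log
#' rows.  The noiseless signal layer is scaled so its maximum equals
#' `exposure`, then background and seeded Gaussian noise are added and the
#' result is clipped to [0, 1].
#'
#' @param dists list of [fragment_distribution], one per sample lane (the
#'   lanes other than `cfg$ladder_lane`, left to right).
#' @param ladder a [ladder_spec].
#' @param cfg a [gel_sim_config].
#' @param range_lo,range_hi window used for the ground-truth in-range
#'   fraction.
#' @return list with `image` (a [gel_image]) and `truth`, a list holding the
#'   per-lane true `mean_bp`/`frac_in_range` (computed by [true_stats()] over
#'   the calibrated range the analysis will see), `ladder_rows`, lane layout
#'   and the calibrated bp range.
#' @export
simulate_gel <- function(dists, ladder, cfg, range_lo = 200, range_hi = 600) {
  stopifnot(inherits(ladder, "ladder_spec"), inherits(cfg, "gel_sim_config"))
  if (!is.list(dists) || !all(vapply(dists, inherits, TRUE,
                                     "fragment_distribution")))
    gq_validation_error("`dists` must be a list of fragment_distribution")
  n_lanes <- length(cfg$lane_centers)
  if (length(dists) != n_lanes - 1L)
    gq_validation_error(sprintf(
      "need %d distributions for %d lanes (one is the ladder), got %d",
      n_lanes - 1L, n_lanes, length(dists)))

  nr <- cfg$shape[1]; ncl <- cfg$shape[2]
  ladder_rows <- cfg$a - cfg$b * log10(ladder$sizes_bp)
  bad <- which(ladder_rows < 1 | ladder_rows > nr)
  if (length(bad))
    gq_config_error(sprintf(
      "ladder band %g bp maps to row %.1f, outside the %d-row image",
      ladder$sizes_bp[bad[1]], ladder_rows[bad[1]], nr))

  rows <- seq_len(nr)
  x_of_row <- (cfg$a - rows) / cfg$b        # log10(bp) at each row
  signal <- matrix(0, nr, ncl)
  lat <- lane_lateral_weights(cfg$lane_half_width)

  paint <- function(profile, center) {
    cols <- (center - cfg$lane_half_width):(center + cfg$lane_half_width)
    signal[, cols] <<- signal[, cols] + outer(profile, lat)
  }

  sample_lanes <- setdiff(seq_len(n_lanes), cfg$ladder_lane)
  for (k in seq_along(sample_lanes)) {
    prof <- dist_density_log10(dists[[k]], x_of_row)
    prof <- gaussian_smooth(prof, cfg$psf_sigma)
    paint(prof, cfg$lane_centers[sample_lanes[k]])
  }
  lad_prof <- rep(0, nr)
  for (r0 in ladder_rows)
    lad_prof <- lad_prof + exp(-(rows - r0)^2 / (2 * cfg$psf_sigma^2))
  paint(lad_prof, cfg$lane_centers[cfg$ladder_lane])

  mx <- max(signal)
  if (mx > 0) signal <- signal * (cfg$exposure / mx)
  bg <- cfg$background_base + cfg$background_gradient * (rows - 1)
  img_mat <- signal + matrix(bg, nr, ncl)
  if (cfg$noise_sigma > 0) {
    set.seed(cfg$seed)
    img_mat <- img_mat + matrix(
      stats::rnorm(nr * ncl, sd = cfg$noise_sigma * cfg$exposure), nr, ncl)
  }
  img_mat <- pmin(pmax(img_mat, 0), 1)

  # calibrated range the analysis pipeline will see: ladder rows extended by
  # half of each end gap, clipped to the image
  gaps <- diff(sort(ladder_rows))
  row_min <- max(1, min(ladder_rows) - gaps[1] / 2)
  row_max <- min(nr, max(ladder_rows) + gaps[length(gaps)] / 2)
  cal_bp <- sort(10^((cfg$a - c(row_min, row_max)) / cfg$b))

  lane_truth <- lapply(dists, function(d)
    true_stats(d, range_lo, range_hi, convention = "gel",
               cal_range = cal_bp))
  truth <- list(
    mean_bp = vapply(lane_truth, `[[`, 0, "mean_bp"),
    frac_in_range = vapply(lane_truth, `[[`, 0, "frac_in_range"),
    range_lo = range_lo, range_hi = range_hi,
    ladder_rows = ladder_rows,
    lane_centers = cfg$lane_centers,
    ladder_lane = cfg$ladder_lane,
    cal_bp_range = cal_bp,
    a = cfg$a, b = cfg$b, seed = cfg$seed)

  list(image = gel_image(img_mat, bit_depth = 16L,
                         source_path = "<simulated>"),
       truth = truth)
}
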
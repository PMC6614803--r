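# Internal helpers shared across modules: classed conditions, signal-processing
# primitives (local maxima with prominence, rolling-minimum baseline) and
# deterministic, atomically written text output.

gq_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gelquant_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

gq_validation_error  <- function(msg) gq_error(msg, "gq_validation_error")
gq_io_error          <- function(msg) gq_error(msg, "gq_io_error")
gq_calibration_error <- function(msg) gq_error(msg, "gq_calibration_error")
gq_config_error      <- function(msg) gq_error(msg, "gq_config_error")
gq_format_error      <- function(msg) gq_error(msg, "gq_format_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    gq_validation_error(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    gq_validation_error(sprintf("`%s` must be > 0", name))
  invisible(x)
}

#' Locate local maxima of a 1-D signal with topographic prominence
#'
#' A sample is a local maximum when it is strictly greater than its left
#' neighbour and at least as great as its right neighbour (plateaus resolve to
#' their leftmost sample, so ties are broken deterministically).  Prominence is
#' the drop from the peak to the highest of the two key saddles: on each side
#' the signal is scanned until a strictly higher sample (or the edge) is met
#' and the minimum over that stretch recorded.
#'
#' @param x numeric vector.
#' @return data.frame with columns `index`, `height`, `prominence`, ordered by
#'   index.
#' @keywords internal
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L)
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(idx))
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

# Per-lane baseline: centered rolling minimum (window 10% of rows) locates
# the support points -- rows where the profile itself attains the local
# minimum -- and the baseline is the linear interpolation of the profile
# between consecutive support points, capped by the profile.  Bridging
# between valleys keeps the baseline from climbing the flanks of smears wider
# than the window, while still tracking a (linear) background gradient
# through the valley levels on either side.
rolling_min_baseline <- function(x, window = max(3L, round(0.1 * length(x)))) {
  n <- length(x)
  window <- max(3L, as.integer(window))
  half <- window %/% 2L
  rmin <- vapply(seq_len(n), function(i)
    min(x[max(1L, i - half):min(n, i + half)]), numeric(1))
  eps <- 1e-12 * max(abs(x), 1)
  support <- which(x <= rmin + eps)
  support <- unique(c(1L, support, n))
  # at each support the baseline level is the local median, not the raw
  # minimum: under additive noise the window minimum sits ~2 sigma below the
  # true background and interpolating raw minima would leave a positive
  # pedestal over the whole lane
  mhalf <- max(2L, half %/% 4L)
  level <- vapply(support, function(i)
    stats::median(x[max(1L, i - mhalf):min(n, i + mhalf)]), numeric(1))
  stats::approx(support, level, xout = seq_len(n), rule = 2)$y
}

# Simple centered moving average with edge shrinkage.
running_mean <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- window %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Gaussian convolution along a vector, kernel truncated at 4 sigma,
# edge-renormalized so flat signals stay flat.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(padded, k, sides = 2)[(half + 1L):(half + n)]
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::filter(ones, k, sides = 2)[(half + 1L):(half + n)]
  as.numeric(num / den)
}

# Deterministic md5 of a configuration list: canonical JSON -> file -> md5.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# Atomic text output: `writer(path)` renders into a temp file in the target
# directory which is then renamed over the destination.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  invisible(path)
}

# Timestamp-free metadata header carried by every TSV output so a run can be
# reproduced exactly: tool version, hash of the effective configuration, seed.
metadata_header <- function(cfg, seed = NULL) {
  c(sprintf("# gelquant %s",
            as.character(utils::packageVersion("gelquant"))),
    sprintf("# config_hash=%s", config_hash(cfg)),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else format(seed)))
}

# TSV with metadata header, written atomically.
write_tsv_with_header <- function(df, path, cfg, seed = NULL) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(metadata_header(cfg, seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
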
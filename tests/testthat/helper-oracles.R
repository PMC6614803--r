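# Shared fixtures and independent oracles.  Oracles here deliberately avoid
# the code paths they check: brute-force interval scans, closed-form least
# squares, a continued-fraction t CDF, Monte-Carlo smear statistics.

std_ladder <- function() ladder_spec(c(1000, 700, 500, 400, 300, 200, 100))

# A small simulated gel: 1 ladder + n_sample lanes.
make_sim <- function(seed, medians, sigmas = 0.15, n_rows = 480,
                     noise_sigma = 0.02, ladder = std_ladder(), ...) {
  n_lanes <- length(medians) + 1L
  width <- 60L * n_lanes + 20L
  centers <- round(seq(40, width - 40, length.out = n_lanes))
  dists <- Map(function(m, s) fragment_distribution(m, s),
               medians, rep_len(sigmas, length(medians)))
  cfg <- gel_sim_config(shape = c(n_rows, width), lane_centers = centers,
                        noise_sigma = noise_sigma, seed = seed, ...)
  sim <- simulate_gel(dists, ladder, cfg)
  sim$cfg <- cfg
  sim$dists <- dists
  sim
}

# Closed-form simple-regression estimates of ct ~ log10(conc).
ols_oracle <- function(conc, ct) {
  x <- log10(conc)
  sxx <- sum((x - mean(x))^2)
  m <- sum((x - mean(x)) * (ct - mean(ct))) / sxx
  b <- mean(ct) - m * mean(x)
  fitted <- m * x + b
  r2 <- 1 - sum((ct - fitted)^2) / sum((ct - mean(ct))^2)
  list(m = m, b = b, r2 = r2)
}

# Student t CDF from scratch: regularized incomplete beta via Lentz's
# continued fraction (textbook construction, independent of stats::pt).
ref_betacf <- function(x, a, b) {
  # continued fraction for the incomplete beta (modified Lentz)
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < 1e-300) d <- 1e-300
  d <- 1 / d
  h <- d
  for (m in 1:300) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-300) d <- 1e-300
    c <- 1 + aa / c; if (abs(c) < 1e-300) c <- 1e-300
    d <- 1 / d
    h <- h * d * c
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-300) d <- 1e-300
    c <- 1 + aa / c; if (abs(c) < 1e-300) c <- 1e-300
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < 1e-15) break
  }
  h
}

ref_incbeta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  bt <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
              a * log(x) + b * log(1 - x))
  if (x < (a + 1) / (a + b + 2))
    bt * ref_betacf(x, a, b) / a
  else
    1 - bt * ref_betacf(1 - x, b, a) / b
}

ref_pt <- function(t, df) {
  x <- df / (df + t^2)
  p <- ref_incbeta(x, df / 2, 0.5) / 2
  if (t > 0) 1 - p else p
}

ref_t_pvalue <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * ref_pt(-abs(tt), na + nb - 2)
}

# O(n*m) all-pairs overlap oracle (>= 1 bp shared, half-open).
brute_overlap_hits <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         marks = "H3K4m3") {
  start <- sample.int(max_pos, n, replace = TRUE)
  df <- data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(5000, n, replace = TRUE),
    name = sprintf("p%d", seq_len(n)),
    score = sample.int(1000, n, replace = TRUE),
    strand = ".",
    fold_enrichment = round(runif(n, 0, 12), 3),
    neg_log10_p = round(runif(n, 0, 40), 3),
    neg_log10_q = round(runif(n, 0, 30), 3),
    mark = sample(marks, n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

# Monte-Carlo smear statistics under the gel (no-Jacobian) convention:
# with sizes S = 10^Z drawn from the mixture, mean = E[S^2]/E[S] and
# frac = E[S 1(lo<=S<=hi)]/E[S] (see vignette for the derivation).
mc_true_stats <- function(dist, lo, hi, n = 1e6, seed = 1) {
  set.seed(seed)
  cmp <- dist$components
  k <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
  s <- 10^rnorm(n, log10(cmp$median_bp[k]), cmp$sigma_log10[k])
  list(mean_bp = mean(s^2) / mean(s),
       frac_in_range = mean(s * (s >= lo & s <= hi)) / mean(s),
       draws = s)
}
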
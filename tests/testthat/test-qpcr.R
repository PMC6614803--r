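test_that("perfect 10-fold doubling series: efficiency 1, r2 = 1", {
  m <- -1 / log10(2)
  conc <- 10^(0:-4)
  ct <- m * log10(conc) + 30
  sc <- fit_standard_curve(conc, ct, "p1")
  expect_equal(sc$slope, m, tolerance = 1e-9)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-4)
  expect_equal(sc$r2, 1.0, tolerance = 1e-9)
  expect_length(sc$flags, 0)
})

test_that("degenerate and invalid series are flagged or refused", {
  sc <- fit_standard_curve(10^(0:-3), rep(25, 4))
  expect_equal(sc$slope, 0)
  expect_true("nonnegative_slope" %in% sc$flags)
  expect_error(fit_standard_curve(rep(1, 4), c(20, 21, 22, 23)),
               class = "gq_validation_error")
  expect_error(fit_standard_curve(10^(0:-1), c(20, 23)),
               class = "gq_validation_error")
})

test_that("noisy series match the closed-form OLS oracle; efficiency close", {
  m_true <- -1 / log10(2)
  eff_err <- numeric(100)
  for (seed in 1:100) {
    set.seed(seed)
    conc <- 10^(0:-4)
    ct <- m_true * log10(conc) + 28 + rnorm(5, sd = 0.1)
    sc <- fit_standard_curve(conc, ct)
    o <- ols_oracle(conc, ct)
    expect_equal(sc$slope, o$m, tolerance = 1e-12)
    expect_equal(sc$intercept, o$b, tolerance = 1e-12)
    expect_equal(sc$r2, o$r2, tolerance = 1e-12)
    eff_err[seed] <- abs(sc$efficiency - 1)
  }
  expect_lt(mean(eff_err), 0.03)
})

test_that("ct_to_quantity inverts the curve; replicates average first", {
  conc <- 10^(0:-3)
  sc <- fit_standard_curve(conc, -3.5 * log10(conc) + 30)
  expect_equal(ct_to_quantity(sc$intercept, sc), 1, tolerance = 1e-9)
  expect_equal(ct_to_quantity(sc$intercept + sc$slope, sc), 10,
               tolerance = 1e-9)
  # random (m, b, conc) round-trip
  for (seed in 1:50) {
    set.seed(seed)
    m <- runif(1, -4, -2.5); b <- runif(1, 25, 35)
    conc <- 10^seq(0, -3)
    curve <- fit_standard_curve(conc, m * log10(conc) + b)
    q <- runif(1, 1e-4, 10)
    expect_equal(ct_to_quantity(m * log10(q) + b, curve), q,
                 tolerance = 1e-9)
  }
  # mean-of-Ct, not mean-of-quantity
  curve <- fit_standard_curve(10^(0:-3), -3.3 * log10(10^(0:-3)) + 30)
  reps <- c(24, 26)
  expect_equal(ct_to_quantity(reps, curve), ct_to_quantity(25, curve))
  expect_error(ct_to_quantity(25, fit_standard_curve(10^(0:-3),
                                                     rep(25, 4))),
               class = "gq_validation_error")
})

test_that("fraction of input: identity, one decade, dilution rescaling", {
  conc <- 10^(0:-4)
  m <- -1 / log10(2)
  curve <- fit_standard_curve(conc, m * log10(conc) + 30)
  ip <- chip_measurement("s1", "t", "ab", ct_replicates = rep(25, 4))
  inp <- chip_measurement("s1", "t", "input", ct_replicates = rep(25, 4),
                          is_input = TRUE, input_dilution = 1)
  expect_equal(fraction_of_input(ip, inp, curve)$value, 1.0,
               tolerance = 1e-9)

  ip2 <- chip_measurement("s1", "t", "ab", rep(25 + abs(m), 4))
  expect_equal(fraction_of_input(ip2, inp, curve)$value, 0.1,
               tolerance = 1e-9)

  inp10 <- chip_measurement("s1", "t", "input", rep(25, 4), is_input = TRUE,
                            input_dilution = 10)
  expect_equal(fraction_of_input(ip, inp10, curve)$value, 0.1,
               tolerance = 1e-9)
  expect_error(fraction_of_input(ip, ip2, curve),
               class = "gq_validation_error")
})

test_that("plate-level Ct shift cancels in fraction of input (property)", {
  conc <- 10^(0:-4)
  curve <- fit_standard_curve(conc, -3.4 * log10(conc) + 31)
  for (seed in 1:20) {
    set.seed(seed)
    ct_ip <- runif(4, 24, 30); ct_in <- runif(4, 20, 26)
    shift <- runif(1, -3, 3)
    f0 <- fraction_of_input(
      chip_measurement("s", "t", "ab", ct_ip),
      chip_measurement("s", "t", "in", ct_in, is_input = TRUE), curve)$value
    f1 <- fraction_of_input(
      chip_measurement("s", "t", "ab", ct_ip + shift),
      chip_measurement("s", "t", "in", ct_in + shift, is_input = TRUE),
      curve)$value
    expect_equal(f1, f0, tolerance = 1e-9)
  }
})

test_that("simulated plate recovers known enrichments within 5% at sd 0.1", {
  m_true <- -1 / log10(2); b_true <- 30
  conc <- 10^seq(-3, 1)
  curve <- fit_standard_curve(conc, m_true * log10(conc) + b_true)
  enrich <- 10^seq(log10(0.001), log10(0.2), length.out = 8)
  set.seed(77)
  rel_err <- replicate(50, {
    e <- sample(enrich, 1)
    q_input <- 5; dil <- 10
    ct_in <- m_true * log10(q_input / dil) + b_true + rnorm(4, sd = 0.1)
    ct_ip <- m_true * log10(e * q_input) + b_true + rnorm(4, sd = 0.1)
    est <- fraction_of_input(
      chip_measurement("s", "t", "ab", ct_ip),
      chip_measurement("s", "t", "in", ct_in, is_input = TRUE,
                       input_dilution = dil), curve)$value
    abs(est - e) / e
  })
  expect_lt(mean(rel_err), 0.05)
})

test_that("significance marks: trivial cases and the mark mapping", {
  g <- c(1, 2, 3, 4)
  expect_equal(pairwise_significance(g, g)$p_value, 1)
  expect_equal(pairwise_significance(g, g)$mark, "none")

  set.seed(1)
  a <- rnorm(4, 0, 1e-6); b <- 1 + rnorm(4, 0, 1e-6)
  mk <- pairwise_significance(a, b)
  expect_lt(mk$p_value, 0.01)
  expect_equal(mk$mark, "large_circle")

  # constant equal groups -> degenerate p = 1; constant unequal -> p = 0
  expect_equal(pairwise_significance(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(pairwise_significance(c(2, 2), c(3, 3))$p_value, 0)
  expect_error(pairwise_significance(1, c(1, 2)),
               class = "gq_validation_error")
})

test_that("p-values agree with an independent t CDF within 1e-6", {
  set.seed(123)
  for (i in 1:1000) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 2))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    p <- pairwise_significance(a, b)$p_value
    expect_equal(p, ref_t_pvalue(a, b), tolerance = 1e-6)
  }
})

test_that("efficiency strictly decreases as |m| grows (property)", {
  ms <- -seq(2.5, 5, by = 0.1)
  effs <- 10^(-1 / ms) - 1
  expect_true(all(diff(effs) < 0))
  # and the package computes the same formula through the fit
  conc <- 10^(0:-3)
  e1 <- fit_standard_curve(conc, -3.0 * log10(conc) + 30)$efficiency
  e2 <- fit_standard_curve(conc, -3.8 * log10(conc) + 30)$efficiency
  expect_gt(e1, e2)
})

test_that("plate table I/O and quantify_plate wire together", {
  dir <- withr::local_tempdir()
  man <- make_fixtures(dir, seed = 4)
  std <- read_dilution_series(file.path(dir, "standards.csv"))
  plate <- read_plate_table(file.path(dir, "plate.csv"))
  foi <- quantify_plate(std, plate)
  expect_equal(nrow(foi), 4)
  expect_equal(foi$fraction_of_input, man$qpcr$true_enrichments,
               tolerance = 0.12)
})
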
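write_peak_lines <- function(lines) {
  f <- tempfile(fileext = ".broadPeak")
  writeLines(lines, f)
  f
}

test_that("well-formed broadPeak parses with fields mapped correctly", {
  f <- write_peak_lines(c(
    "chr1\t100\t900\tpeak1\t150\t.\t5.2\t20.1\t12.5",
    "chr1\t2000\t2600\tpeak2\t80\t.\t2.4\t6.0\t3.5",
    "chr2\t10\t60\tpeak3\t900\t.\t9.0\t50.0\t44.0"))
  pk <- read_broadpeak(f, mark = "H3K4m1")
  expect_equal(nrow(pk), 3)
  expect_equal(pk$start, c(100, 2000, 10))
  expect_equal(pk$fold_enrichment, c(5.2, 2.4, 9.0))
  expect_equal(pk$neg_log10_q, c(12.5, 3.5, 44.0))
  expect_equal(unique(pk$mark), "H3K4m1")
})

test_that("malformed lines are rejected with their line number", {
  f <- write_peak_lines(c("chr1\t100\t900\tp\t1\t.\t2\t3\t4",
                          "chr1\t500\t500\tp\t1\t.\t2\t3\t4"))
  err <- tryCatch(read_broadpeak(f), condition = identity)
  expect_s3_class(err, "gq_format_error")
  expect_match(conditionMessage(err), "line 2")

  short <- write_peak_lines("chr1\t1\t2\tp\t1\t.")
  expect_error(read_broadpeak(short), class = "gq_format_error")
})

test_that("1000 random peaks survive a write/read round-trip", {
  set.seed(8)
  pk <- random_peaks(1000)
  f <- tempfile(fileext = ".broadPeak")
  write_broadpeak(pk, f)
  back <- read_broadpeak(f, mark = "H3K4m3")
  for (col in c("chrom", "start", "end", "name", "fold_enrichment",
                "neg_log10_q"))
    expect_equal(back[[col]], pk[[col]], label = col)
})

test_that("published filter thresholds behave as printed, strictly", {
  mk <- function(mark, q, fe) {
    df <- random_peaks(1)
    df$mark <- mark; df$neg_log10_q <- q; df$fold_enrichment <- fe
    df
  }
  # broad-mark rule: q < 1e-3 AND fold > 2
  expect_equal(nrow(filter_peaks(mk("H3K4m1", 3.5, 2.5))), 1)
  expect_equal(nrow(filter_peaks(mk("H3K4m1", 3.0, 2.5))), 0)  # q = 1e-3 fails
  expect_equal(nrow(filter_peaks(mk("H3K4m1", 3.5, 2.0))), 0)  # fold = 2 fails
  # default rule: q < 1e-10 AND fold > 5
  expect_equal(nrow(filter_peaks(mk("H3K4m3", 9.9, 10))), 0)
  expect_equal(nrow(filter_peaks(mk("H3K4m3", 10.1, 5.1))), 1)
})

test_that("filtering matches a per-record oracle on 1e4 random peaks", {
  set.seed(21)
  pk <- random_peaks(10000, marks = c("H3K4m1", "H3K27m3", "H3K27Ac",
                                      "H3K4m3", "H3K9Ac", "CTCF"))
  out <- filter_peaks(pk)
  keep_oracle <- vapply(seq_len(nrow(pk)), function(i) {
    broad <- pk$mark[i] %in% c("H3K4m1", "H3K27m3", "H3K27Ac")
    if (broad) pk$neg_log10_q[i] > 3 && pk$fold_enrichment[i] > 2
    else pk$neg_log10_q[i] > 10 && pk$fold_enrichment[i] > 5
  }, logical(1))
  expect_equal(out$name, pk$name[keep_oracle])
  # idempotence
  expect_equal(filter_peaks(out), out)
})

test_that("rule matching errors: unmatched mark, duplicate rules", {
  pk <- random_peaks(5, marks = "H3K9Ac")
  rules <- list(filter_rule("H3K4m1", 1e-3, 2))
  expect_error(filter_peaks(pk, rules), class = "gq_config_error")
  dup <- list(filter_rule("H3K4m1", 1e-3, 2), filter_rule("H3K4m1", 1e-5, 3))
  expect_error(filter_peaks(pk, dup), class = "gq_config_error")
})

test_that("overlap: self-overlap is 100%, disjoint chromosomes 0%", {
  set.seed(3)
  pk <- random_peaks(200)
  ov <- overlap_fraction(pk, pk)
  expect_equal(ov$percent, 100)
  a <- random_peaks(50, chroms = "chr1")
  b <- random_peaks(50, chroms = "chr2")
  expect_equal(overlap_fraction(a, b)$percent, 0)
  e <- overlap_fraction(a[0, ], b)
  expect_true(is.na(e$percent) && "undefined" %in% e$flags)
})

test_that("half-open semantics: touching intervals do not overlap", {
  a <- random_peaks(1); a$chrom <- "chr1"; a$start <- 100; a$end <- 200
  b <- random_peaks(2); b$chrom <- "chr1"
  b$start <- c(200, 0); b$end <- c(300, 100)
  expect_equal(overlap_fraction(a, b)$count_overlapping, 0)
  b$end[2] <- 101
  expect_equal(overlap_fraction(a, b)$count_overlapping, 1)
})

test_that("sweep-line equals the all-pairs oracle on 20 random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- random_peaks(500, chroms = c("chr1", "chr2", "chrX"), max_pos = 2e5)
    b <- random_peaks(500, chroms = c("chr1", "chr2", "chrX"), max_pos = 2e5)
    ov <- overlap_fraction(a, b)
    hits <- brute_overlap_hits(a, b)
    expect_identical(ov$count_overlapping, sum(hits))
    expect_lte(ov$count_overlapping, ov$count_a)
    # merging B first never changes the count (merge happens internally;
    # emulate by unioning B with itself shifted into itself)
    ov2 <- overlap_fraction(a, rbind(b, b))
    expect_identical(ov2$count_overlapping, ov$count_overlapping)
  }
})

test_that("TSS window assignment: direct hits, boundaries, oracle", {
  pk <- random_peaks(1); pk$chrom <- "chr1"; pk$start <- 5000; pk$end <- 5200
  tss <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    start = 0, end = 0, strand = "+",
                    tss = c(5100, 5200 + 2000 - 1, 5200 + 2000))
  tss$start <- tss$tss; tss$end <- tss$tss + 1
  flags <- assign_tss_marks(pk, tss, window = 2000)
  expect_true(flags[["g1"]])            # peak covers the TSS
  expect_true(flags[["g2"]])            # window edge still inside the peak
  expect_false(flags[["g3"]])           # half-open: touching is not overlap

  # peak ending exactly at tss - window does not reach the window
  pk2 <- pk; pk2$start <- 100; pk2$end <- 1000
  tssb <- tss[1, ]; tssb$tss <- 3000    # window starts at 1000
  expect_false(assign_tss_marks(pk2, tssb, window = 2000)[[1]])
  pk2$end <- 1001
  expect_true(assign_tss_marks(pk2, tssb, window = 2000)[[1]])

  for (seed in 1:20) {
    set.seed(seed)
    peaks <- random_peaks(200, max_pos = 5e5)
    genes <- data.frame(gene_id = sprintf("g%d", 1:150),
                        chrom = sample(c("chr1", "chr2"), 150, TRUE),
                        strand = "+",
                        tss = sample.int(5e5, 150))
    genes$start <- genes$tss; genes$end <- genes$tss + 1
    got <- assign_tss_marks(peaks, genes, window = 2000)
    want <- vapply(seq_len(nrow(genes)), function(i) {
      any(peaks$chrom == genes$chrom[i] &
            peaks$start < genes$tss[i] + 2000 &
            peaks$end > max(0, genes$tss[i] - 2000))
    }, logical(1))
    expect_identical(unname(got), want)
  }
})

test_that("gene-body mode needs spans and unions them in", {
  pk <- random_peaks(1); pk$chrom <- "chr1"; pk$start <- 50000; pk$end <- 50100
  tss <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                    end = 60000, strand = "+", tss = 10000)
  expect_error(assign_tss_marks(pk, tss, include_gene_body = TRUE),
               class = "gq_config_error")
  spans <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 60000)
  expect_false(assign_tss_marks(pk, tss, window = 2000)[[1]])
  expect_true(assign_tss_marks(pk, tss, window = 2000,
                               include_gene_body = TRUE,
                               gene_spans = spans)[[1]])
})

test_that("expression strata: partition, two-point case, recovery", {
  expr <- data.frame(gene_id = c("g1", "g2"), fpkm = c(32, 0.5))
  st <- expression_strata(c(g1 = TRUE, g2 = FALSE), expr)
  expect_equal(st$with_mark$gene_id, "g1")
  expect_equal(st$summary$mean_fpkm[st$summary$stratum == "with_mark"], 32)
  expect_equal(st$summary$mean_fpkm[st$summary$stratum == "without_mark"],
               0.5)
  expect_equal(nrow(st$with_mark) + nrow(st$without_mark), nrow(expr))

  all_on <- expression_strata(c(g1 = TRUE, g2 = TRUE), expr)
  expect_equal(nrow(all_on$without_mark), 0)
  expect_error(expression_strata(c(g1 = TRUE), expr[0, ]),
               class = "gq_validation_error")

  # bimodal cohort: flagged genes ~ LN(32), unflagged ~ LN(0.5)
  set.seed(9)
  n <- 2000
  flagged <- seq_len(n) <= n / 2
  fpkm <- ifelse(flagged, 32 * exp(rnorm(n, 0, 0.5)),
                 0.5 * exp(rnorm(n, 0, 0.5)))
  cohort <- data.frame(gene_id = sprintf("g%d", 1:n), fpkm = fpkm)
  fl <- setNames(flagged, cohort$gene_id)
  st2 <- expression_strata(fl, cohort)
  mu_with <- st2$summary$mean_fpkm[st2$summary$stratum == "with_mark"]
  mu_without <- st2$summary$mean_fpkm[st2$summary$stratum == "without_mark"]
  expect_lt(abs(mu_with - 32 * exp(0.125)) / (32 * exp(0.125)), 0.1)
  expect_lt(abs(mu_without - 0.5 * exp(0.125)) / (0.5 * exp(0.125)), 0.1)
})
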
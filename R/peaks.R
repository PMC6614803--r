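# broadPeak filtering, interval-overlap concordance, TSS mark assignment and
# expression stratification.  All coordinates are BED-style: 0-based,
# half-open [start, end).

#' Read a MACS2 broadPeak file
#'
#' BED6+3 layout: chrom, start, end, name, score, strand, fold_enrichment
#' (column 7), -log10(p) (column 8), -log10(q) (column 9).  Malformed lines
#' (wrong coordinate order, non-numeric scores) raise a format error that
#' names the first offending line.
#'
#' @param path broadPeak file.
#' @param mark histone mark / factor label attached to every peak.
#' @return data.frame of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `fold_enrichment`, `neg_log10_p`,
#'   `neg_log10_q`, `mark`.
#' @export
read_broadpeak <- function(path, mark = NA_character_) {
  if (!file.exists(path)) gq_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(empty_peak_set(mark))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 9L))
    gq_format_error(sprintf(
      "broadPeak needs >= 9 tab-separated columns; line %d has %d",
      which(ncols < 9L)[1], min(ncols)))
  m <- do.call(rbind, lapply(parts, `[`, 1:9))
  df <- data.frame(
    chrom = m[, 1],
    start = suppressWarnings(as.numeric(m[, 2])),
    end = suppressWarnings(as.numeric(m[, 3])),
    name = m[, 4],
    score = suppressWarnings(as.numeric(m[, 5])),
    strand = m[, 6],
    fold_enrichment = suppressWarnings(as.numeric(m[, 7])),
    neg_log10_p = suppressWarnings(as.numeric(m[, 8])),
    neg_log10_q = suppressWarnings(as.numeric(m[, 9])),
    mark = mark,
    stringsAsFactors = FALSE)
  bad_num <- which(!is.finite(df$start) | !is.finite(df$end) |
                   !is.finite(df$fold_enrichment) | !is.finite(df$neg_log10_q))
  if (length(bad_num))
    gq_format_error(sprintf("non-numeric coordinate or score on line %d",
                            bad_num[1]))
  bad_coord <- which(df$start < 0 | df$end <= df$start)
  if (length(bad_coord))
    gq_format_error(sprintf(
      "invalid interval on line %d: start %g, end %g (need 0 <= start < end)",
      bad_coord[1], df$start[bad_coord[1]], df$end[bad_coord[1]]))
  class(df) <- c("peak_set", "data.frame")
  df
}

empty_peak_set <- function(mark = NA_character_) {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   name = character(), score = numeric(), strand = character(),
                   fold_enrichment = numeric(), neg_log10_p = numeric(),
                   neg_log10_q = numeric(), mark = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Write peaks in broadPeak layout
#'
#' @param peaks a `peak_set` data.frame.
#' @param path output file.
#' @export
write_broadpeak <- function(peaks, path) {
  atomic_write(path, function(tmp) {
    out <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                     "fold_enrichment", "neg_log10_p", "neg_log10_q")]
    utils::write.table(format(out, trim = TRUE, scientific = FALSE,
                              drop0trailing = TRUE),
                       tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}

#' Per-mark peak quality filter rule
#'
#' @param mark_set character vector of mark names the rule applies to, or
#'   `NULL` for a default rule catching all other marks.
#' @param q_max keep peaks with q-value strictly below this (0 < q_max < 1).
#' @param fold_min keep peaks with fold enrichment strictly above this (> 0).
#' @return object of class `filter_rule`.
#' @export
filter_rule <- function(mark_set, q_max, fold_min) {
  if (q_max <= 0 || q_max >= 1)
    gq_validation_error("`q_max` must be in (0, 1)")
  if (fold_min <= 0) gq_validation_error("`fold_min` must be > 0")
  structure(list(mark_set = mark_set, q_max = q_max, fold_min = fold_min),
            class = "filter_rule")
}

#' The published quality-filter rule set for histone-mark peaks
#'
#' Broad marks H3K4m1, H3K27m3 and H3K27Ac: keep peaks with q-value < 1e-3
#' and fold enrichment > 2.  All other marks: q-value < 1e-10 and fold
#' enrichment > 5.  Inequalities are strict.
#'
#' @return list of two [filter_rule]s (the second is the catch-all default).
#' @export
default_filter_rules <- function() {
  list(filter_rule(c("H3K4m1", "H3K27m3", "H3K27Ac"), 1e-3, 2),
       filter_rule(NULL, 1e-10, 5))
}

#' Filter peaks by per-mark q-value and fold-enrichment thresholds
#'
#' A peak is kept iff `q < q_max` (equivalently `neg_log10_q > -log10(q_max)`)
#' AND `fold_enrichment > fold_min`, both strict.  Each peak's mark must match
#' exactly one rule; a rule with `mark_set = NULL` acts as the default for
#' marks named by no other rule.  Input order is preserved.
#'
#' @param peaks a `peak_set`.
#' @param rules list of [filter_rule]; defaults to [default_filter_rules()].
#' @return the surviving `peak_set`.
#' @export
filter_peaks <- function(peaks, rules = default_filter_rules()) {
  if (inherits(rules, "filter_rule")) rules <- list(rules)
  named <- unlist(lapply(rules, `[[`, "mark_set"))
  if (anyDuplicated(named))
    gq_config_error("a mark is named by more than one filter rule")
  default_idx <- which(vapply(rules, function(r) is.null(r$mark_set), TRUE))
  if (length(default_idx) > 1L)
    gq_config_error("at most one default (mark_set = NULL) rule is allowed")
  if (!nrow(peaks)) return(peaks)

  rule_of <- function(mark) {
    for (i in seq_along(rules))
      if (!is.null(rules[[i]]$mark_set) && mark %in% rules[[i]]$mark_set)
        return(i)
    if (length(default_idx)) return(default_idx)
    gq_config_error(sprintf("no filter rule matches mark '%s'", mark))
  }
  idx <- vapply(peaks$mark, rule_of, 0L)
  q_max <- vapply(rules, `[[`, 0, "q_max")[idx]
  fold_min <- vapply(rules, `[[`, 0, "fold_min")[idx]
  keep <- peaks$neg_log10_q > -log10(q_max) & peaks$fold_enrichment > fold_min
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge intervals (already subset to one chromosome) into disjoint sorted
# runs; intervals are half-open so touching intervals ([0,5) and [5,9)) do
# NOT merge, which matters for >= 1 bp overlap semantics.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  n <- length(start)
  if (n <= 1L) return(list(start = start, end = end))
  ms <- numeric(n); me <- numeric(n)
  k <- 1L; ms[1] <- start[1]; me[1] <- end[1]
  for (i in 2:n) {
    if (start[i] < me[k]) {
      if (end[i] > me[k]) me[k] <- end[i]
    } else {
      k <- k + 1L; ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  list(start = ms[seq_len(k)], end = me[seq_len(k)])
}

# Which of the query intervals share >= 1 bp with any subject interval?
# Per chromosome: merge subjects, then a sorted sweep -- a query [s, e)
# overlaps iff the merged run starting before e has its end after s.
intervals_overlap_any <- function(q_chrom, q_start, q_end,
                                  s_chrom, s_start, s_end) {
  hit <- logical(length(q_start))
  if (!length(q_start) || !length(s_start)) return(hit)
  for (chr in unique(q_chrom)) {
    qi <- which(q_chrom == chr)
    si <- which(s_chrom == chr)
    if (!length(si)) next
    m <- merge_intervals(s_start[si], s_end[si])
    # merged runs are disjoint with increasing starts AND ends, so only the
    # last run starting strictly before q_end can overlap the query
    j <- findInterval(q_end[qi], m$start, left.open = TRUE)
    ok <- j >= 1L
    ok[ok] <- m$end[j[ok]] > q_start[qi][ok]
    hit[qi] <- ok
  }
  hit
}

#' Overlap concordance between two peak sets
#'
#' Counts the peaks of set A that share at least 1 bp with any peak of set B
#' (half-open intersection), via per-chromosome sorting, merging of B and a
#' sweep over A.  No reciprocal-fraction requirement is applied.
#'
#' @param peaks_a,peaks_b `peak_set` data.frames on the same assembly.
#' @return list with `count_a`, `count_overlapping`, `percent`
#'   (`100 * count_overlapping / count_a`; `NA` with an `"undefined"` flag
#'   when A is empty).
#' @export
overlap_fraction <- function(peaks_a, peaks_b) {
  count_a <- nrow(peaks_a)
  if (count_a == 0L)
    return(list(count_a = 0L, count_overlapping = 0L, percent = NA_real_,
                flags = "undefined"))
  hit <- intervals_overlap_any(peaks_a$chrom, peaks_a$start, peaks_a$end,
                               peaks_b$chrom, peaks_b$start, peaks_b$end)
  list(count_a = count_a, count_overlapping = sum(hit),
       percent = 100 * sum(hit) / count_a, flags = character())
}

#' Read TSS (or gene-span) records from a BED6 file
#'
#' For TSS usage the record's anchor is the strand-aware 5' end: `start` for
#' `+` and `end - 1` for `-`.
#'
#' @param path BED file with >= 4 columns: chrom, start, end, name and
#'   optionally score and strand.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) gq_io_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4L)
    gq_format_error("TSS BED needs >= 4 columns (chrom, start, end, name)")
  strand <- if (ncol(df) >= 6L) df[[6]] else rep("+", nrow(df))
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(gene_id = as.character(df[[4]]), chrom = df[[1]],
             start = df[[2]], end = df[[3]], strand = strand,
             tss = ifelse(strand == "+", df[[2]], df[[3]] - 1),
             stringsAsFactors = FALSE)
}

#' Flag genes whose TSS neighbourhood (or gene body) carries a peak
#'
#' A gene is flagged iff any peak intersects the strand-independent window
#' `[tss - window, tss + window)` (clipped at 0), or -- when
#' `include_gene_body = TRUE` -- the gene's own span from `gene_spans`.
#'
#' @param peaks a `peak_set` (typically already quality-filtered).
#' @param tss data.frame from [read_tss_bed()].
#' @param window half-width of the TSS window in bp (> 0).  The published
#'   analysis does not state its window; 2000 bp is this package's default
#'   and is recorded in output metadata.
#' @param include_gene_body also test the gene body.
#' @param gene_spans data.frame with `gene_id`, `chrom`, `start`, `end`;
#'   required when `include_gene_body = TRUE`.
#' @return named logical vector, one entry per row of `tss`.
#' @export
assign_tss_marks <- function(peaks, tss, window = 2000,
                             include_gene_body = FALSE, gene_spans = NULL) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  if (include_gene_body && is.null(gene_spans))
    gq_config_error("`gene_spans` is required when include_gene_body = TRUE")
  w_start <- pmax(0, tss$tss - window)
  w_end <- tss$tss + window
  flags <- intervals_overlap_any(tss$chrom, w_start, w_end,
                                 peaks$chrom, peaks$start, peaks$end)
  if (include_gene_body) {
    idx <- match(tss$gene_id, gene_spans$gene_id)
    has_span <- !is.na(idx)
    if (any(has_span)) {
      body <- intervals_overlap_any(
        gene_spans$chrom[idx[has_span]], gene_spans$start[idx[has_span]],
        gene_spans$end[idx[has_span]],
        peaks$chrom, peaks$start, peaks$end)
      flags[has_span] <- flags[has_span] | body
    }
  }
  stats::setNames(flags, tss$gene_id)
}

#' Partition gene expression by mark presence
#'
#' Splits genes into with-mark / without-mark strata (genes absent from
#' `flags` count as without-mark) and summarizes FPKM per stratum on the raw
#' and `log2(FPKM + 1)` scales.
#'
#' @param flags named logical vector from [assign_tss_marks()].
#' @param expression data.frame with columns `gene_id`, `fpkm` (>= 0).
#' @return object of class `expression_strata`: `with_mark` and
#'   `without_mark` data.frames, `summary` data.frame with per-stratum n,
#'   mean/median FPKM and mean/median log2(FPKM + 1).
#' @export
expression_strata <- function(flags, expression) {
  if (!is.data.frame(expression) ||
      !all(c("gene_id", "fpkm") %in% names(expression)))
    gq_validation_error("`expression` must have columns gene_id, fpkm")
  if (!nrow(expression))
    gq_validation_error("empty expression table")
  if (any(expression$fpkm < 0))
    gq_validation_error("FPKM values must be >= 0")
  marked <- names(flags)[flags]
  has <- expression$gene_id %in% marked
  strat <- function(df) {
    lg <- log2(df$fpkm + 1)
    data.frame(n = nrow(df),
               mean_fpkm = if (nrow(df)) mean(df$fpkm) else NA_real_,
               median_fpkm = if (nrow(df)) stats::median(df$fpkm) else NA_real_,
               mean_log2 = if (nrow(df)) mean(lg) else NA_real_,
               median_log2 = if (nrow(df)) stats::median(lg) else NA_real_)
  }
  with_mark <- expression[has, , drop = FALSE]
  without_mark <- expression[!has, , drop = FALSE]
  summ <- rbind(cbind(stratum = "with_mark", strat(with_mark)),
                cbind(stratum = "without_mark", strat(without_mark)))
  structure(list(with_mark = with_mark, without_mark = without_mark,
                 summary = summ),
            class = "expression_strata")
}
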
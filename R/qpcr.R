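# ChIP-qPCR quantification: standard curves, Ct -> quantity conversion,
# fraction of input, and circle-coded pairwise significance.
#
# A qPCR standard curve is an ordinary least-squares line
#   Ct = m * log10(concentration) + b,  m < 0,
# fitted to a dilution series of genomic DNA; amplification efficiency is
# E = 10^(-1/m) - 1 (E = 1 for perfect per-cycle doubling, m ~ -3.3219).

#' Fit a per-primer qPCR standard curve
#'
#' @param concentration template amounts (> 0, any consistent unit).
#' @param ct observed cycle-threshold values, same length.
#' @param primer_pair label.
#' @return object of class `standard_curve`: `slope` (m), `intercept` (b),
#'   `r2`, `efficiency`, `primer_pair`, `flags` (contains
#'   `"nonnegative_slope"` when m >= 0 and/or `"poor_fit"` when r2 < 0.98).
#' @export
fit_standard_curve <- function(concentration, ct, primer_pair = "primer") {
  concentration <- as.numeric(concentration)
  ct <- as.numeric(ct)
  if (length(concentration) != length(ct))
    gq_validation_error("`concentration` and `ct` must have the same length")
  if (length(ct) < 3L)
    gq_validation_error("a standard curve needs at least 3 dilution points")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    gq_validation_error("concentrations must be finite and > 0")
  if (any(!is.finite(ct)) || any(ct <= 0))
    gq_validation_error("Ct values must be finite and > 0")
  x <- log10(concentration)
  if (length(unique(x)) < 2L)
    gq_validation_error("at least 2 distinct concentrations required")

  fit <- stats::lm(ct ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  eff <- if (m != 0) 10^(-1 / m) - 1 else NA_real_
  flags <- character()
  if (m >= 0) flags <- c(flags, "nonnegative_slope")
  if (r2 < 0.98) flags <- c(flags, "poor_fit")
  structure(
    list(slope = m, intercept = b, r2 = r2, efficiency = eff,
         primer_pair = primer_pair, flags = flags),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: Ct = %.3f log10(conc) + %.3f, r2 = %.4f, E = %.3f%s\n",
    x$primer_pair, x$slope, x$intercept, x$r2, x$efficiency,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Convert Ct values to template quantity via a standard curve
#'
#' Replicate Ct vectors are averaged (arithmetic mean of Ct) before
#' conversion; the quantity is `10^((ct - b) / m)`.
#'
#' @param ct numeric vector of replicate Ct values (averaged) or a single Ct.
#' @param curve a `standard_curve` with negative slope.
#' @return scalar concentration in the standard curve's units.
#' @export
ct_to_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0)
    gq_validation_error(
      "standard curve slope is >= 0; refusing Ct -> quantity conversion")
  ct <- as.numeric(ct)
  if (!length(ct) || any(!is.finite(ct)))
    gq_validation_error("Ct values must be finite")
  10^((mean(ct) - curve$intercept) / curve$slope)
}

#' A ChIP (or input) qPCR measurement
#'
#' @param sample_id,target,antibody labels.
#' @param ct_replicates replicate Ct values (quadruplicates in the standard
#'   workflow, but any count >= 1 is accepted).
#' @param is_input whether this well measures un-precipitated input chromatin.
#' @param input_dilution dilution factor (>= 1) applied to the input before
#'   qPCR; used to rescale the input to undiluted equivalents.
#' @return object of class `chip_measurement`.
#' @export
chip_measurement <- function(sample_id, target, antibody = "",
                             ct_replicates, is_input = FALSE,
                             input_dilution = 1) {
  ct_replicates <- as.numeric(ct_replicates)
  if (!length(ct_replicates) || any(!is.finite(ct_replicates)))
    gq_validation_error("at least one finite Ct replicate required")
  if (input_dilution < 1)
    gq_validation_error("`input_dilution` must be >= 1")
  structure(
    list(sample_id = sample_id, target = target, antibody = antibody,
         ct_replicates = ct_replicates, is_input = isTRUE(is_input),
         input_dilution = input_dilution),
    class = "chip_measurement")
}

#' Fraction of input
#'
#' ChIP-enriched quantity divided by the input quantity rescaled to undiluted
#' equivalents: `q(ip) / (q(input) * input_dilution)`.  Both measurements are
#' converted with the same per-primer standard curve after averaging their
#' replicate Ct values.
#'
#' @param ip a `chip_measurement` (the ChIP well).
#' @param input_ref a `chip_measurement` with `is_input = TRUE`.
#' @param curve the primer pair's `standard_curve`.
#' @return object of class `fraction_of_input`: `value`, `sample_id`,
#'   `target`, `antibody`, `flags` (`"undefined"` when the input quantity is
#'   zero; `value` is then `NA`, no exception is thrown).
#' @export
fraction_of_input <- function(ip, input_ref, curve) {
  stopifnot(inherits(ip, "chip_measurement"),
            inherits(input_ref, "chip_measurement"))
  if (!input_ref$is_input)
    gq_validation_error("`input_ref` must be an input measurement")
  if (!identical(ip$target, input_ref$target))
    gq_validation_error(sprintf(
      "ip target '%s' and input target '%s' differ", ip$target,
      input_ref$target))
  q_ip <- ct_to_quantity(ip$ct_replicates, curve)
  q_in <- ct_to_quantity(input_ref$ct_replicates, curve) *
    input_ref$input_dilution
  flags <- character()
  value <- if (q_in <= 0) {
    flags <- "undefined"
    NA_real_
  } else q_ip / q_in
  structure(
    list(value = value, sample_id = ip$sample_id, target = ip$target,
         antibody = ip$antibody, flags = flags),
    class = "fraction_of_input")
}

#' Two-sample Student t test with circle-coded significance
#'
#' Classical pooled-variance two-tailed Student t test (Welch's unequal
#' variance form available via `welch = TRUE`).  The p-value is encoded the
#' way qPCR comparison graphs mark it: a large circle for p < 0.01, a small
#' circle for 0.01 <= p < 0.05, no mark otherwise.  When both groups have
#' zero variance and equal means the test is degenerate and p = 1; with zero
#' variance but different means p = 0.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @param welch use the Welch (unequal-variance) form.
#' @return object of class `significance_mark`: `p_value`, `mark` (one of
#'   `"none"`, `"small_circle"`, `"large_circle"`), `t`, `df`.
#' @export
pairwise_significance <- function(group_a, group_b, welch = FALSE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    gq_validation_error("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    gq_validation_error("group values must be finite")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    p <- if (delta == 0) 1 else 0
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- na + nb - 2
  } else if (welch) {
    se2 <- va / na + vb / nb
    tstat <- delta / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  mark <- if (p < 0.01) "large_circle" else if (p < 0.05) "small_circle"
          else "none"
  structure(list(p_value = p, mark = mark, t = tstat, df = df),
            class = "significance_mark")
}

#' Read a dilution-series table
#'
#' CSV/TSV with columns `primer_pair`, `concentration`, `ct` (separator
#' inferred from the extension).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_dilution_series <- function(path) {
  if (!file.exists(path)) gq_io_error(sprintf("file not found: %s", path))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("primer_pair", "concentration", "ct")
  if (!all(need %in% names(df)))
    gq_format_error(sprintf("dilution series must have columns %s",
                            paste(need, collapse = ", ")))
  df
}

#' Read a ChIP-qPCR plate table
#'
#' CSV/TSV with columns `sample_id`, `target`, `antibody`, `is_input`,
#' `input_dilution` and replicate columns `ct_1`, `ct_2`, ...
#'
#' @param path file path.
#' @return list of [chip_measurement].
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) gq_io_error(sprintf("file not found: %s", path))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "target", "antibody", "is_input", "input_dilution")
  if (!all(need %in% names(df)))
    gq_format_error(sprintf("plate table must have columns %s",
                            paste(need, collapse = ", ")))
  ct_cols <- grep("^ct_[0-9]+$", names(df), value = TRUE)
  if (!length(ct_cols))
    gq_format_error("plate table needs at least one ct_<k> column")
  lapply(seq_len(nrow(df)), function(i) {
    cts <- as.numeric(df[i, ct_cols])
    chip_measurement(df$sample_id[i], df$target[i], df$antibody[i],
                     cts[is.finite(cts)],
                     is_input = as.logical(df$is_input[i]),
                     input_dilution = df$input_dilution[i])
  })
}

#' Fraction-of-input table for a whole plate
#'
#' Fits one standard curve per primer pair from the dilution series, then for
#' every non-input measurement finds the input measurement with the same
#' `sample_id` and `target` and computes the fraction of input.
#'
#' @param standards data.frame from [read_dilution_series()].
#' @param plate list of [chip_measurement] from [read_plate_table()].
#' @return data.frame with columns `sample_id`, `target`, `antibody`,
#'   `fraction_of_input`, `flags`.
#' @export
quantify_plate <- function(standards, plate) {
  curves <- lapply(split(standards, standards$primer_pair), function(d)
    fit_standard_curve(d$concentration, d$ct, primer_pair = d$primer_pair[1]))
  is_inp <- vapply(plate, `[[`, TRUE, "is_input")
  inputs <- plate[is_inp]
  ips <- plate[!is_inp]
  input_key <- vapply(inputs, function(m)
    paste(m$sample_id, m$target, sep = "\r"), "")
  rows <- lapply(ips, function(m) {
    curve <- curves[[m$target]]
    if (is.null(curve))
      gq_config_error(sprintf("no standard curve for target '%s'", m$target))
    idx <- match(paste(m$sample_id, m$target, sep = "\r"), input_key)
    if (is.na(idx))
      gq_config_error(sprintf("no input measurement for sample '%s' target '%s'",
                              m$sample_id, m$target))
    foi <- fraction_of_input(m, inputs[[idx]], curve)
    data.frame(sample_id = m$sample_id, target = m$target,
               antibody = m$antibody, fraction_of_input = foi$value,
               flags = paste(foi$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
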
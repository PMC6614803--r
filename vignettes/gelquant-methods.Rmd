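---
title: "Methods: gel smear quantification, qPCR curves and peak concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gel smear quantification, qPCR curves and peak concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelquant)
```

# Scope and model

gelquant covers the analytical tail of a high-throughput chromatin-shearing
workflow: (1) quantifying sheared-DNA smears on photographs of ethidium-
bromide-stained agarose gels, (2) ChIP-qPCR standard-curve quantification
with fraction-of-input readout and circle-coded significance, (3) broadPeak
quality filtering, interval-overlap concordance and TSS-mark expression
stratification, and (4) a synthetic gel simulator that provides exact ground
truth for validating (1).

## Migration model

A fragment of size $s$ (bp) migrates a distance approximately linear in
$\log_{10} s$:

$$ d = a - b\,\log_{10}(s), \qquad b > 0 . $$

A single semi-log regime is assumed, which is adequate for the 100–1000 bp
range relevant to shearing QC; reptation corrections for larger fragments
are out of scope. The ladder lane carries $K \ge 3$ fragments of known size;
fitting $d$ against $\log_{10} s$ at the matched band rows calibrates the
whole gel. Two calibration models are offered: `semilog_linear` (ordinary
least squares, reporting $r^2$) and `monotone_interpolation` (piecewise
linear in $(\text{row}, \log_{10} s)$, extrapolation limited to half of each
end gap). The valid row range for both is the band span extended by half of
each end gap — beyond that the map is an extrapolation we refuse to trust.

## Ladder band matching

Candidate bands are local maxima of the ladder-lane profile ranked by
topographic prominence. The matcher selects, among all monotone assignments
of $K$ of the top $K+8$ candidates to the $K$ ladder sizes (largest size at
the smallest row), the one minimizing the residual sum of squares of the
semi-log line. This makes the assignment robust to spurious bright specks,
which are skipped whenever they break the semi-log trend. With $K \le 12$
the bounded exhaustive search over monotone assignments is exact and
deterministic. Selected rows are refined to sub-pixel positions by a
log-parabolic interpolation through the peak and its two neighbours, which
is exact for Gaussian band profiles; this is what lets a noiseless gel
reproduce its nominal sizes to within one pixel's bp quantum and $r^2 = 1$
to $10^{-6}$.

## Lane detection and profiles

Lanes are the `n` highest-prominence maxima of the smoothed lateral
projection (column sums), with two robustness refinements: greedy
non-maximum suppression with a minimum separation of half the expected lane
pitch (flat-topped lanes yield plateaus whose samples all carry full
prominence, so the raw rule can place two "lanes" in one physical lane), and
refinement of each center to the local background-subtracted intensity
centroid (the raw maximum of a smoothed flat top sits at the plateau edge,
biased by several pixels). Equal-prominence ties resolve to the leftmost
column; the output is deterministic. If fewer maxima than lanes are found,
centers fall back to equal spacing across the occupied span and the geometry
is flagged `low_confidence`.

A lane profile is the per-row sum over the lane window (center ± half
width). The baseline is a rolling-minimum construction with a window of 10%
of the rows: the rolling minimum locates *support rows* (rows that attain
their own window minimum), and the baseline linearly interpolates between
supports. Two details matter and were set by measurement against simulator
ground truth:

* **Support values are local medians, not raw minima.** Under additive noise
  the window minimum sits roughly $2\sigma$ below the true background;
  interpolating raw minima leaves a positive pedestal across the whole lane
  that biased the mean fragment size by up to ~6%.
* **Bridging, not tracking.** Intensity between supports is *not* used:
  inside a smear wider than the window the rolling minimum climbs the smear
  flanks, and subtracting it reshaped the curve (up to ~17% bias on the mean
  even without noise). Bridging between valleys leaves broad smears intact
  while still following a linear background gradient exactly (the chord
  between two points of a line is the line).

After subtraction, rows below $3\times$ the robust per-row noise scale
(MAD of first differences, scaled) are set to zero: they carry no resolvable
signal, and because re-indexing to a uniform bp grid gives low-row (large
fragment) pixels more grid points per pixel, a clamped-noise pedestal
otherwise drifts the mean toward the middle of the calibrated range.

## Re-indexing convention (no Jacobian)

The profile is re-indexed from rows to a uniform bp grid by evaluating the
calibration at each row and interpolating — *without* multiplying by
$|\mathrm{d}\,\text{row}/\mathrm{d}\,s|$. The signal is treated as a curve
re-indexed by size: a flat profile stays flat. This mirrors the original
tool's "resize to a linear scale" behaviour and is the convention every
ground-truth oracle in this package uses. Users wanting a true mass density
per bp can pass `jacobian = TRUE` (CLI `--jacobian`), which multiplies by
$b/(s \ln 10)$ under the semi-log model. Note the two conventions give
different mean sizes and in-range fractions; comparisons across instruments
or publications must fix the convention first.

Smoothing (the "best-fit curve") is nonparametric: locally weighted
quadratic regression (loess, degree 2) with a window of 5% of the grid
points, at least 5. A parametric Gaussian fit was rejected because real
shear smears are skewed. Smoothing happens *after* re-indexing; the original
tool's order is unstated. The curve is then peak-normalized to 1 (all-zero
lanes stay all-zero).

## Lane statistics

With density $c_i$ on the uniform grid $s_i$:

$$ \overline{s} = \frac{\sum_i c_i s_i}{\sum_i c_i}, \qquad
   f_{[lo,hi]} = \frac{\sum_{lo \le s_i \le hi} c_i}{\sum_i c_i} . $$

The default window is 200–600 bp (the usual shearing target) and is
configurable. The denominator is the calibrated region, not the whole lane
(the source material is ambiguous on this; the choice is recorded here and
in output metadata). The mean is computed over the full calibrated grid, not
just the window, because the two statistics are reported separately.
Normalization cancels in both, so they are invariant to exposure scaling.

# The simulator and what a green test establishes

Each sample lane is a mixture of log-normal components (mass weight, median
bp, $\sigma_{\log_{10}}$). Because migration distance is linear in
$\log_{10} s$, the mass distribution over $\log_{10} s$ *is* (up to $1/b$)
the physical per-row intensity, so the rendered lane at row $r$ is the
mixture density evaluated at $x(r) = (a - r)/b$, convolved with a Gaussian
point-spread along the migration axis. Staining is mass-proportional
(ethidium-bromide-like), not molar. The ladder renders as equal-amplitude
Gaussian bands at its semi-log rows. The camera model is a linear vertical
background gradient plus iid Gaussian noise (fraction of the peak signal
amplitude), clipped to $[0,1]$. Defaults (480×520 px, $a = 950$,
$b = 300$ px/decade, PSF $\sigma = 3$ px, background 0.05 + 5·10⁻⁵/row,
noise 2%, exposure 0.7, 13 lanes) were chosen once to look like a typical
gel-documentation photograph of a 13-lane mini-gel and are not tuned per
test.

Ground truth uses the same no-Jacobian convention as the analysis. For a
mixture with components $(w_k, \mu_k, \sigma_k)$ on the $\log_{10}$ scale,
the re-indexed curve at size $s$ is $g(\log_{10} s)$ with
$g(x) = \sum_k w_k \phi((x-\mu_k)/\sigma_k)/\sigma_k$, and every statistic
is a ratio of truncated moments
$\int_a^b 10^{kx}\phi(\cdot)\,\mathrm{d}x$, which have closed forms in the
normal CDF. `true_stats()` evaluates those closed forms (exact and stable in
the $\sigma \to 0$ band limit, where adaptive quadrature fails); the test
suite checks them against an independent trapezoid quadrature and a 10⁶-draw
Monte-Carlo estimator ($\overline{s} = E[S^2]/E[S]$ with $S = 10^Z$).

The simulator deliberately omits: lane smiling/curvature, Poisson shot
noise, saturation blooming, partial-digestion kinetics, and any physics of
the shearing instrument itself. A green recovery test therefore establishes
that the pipeline inverts *this* forward model within tolerance (5% on the
mean, 0.03 on the in-range fraction, across noise up to 5% and
$\sigma_{\log_{10}}$ 0.1–0.2) — not that it is unbiased on distorted or
saturated real photographs. Real-gel features that do survive the model:
ladder calibration, background gradients, broad overlapping smears,
quantization to 8 bits.

# qPCR quantification

Standard curves are ordinary least squares of $C_t$ on
$\log_{10}(\text{concentration})$ per primer pair; amplification efficiency
is $E = 10^{-1/m} - 1$ ($E = 1$ at the perfect-doubling slope
$m = -1/\log_{10} 2 \approx -3.32$). Fits with $m \ge 0$ or $r^2 < 0.98$
carry warning flags. Replicate $C_t$ values are averaged *before*
conversion (matching the original workflow's wording); quantity is
$10^{(C_t - b)/m}$. Fraction of input divides the ChIP quantity by the input
quantity rescaled to undiluted equivalents
($q_\text{input} \times \text{dilution}$); a zero input flags the result
undefined rather than erroring. A plate-wide $C_t$ shift cancels exactly.

Significance marks reproduce the circle encoding of the original graphing
tool: pooled-variance two-tailed Student $t$ (Welch behind a flag; the
original names only "Student's t-test"), large circle $p<0.01$, small circle
$0.01 \le p < 0.05$, none otherwise. Degenerate zero-variance groups are
defined explicitly ($p = 1$ on equal means, $p = 0$ otherwise) because
`t.test()` refuses them. No multiple-testing correction is applied, matching
the original readout.

A note on tolerances: with quadruplicate $C_t$s at $\sigma_{C_t} = 0.1$ and
doubling chemistry, one fraction-of-input measurement has a sampling sd of
about 4.9%, so "recovers enrichments within 5%" is asserted on the mean
relative error over many simulated measurements, not per measurement.

# Peak concordance

broadPeak records are 0-based half-open; column 7 is taken as fold
enrichment over input and column 9 as $-\log_{10} q$. Quality filtering
keeps a peak iff $q < q_\text{max}$ and fold $> f_\text{min}$, strict
inequalities exactly as printed: $q<10^{-3}$, fold $>2$ for H3K4m1, H3K27m3
and H3K27Ac; $q<10^{-10}$, fold $>5$ for all other marks. Overlap between
two peak sets counts a peak of A as concordant if it shares $\ge 1$ bp with
any peak of B (per-chromosome sort, merge of B, sweep over A; no
reciprocal-fraction requirement) — merged runs have increasing starts *and*
ends, so only the last run starting before a query's end can overlap it.
The test suite pins the sweep-line to an $O(nm)$ all-pairs oracle.

TSS assignment flags a gene when any peak intersects the strand-independent
window $[\text{TSS} - w, \text{TSS} + w)$, optionally unioned with the gene
body (as the published analysis does for H3K27Ac/H3K27m3). The window size
used in the original figures is unstated; the default here is $w = 2000$ bp,
configurable and recorded in output metadata rather than guessed silently.
Expression stratification partitions genes by flag and summarizes FPKM on
raw and $\log_2(\text{FPKM}+1)$ scales.

# Determinism and outputs

Every simulator call is seeded; identical configuration and seed give
bit-identical images and byte-identical TSVs. Output tables carry a
timestamp-free metadata header (package version, configuration hash, seed)
sufficient to reproduce them, and files are written atomically (temp file +
rename). The CLI returns 0 on success, 1 on validation/I-O failures and 2 on
usage errors.

# Known limitations

* No TIFF I/O (no decoder in the supported dependency set); PNG, JPEG and
  plain PGM are supported. PNG output is 8-bit; use PGM for 16-bit.
* Saturated pixels are flagged and counted but not inpainted; heavily
  saturated smears will bias toward flat tops.
* The semi-log migration law degrades above ~2 kb; calibration quality is
  reported ($r^2$) but not corrected.
* Band-counting/genotyping, 2-D gels, cross-gel registration and
  electropherogram file parsing of commercial fragment analyzers are
  non-goals. Instrument-dependent size offsets between agarose gels and
  capillary instruments (tens of bp) are real and are not modelled.
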
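---
title: "Methods: from whole-cell spectra to toxin fingerprints"
author: "toxprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from whole-cell spectra to toxin fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxprint)
```

## The problem

Intact-cell MALDI-TOF mass spectrometry (IC-MS) profiles whole, unfractionated
cells: a linear positive-mode spectrum between m/z 2,000 and 20,000 whose
peaks are mostly small proteins and peptides. When cultured fish liver cells
(RTL-W1) are exposed to a toxicant for 24 h, the abundances of a reproducible
panel of peaks shift, and the *pattern* of shifts — which peaks move, in which
direction, at which exposure level — is characteristic of the substance class.
`toxprint` implements the full computational chain that turns raw spectra of
exposed and control cultures into such differential fingerprints, together
with the viability dose–response (EC50) stage used to choose exposure levels.

The panel at the centre of the package is a set of 15 marker peaks labelled
A–O between m/z 4,562 and 15,292, with annotated directions of change and
paired-t significance marks for three model toxicants: copper sulfate (a metal
compound, reference exposure 9 mg/L), acridine (an NSO-heterocycle, 150 µM),
and β-naphthoflavone (BNF, a PAH, 50 µM). The panel ships as a plain-text
fixture (`load_marker_fixture()`) and doubles as the default ground truth of
the synthetic-data generator.

## The synthetic-data generator

No public raw spectra exist for this assay, so every stage is exercised
against a forward model with retrievable ground truth
(`make_default_truth()`, `simulate_experiment()`):

* **Peaks** are Gaussians whose width grows linearly in m/z
  (FWHM = 6 + 2.5·10⁻⁴·m Da, i.e. ≈7 Da at m/z 4,562 and ≈10 Da at 15,292).
  Linear-TOF resolving power degrades roughly linearly in mass, and the panel
  itself constrains the width from above: its closest pairs (A/B and C/D) are
  14 Da apart and must stay resolvable.
* **Abundances** are drawn once per truth (uniform 900–2,600 mV) and scaled
  per condition by fold changes whose signs reproduce every annotated arrow
  of the marker panel at the reference concentration; at other concentrations
  the log fold change scales proportionally with dose, giving the
  concentration-dependent profiles the differential and PCA stages expect.
  Arrow magnitudes are 2.5× for `**` cells and 2.0× for `*` cells (inverted
  for decreases).
* **Replicate structure.** Each simulated spectrum carries a per-spectrum
  lognormal spot factor (sdlog 0.3) and a small per-peak biological factor
  (sdlog 0.015). This composition — overall spot-to-spot ionization
  variability dominating peak-specific variation — is what makes the marker
  analysis coherent: the 15 per-peak paired t tests on one experiment are
  then strongly correlated, so testing them without multiplicity correction
  (as the marker table does) keeps the family-wise false-mark rate near the
  single-test level (≈0.9 of null experiments show no mark at all). If
  per-peak noise dominated instead, 15 uncorrected tests would false-mark in
  more than half of all experiments and the per-peak marking scheme would be
  indefensible.
* **Baseline and noise**: a decaying-exponential chemical-noise baseline
  (150 mV amplitude, 3,000 Da decay scale, 10 mV offset) plus additive
  Gaussian detector noise (15 mV), standing in for the shot-averaged
  acquisition of the real instrument.
* **Mass-axis drift**: each spectrum receives an affine perturbation in the
  √(m/z) domain (TOF flight time ∝ √(m/z)); the slope deviates from 1 by
  ~2·10⁻⁴ (clamped at 10⁻³), displacing peaks by up to ≈±15 Da at high mass.
  This is the drift family the internal calibration stage must invert.
* **Grid**: uniform 0.2 Da steps ("channel" = one grid sample). The
  processing widths quoted in channels (smoothing 50, baseline 100) then
  correspond to 10 and 20 Da. A coarser 1 Da grid was rejected because a
  50-channel smoothing window would then span 50 Da — wider than any
  physically plausible peak — and would erase the 14-Da marker pairs; the
  instrument's true digitizer rate is much finer than either choice.

Everything is seeded: equal seeds regenerate experiments bit for bit, each
spectrum records its emitted peak positions and heights, and per-spectrum
seeds are derived from (experiment seed, condition, replicate) so results do
not depend on simulation order.

What the generator does **not** emulate: isotope structure, adducts or matrix
clusters, detector saturation, cell-count dilution effects, or correlated
(non-white) noise. Passing recovery suites on these simulations therefore
demonstrates the correctness of the analysis chain under its stated
assumptions, not instrument-level performance on real spectra.

## Preprocessing

Processing order is fixed: smooth → estimate baseline → subtract → detect →
calibrate.

* **Smoothing** (`smooth_spectrum()`): centred moving average, default 50
  channels rounded up to odd; edges use shrinking windows so interior total
  ion current is preserved.
* **Baseline** (`estimate_baseline()`): a rolling minimum followed by a
  rolling mean of the same width (default 100 channels). The minimum filter
  cannot follow narrow maxima, so peaks are ignored; the mean re-centres the
  lower envelope. On a peak-free decaying-exponential baseline the estimate
  is within 2 % of the amplitude everywhere. Subtraction clips at zero and
  reports the number of clipped channels.
* **Noise** (`estimate_noise()`): 1.4826 × the median absolute deviation of
  the signal around its local median, evaluated on window-sized blocks
  (default 2,501 channels ≈ 500 Da) and interpolated between block centres.
  The MAD is insensitive to the sparse peaks riding on the noise.
* **Peak detection** (`detect_peaks()`): local maxima passing *both*
  thresholds — S/N ≥ 3 against the local noise and apex ≥ 200 mV — with
  plateau ties resolved to the lowest-mass channel, maxima closer than the
  local FWHM merged into the taller one, and the reported mass an
  intensity-weighted centroid over the apex ±3 channels. Thresholds are
  applied to the preprocessed signal. Raising either threshold can only
  shrink the peak list.
* **Internal calibration** (`select_calibration_peaks()`, `calibrate()`):
  following common practice, 10 peaks that occur in the majority of spectra
  and spread evenly over the mass range are chosen as references (greedy
  farthest-point over qualifying cluster medians). Selection clusters with a
  wide link tolerance (2 Da + 2,000 ppm) so that one species' drifted masses
  chain together, and discards *ambiguous* clusters to which a single
  spectrum contributes more than one peak — the 14-Da pairs eliminate
  themselves this way rather than yielding a biased reference. Each spectrum
  is then recalibrated by a least-squares affine fit in √(m/z) mapping
  observed to reference masses (matching window 2 Da + 2,000 ppm, wide
  enough for the whole admissible drift family); the identity map is kept
  whenever the fit would not reduce the RMS residual, so calibration never
  makes references worse and is idempotent. Residual mass error after
  calibration is ≈0.1 Da at m/z 17,000 under the default drift.

## Alignment and the consensus table

`match_peaks()` pools all detected masses and single-linkage-chains them with
a link threshold of max(2 Da, 500 ppm·m); each cluster becomes a consensus row
(median mass, letter label in mass order). The 500 ppm tolerance sits well
above the post-calibration residual (<1 Da) and well below the closest marker
pair spacing (14 Da). A sample that contributes no peak to a row is recorded
as 0 mV — the *absence convention* that keeps paired statistics defined when
a peak disappears under treatment; `summarize_conditions()` then reports
mean, SD and n per condition.

## Differential statistics

For each peak and toxin, `build_marker_table()` compares the reference
concentration with the toxin series' own control, pairing by replicate
(independent experiment) index:

1. one pass of Grubbs' test (α = 0.05, two-sided, at most one exclusion per
   arm; an excluded value removes its pair);
2. a classical paired two-sample t test on the surviving pairs (two-sided);
3. the direction of deviation (sign of the mean paired difference) and a
   mark: `*` for p < 0.05, `**` for p < 0.01.

Fewer than three surviving pairs makes a peak *untestable* — it is flagged,
never silently dropped. **No multiple-testing correction is applied across
the 15 peaks**: marks are per-peak paired-t results, and the generator's
replicate structure (above) is what keeps that scheme's family-wise behaviour
acceptable. `relative_change()` expresses treated means as ratios to the
control mean (peaks with a zero control mean are excluded with a report), and
`count_significant()` / `shared_and_specific()` reproduce the panel's
bookkeeping: 8 marked peaks for copper sulfate, 7 for acridine, 9 for BNF,
the set {C, K, L} shared by all three, and {G, I, J, N, O} specific to copper
sulfate.

## Fingerprints

`build_change_matrix()` arranges relative changes as peaks × treatments with
one pooled control column (≡1 on the ratio scale), and `pca_fingerprint()`
decomposes the log-transformed (fold changes are multiplicative; the
transform is a flag), column-centred matrix. Treatments are the *variables*,
so the loadings give the variables-factor-map view in which each treatment is
an arrow in the (PC1, PC2) plane; component signs follow a deterministic
convention (largest-magnitude loading positive) and no randomized solver is
involved. `toxin_separation()` makes the qualitative claim — different toxins
occupy different sectors — testable: it checks that every pair of toxins'
loading vectors can be separated by a line through the origin. Under the
default truth this holds in essentially every seeded experiment.
`fingerprint_distance()` (cosine dissimilarity of log-ratio profiles, 0 for
proportional, 2 for antipodal) supports simple profile matching.

Variable standardization before PCA is exposed as the `scale.` flag (default
off); with unit-variance scaling the treatment arrows answer "which peaks
move together" rather than "which treatments move peaks most".

## Dose–response stage

`normalize_viability()` maps raw plate signals to percent of control using
blank wells as 0 % and untreated controls as 100 %; the mapping is invariant
to adding a constant to all signals. `fit_4pl()` fits

response = bottom + (top − bottom) / (1 + (dose/EC50)^hill)

by least squares with EC50 parameterized on the log scale (data-driven
starting values, a small multistart grid on failure; unconstrained plateaus by
default). The 95 % CI is asymptotic on log(EC50) and exponentiated, giving
the conventional asymmetric interval; multiplying doses by a constant scales
EC50 and its CI exactly. Controls anchor the normalization and are not
log-dose curve points. Coverage of the true EC50 is ~95 % over seeded
5 %-noise simulations.

`detect_response_outliers()` emulates automatic outlier removal:
a robust preliminary fit (iteratively reweighted soft-L1), residual scale by
MAD, per-point t-tail probabilities and a Benjamini–Hochberg call at
Q = 1 %; flagged points are removed and the curve refit unless more than
30 % of points are implicated (then flags are reported but the refit is
declined). With fewer than six points the procedure declines to flag at all.
The reference implementation of this idea in commercial software is
proprietary; this is an open emulation and labelled as such.

`anova_dunnett()` runs the one-way ANOVA and Dunnett many-to-one comparisons
against the control: t statistics on the pooled error variance, adjusted
p-values from the maximum-modulus multivariate-t distribution with the exact
(possibly unbalanced) Dunnett correlation structure, integrated by seeded
randomized quasi-Monte-Carlo (mvtnorm, ≤10⁵ points, absolute tolerance
10⁻⁴). Adjusted p-values agree with `multcomp::glht` to ~10⁻⁴ and are never
smaller than the unadjusted pooled-t p-value.

## Numerical and design choices

* Window widths in channels are rounded **up** to odd so filters are centred.
* Peak-list/consensus tolerances: max(2 Da, 500 ppm); calibration matching:
  2 Da + 2,000 ppm (must admit the full drift family).
* Grubbs is applied to raw abundances; on lognormal replicate noise the
  skew inflates the per-test paired-t rate slightly (~0.055), which bounds
  the achievable family-wise null cleanliness at ~0.92.
* Degenerate inputs fail loudly: non-monotone mass axes, fewer than two
  matched calibration references, constant dose-responses, zero-variance
  ANOVA, zero-variance PCA matrices. Degenerate *settings* (thresholds no
  peak can pass) complete with warnings and empty tables so pipelines can be
  probed safely.
* The pipeline (`run_pipeline()`) writes every stage artifact plus a
  manifest (config, seed, config hash, package version); a rerun with the
  same config byte-reproduces the marker table.

## Problem sizes used by the test-suite

The packaged suites run on deliberately modest sizes chosen as the smallest
that make the statistical claims sharp: 36–72 simulated spectra per
end-to-end experiment (6 replicates, reference or full concentration grids),
50 spectra for detection recall/precision, 10 seeded experiments for PCA
separability, 10,000 null trials for t-test and Grubbs calibration, 500
simulations for EC50 CI coverage, and 20 repeats for consensus row-count
recovery. `scripts/acceptance.R` recomputes the same quantities from scratch
at these sizes.

## Known limitations

* The generator's peaks are pure Gaussians on a smooth baseline; real IC-MS
  spectra contain unmodelled adducts, matrix clusters and heteroscedastic
  noise, so recovery rates here are upper bounds.
* Published EC50 values for the three toxicants cannot be reproduced exactly
  — the underlying plate data are not public — so the dose–response stage is
  validated by synthetic recovery and calibration instead.
* The printed PCA variance split of the original peak data (59 %/19 %)
  depends on the authors' raw abundances and is likewise not reproducible
  from the fixture alone; the package tests the structural claims
  (orthonormal loadings, variance accounting, toxin separability).
* mzML support is read-only and limited to profile spectra.
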
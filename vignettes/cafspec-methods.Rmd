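---
title: "Methods: simulation, preprocessing and PLS-DA classification of single-cell Raman maps"
author: "cafspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and PLS-DA classification of single-cell Raman maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafspec)
```

# The problem

Cancer-associated fibroblasts (CAFs) in pancreatic ductal adenocarcinoma come
in at least two functionally distinct subtypes — inflammatory iCAFs and
myofibroblastic myCAFs — that respond differently to therapy. Both can be
induced in culture from human pancreatic stellate cells (HPaSC). Label-free
Raman microspectroscopy can distinguish the three cell states from their
vibrational fingerprints alone: a confocal Raman map of a fixed cell yields
on the order of a hundred spectra per cell, each a vector of scattered-light
intensities over Raman shifts of roughly 300–5,000 cm⁻¹, and supervised
chemometrics (PLS-DA) separates the subtypes from those spectra.

`cafspec` implements that analysis as a reusable, tested pipeline:

1. a **synthetic-data generator** that emulates the statistical structure of
   such three-class Raman map experiments,
2. **spectral preprocessing** (iterative polynomial baseline removal,
   Savitzky–Golay smoothing, internal-standard normalization),
3. **PLS-DA** fitted by NIPALS, with **VIP** band selection,
4. **evaluation**: train/test splits, confusion matrices, one-vs-rest
   ROC/AUC, k-fold cross-validation, and per-band two-sample t statistics.

The raw spectra behind the published three-class study are not deposited, so
the generator is first-class, tested code rather than a fixture: every
downstream stage is validated against data whose ground truth is known by
construction.

# The generative model

A dataset is a set of cells per class (default 8 HPaSC, 10 iCAF, 12 myCAF,
the published acquisition design), each imaged at `pixels_per_cell = 100`
map pixels on an approximately square 1-µm grid — the minimum map size per
cell in the emulated experiment. One pixel yields one spectrum on the
default grid of 300–5,000 cm⁻¹ at 1 cm⁻¹ spacing (4,701 channels). The
instrument's true sampling density is unknown; the integer grid is a
convenience that makes band lookup exact and is configurable.

Each class is a `class_profile`: a list of Gaussian peaks (`peak_spec`) with
centers at the study's band assignments (481, 680, 717, 776, 830, 992,
1004, 1175, 1180, 1300, 1370, 1423, 1506, 1638, 1690, 1700 cm⁻¹ in the
fingerprint; 2811, 2896, 2910, 2950 cm⁻¹ CH-stretch; 3400 cm⁻¹ OH), plus
the paraformaldehyde (PFA) fixative band at 1040 cm⁻¹ that serves as the
internal intensity standard. No biological peak is allowed inside the
Raman-silent region (1,800–2,800 cm⁻¹); the constructor enforces this.
Line widths default to 12 cm⁻¹ (fingerprint) and 40 cm⁻¹ (CH stretch) FWHM,
plausible for a 600-groove grating; the study reports no line widths, so
both are configuration-exposed.

For pixel *j* of cell *c*, the spectrum is

$$ y_{cj}(\nu) = \sum_k a_k\, m_{ck}\, \mu_{cjk}\, g_k(\nu)
   \;+\; A^{\mathrm{PFA}}_{c} g_{1040}(\nu) \;+\; b_{cj}(\nu)
   \;+\; \varepsilon_{cj}(\nu), $$

where $g_k$ is the unit-height line shape of peak $k$, $a_k$ its raw
amplitude, $m_{ck}$ a cell-level and $\mu_{cjk}$ a pixel-level log-normal
multiplier (both mean 1), $b_{cj}$ a random order-3 polynomial
autofluorescence baseline (coefficients zero-mean Gaussian, SD 20 counts,
plus a constant 100-count offset, i.e. baseline excursions around 20 % of a
typical peak), and $\varepsilon$ additive white noise (SD 1.5 counts).
The PFA amplitude is drawn per cell (log-normal, mean 100, SD 5 counts).

**Two levels of biological variability.** The cell-level multipliers model
cell-to-cell differences in composition; the pixel-level multipliers model
intracellular heterogeneity — spectra from different subcellular positions
of one cell are genuinely different (nucleus, cytoplasm, lipid droplets).
Real maps show both, and the split matters: the sampling error of a class
mean is governed almost entirely by the number of *cells* when all
variability sits at the cell level, and shrinks toward the number of
*pixels* as variance moves within cells. The experiment behind the emulated
study does not report the split; we place 40 % of the CH-band amplitude
variance between cells and 60 % within cells, and expose both SDs per peak.
iCAF's documented extra heterogeneity in the 700–800 and 1,200–1,400 cm⁻¹
windows is encoded as a larger between-cell SD (0.25 vs 0.08) on the 717,
776, 1300 and 1370 cm⁻¹ peaks.

**Calibration of the 2,896 cm⁻¹ band.** Amplitudes are stated in
post-normalization units and converted to raw counts by the expected PFA
band mean, so that dividing by the measured PFA band during preprocessing
recovers them. The CH-stretch region is calibrated analytically so the
expected normalized band mean at 2,896 ± 2 cm⁻¹ equals the published class
statistics 4.082 (HPaSC), 5.042 (iCAF) and 3.659 (myCAF): the 2,896
amplitude is solved from the class target after subtracting the closed-form
shoulder contributions of the neighbouring broad peaks (mostly the
2,910 cm⁻¹ band, whose Gaussian tail contributes ≈ 71 % of its height at
2,896 cm⁻¹). The per-class amplitude-spread parameters are sized so the
total per-spectrum SD matches the published percent SDs (16.35 %, 11.41 %,
12.96 %). There is no iterative tuning loop; the calibration is closed-form
and then verified empirically by the test suite.

**What the generator does not model:** optics (laser power, NA, exposure),
cosmic rays, detector etaloning, wavenumber miscalibration, and spatial
structure within a cell (pixels of one cell are exchangeable). Passing
tests therefore demonstrate correctness of the analysis pipeline under a
realistic hierarchical noise structure — not instrument-level realism.

# Preprocessing

The chain is baseline removal → Savitzky–Golay smoothing → internal-standard
normalization, applied per spectrum. The order is fixed; normalization must
come last for the reported normalized band statistics to be well defined.

**Baseline.** An iterative modified polynomial fit (order 5, up to 100
iterations, relative tolerance 1e-4): fit by least squares, clip the working
spectrum down to the fit, refit. The specific scheme used by the original
instrument software is not documented; the iterated-clipping family is the
standard choice for Raman autofluorescence, and all its parameters are
exposed in `preprocess_config()`.

One detail matters quantitatively. The *fully* clipped iteration
(`work = min(work, fit)`) keeps lowering the polynomial as long as any noise
excursion lies above it, so on noisy spectra it settles toward the lower
envelope of the noise, roughly one noise SD below the true background. The
corrected intensities are then biased high by a constant, and because the
normalization divides by a *weak* band (the PFA standard) while the bands of
interest are strong, the constant inflates the denominator proportionally
more than the numerator: with our defaults the normalized 2,896 cm⁻¹ band
reads about 1 % low per noise SD. `cafspec` therefore replaces working
points lying more than `clip_sigma` estimated noise SDs above the fit by the
fit itself — peak points become neutral, points inside the noise band are
left untouched. The per-spectrum noise SD is estimated robustly as the MAD
of second differences divided by √6, which is exactly zero on noise-free
input, so the default (`clip_sigma = 0.25`) coincides with the classic rule
on clean spectra; on noisy spectra it removes the envelope settling, and
measurements across a fourfold range of noise levels show the residual band
bias is small (≈ +0.5 %) and nearly independent of the noise level. Setting
`clip_sigma = 0` restores the classic rule. An alternative —
pre-smoothing the estimator's working copy (`baseline_presmooth`) — is also
implemented but off by default: Savitzky–Golay undershoot beside sharp
peaks drags the fit low in peak-dense regions.

**Smoothing.** Savitzky–Golay with window 11, order 3 (both exposed),
delegated to `signal::sgolayfilt`; terminal windows are handled by
evaluating the fitted end-window polynomials, so any polynomial of degree
≤ 3 passes through the filter exactly. The batched path multiplies by an
equivalent sparse operator and is tested to agree with the per-spectrum
filter to machine precision.

**Normalization.** Each spectrum is divided by its mean intensity over the
closed band 1,040 ± 2 cm⁻¹ (the PFA fixative signal), making the band mean
exactly 1. A band mean rather than a single channel is used for robustness
to grid offset; `norm_half_width = 0` selects single-channel normalization.
Whether the original analysis normalized by one channel or a small band is
unstated. Non-positive band means raise an error naming the offending
spectra; negative post-baseline intensities elsewhere are retained, since
clipping them would bias band statistics.

# PLS-DA and VIP

Class labels are one-hot encoded in the declared class order. NIPALS PLS2
regresses the indicator matrix on mean-centered spectra, two latent
components by default (the published choice). Bands are **not** scaled to
unit variance: after internal-standard normalization all bands share a
physical intensity scale, and autoscaling would inflate pure-noise channels
(`scale = TRUE` is available). NIPALS starts each component from the first
response column — deterministic, so fits are bit-reproducible without a
random seed — iterates weight/score/loading updates to a 1e-10 score
tolerance (cap 500), fixes each weight column's sign so its
largest-magnitude entry is positive, and deflates both blocks. Regression
coefficients $B = W (P^{\mathsf T} W)^{-1} Q^{\mathsf T}$ give direct
prediction $\hat Y = (X - \bar x) B + \bar y$; the class decision is the
row-wise argmax with ties broken toward the earliest class in the class
order (the original decision rule is unstated; argmax on the continuous
response is the convention).

Variable importance in projection follows Wold's multi-response form,

$$ \mathrm{VIP}_j \;=\; \sqrt{\,p \,\frac{\sum_a SSY_a\,
   (w_{ja}/\lVert w_a\rVert)^2}{\sum_a SSY_a}\,}, \qquad
   SSY_a = \lVert t_a\rVert^2 \textstyle\sum_k q_{ka}^2, $$

summing the explained response sum of squares over all indicator columns;
with one response it reduces to the classic formula. Squared VIPs average
to 1 across bands, so the conventional threshold 1.0 marks bands
contributing more than an average band; selection is strict (`VIP > t`),
returned in descending VIP order. The model is fitted on the entire stored
spectrum, silent region included, matching the published analysis; cropping
(`crop_range()`) is available as an explicit preprocessing step.

The NIPALS implementation is checked against an independent reference PLS2
implementation (`mixOmics::pls`, regression mode, unscaled) to 1e-6 on
random problems, against ordinary least squares at the full component
count, and for score orthogonality and the $\sum_j \mathrm{VIP}_j^2 = p$
identity on every fit.

# Evaluation

**Splits.** The default is a stratified 70/30 split at the *spectrum*
level, mirroring the published protocol. Because neighbouring pixels of one
cell are correlated, spectrum-level splitting lets the same cell appear on
both sides and yields an optimistic (upper-bound) accuracy — the original
study says as much. `mode = "cell"` assigns whole cells to one side and is
the honest generalization estimate; we recommend it for any real use. The
same two modes govern `cross_validate()` (default 5 folds), which never
places one cell's spectra in two folds in cell mode.

**Metrics.** Confusion matrices store rows = truth, columns = predicted.
Precision, recall and F1 are per class, accuracy is the trace over the
total; a class never predicted gets precision 0 and an explicit flag rather
than NaN. One-vs-rest ROC curves use the continuous PLS responses, with
tie-grouped trapezoidal AUC — algebraically the tie-adjusted Mann–Whitney
concordance probability, and tested against exhaustive pair counting. The
macro AUC is the unweighted mean over classes present in the truth; classes
absent from the truth get a missing AUC, never 0. `band_statistics()`
computes per-class band means with pairwise independent two-sample t-tests,
equal-variance Student's by default (Welch by flag), two-sided,
uncorrected; pairs where both groups have zero variance are flagged
degenerate rather than given p = 0. `reconstruct_test_counts()` inverts a
published precision/recall/correct-count table into implied per-class test
totals — the worked consistency check on the published classification table
lives in the test suite.

**Verification scales.** The acceptance-style checks run the full published
design (30 cells × 100 pixels, 4,701 channels) over 20 seeds for the
band-calibration and VIP-recovery rates, and single seeds for the
classification checks; unit tests use reduced grids (e.g. 300–3,000 cm⁻¹)
and 2–5 cells per class. These sizes are the package's choices for a
desk-scale verification study.

**The 2-standard-error check.** The generator's calibration is declared
successful when each class mean of the normalized 2,896 cm⁻¹ band falls
within two standard errors of the published class statistics, where the
standard error is taken from the *published* dispersion:
$SE_k = s_k/\sqrt{n_k}$ with $s_k$ the printed class SD (0.667, 0.575,
0.474) and $n_k$ the number of cells (8, 10, 12) — cells, not pixels, being
the independent sampling units of the hierarchical design. Estimating the
SE from each simulated run instead would turn the check into a three-way
t-statistic on 7–11 degrees of freedom, which exceeds 2 too often for the
check to be passable even by a perfectly calibrated generator; anchoring
the scale to the published statistics makes the check a fixed, honest
yardstick. With the default variance split the check passes in ≥ 90 % of
seeded runs, as the test suite verifies.

# Numerical choices and degenerate inputs

* Wavenumber windows are closed intervals everywhere they appear.
* Baseline fitting uses an orthonormalized polynomial basis (QR of scaled
  monomials) for conditioning at order 5 over thousands of channels.
* NIPALS convergence is measured on the score vector (relative 1e-10);
  sign fixing makes fits platform-reproducible.
* `fit_plsda` rejects `ncomp > min(n-1, p)`, zero-variance X, and
  non-finite input; `compute_vip` rejects models with no explained
  response variance.
* Splits and CV derive all randomness from an explicit seed and restore
  the caller's RNG state; the pipeline fans a single global seed into
  per-stage substreams so stages can be re-run independently.
* Simulated datasets are bit-identical for identical configurations.

# Known limitations

* The generator's class contrasts are directional (who is highest at which
  band) plus one calibrated band; absolute fingerprint amplitudes are
  plausible inventions, so downstream numbers other than the 2,896 cm⁻¹
  statistics should be read as properties of the pipeline, not predictions
  of any instrument.
* The cell/pixel variance split (40/60) is an assumption; only the total
  dispersion is anchored to published values.
* Spectrum-mode accuracy on simulated maps, like the published figure it
  mirrors, is an upper bound; cell-mode numbers are systematically lower
  and more honest.
* The modified-polynomial baseline has a small residual band-ratio bias
  (≈ +0.5 % at the defaults) that depends on peak density; applications
  that need better than ~1 % absolute band accuracy should calibrate
  against spectra of known composition.
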
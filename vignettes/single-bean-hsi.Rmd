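---
title: "Single-bean SWIR hyperspectral chemometrics: models, choices and limits"
author: "seedHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-bean SWIR hyperspectral chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A push-broom SWIR imager records, line by line, a hypercube of detector
counts `I(line, sample, band)` over 980–2500 nm. Counts depend on
illumination, detector gain and integration time, so they are converted to
reflectance against a white (PTFE) and a dark (shutter-closed) reference:

$$R = \frac{I - D_s}{W - D_w}\cdot\frac{t_w}{t_s}$$

The exposure ratio matters because the white reference saturates at the
exposure that is optimal for dark seeds; acquiring it faster and rescaling
restores a common radiometric scale. Absorbance $A=\log_{10}(1/R)$ then
linearises, to first order, the relationship between band intensity and
absorber concentration (Beer–Lambert behaviour in diffuse reflectance is
only approximate — scatter corrections below absorb much of the
deviation). Elements where $W-D_w\le 0$ or $R\le 0$ carry no information
and are masked as `NA` rather than clipped; masks propagate through every
downstream mean. Reflectance above a configurable cap (default 2.0) is
flagged but kept, since the calibration equation does not bound it. The
first 16 bands of the 256-band grid are unusable detector roll-off and are
trimmed, leaving 240 bands.

The white frame is averaged over its scan lines before use, suppressing
line noise; the interface accepts a per-session or per-cube white, since
either acquisition protocol is in common use. Absorbance uses base-10
logarithms, the NIRS convention.

# Segmentation and the crease

Beans on a near-black stage are darker *in reflectance* than they appear in
absorbance: the stage's mean absorbance (~1.2 au here) sits far above the
beans' (~0.4–0.6 au), so Otsu's threshold on the mean-absorbance image
separates the two modes cleanly and the *low*-absorbance side is kept as
foreground. A 3×3 morphological closing bridges objects split by the
midline crease before connected-component labelling; components under 50
pixels are specks and are dropped. Labels are ordered row-major by centroid
(rows are found by clustering centroid lines with a gap of half the median
object height), giving reproducible bean numbering across repeated scans.
Beans scanned on both surfaces are paired by rank of scan position, with a
reversal flag and an explicit-pairing escape hatch when counts differ.

The crease (mesenteric root) distorts reflectance topographically. The
exclusion rule used by the original instrument software is not documented,
so this package states its own: among pixels within 30 % of the minor-axis
extent of the bean's major axis, those whose spectra deviate from the
bean's band-wise median by more than a z-score threshold (default 3,
measured against a band-wise MAD so the crease cannot inflate its own
denominator) are removed from the calibration mask, capped at 20 % of the
bean's pixels. Crease pixels are still *predicted* in chemical images —
they were only excluded from calibration.

# Pre-treatments

All operators are deterministic and act per spectrum, so the identical
transform applies to a calibration mean spectrum and to a single pixel at
prediction time:

* **SNV** — centre and scale each spectrum to unit (n−1) SD.
* **MSC** — regress each spectrum on a reference (the calibration column
  mean), correct to `(x − b)/a`; the reference is stored on the chain after
  fitting so replays are exact.
* **Savitzky–Golay derivatives** — derivative of a local least-squares
  polynomial (default 5-point window, 2nd-order polynomial, 1st or 2nd
  derivative), implemented as precomputed weight matrices. Derivatives are
  taken with respect to band index: the 980–2500 nm grid is near-uniform
  and this is the standard chemometrics convention. Edges refit the
  polynomial on the truncated one-sided window rather than shortening the
  spectrum — pixel-wise mapping needs length preservation.
* **De-trending** — residual after a polynomial in band index (default
  degree 2; the degree is a documented choice, not an instrument
  constant).

Chains are ordered lists serialised to JSON (17 significant digits, a
lossless decimal round trip for doubles). The "SNV + 1st derivative"
chain applies SNV first, matching the label order of that treatment's
name; the order is configurable.

# PLS1, cross-validation and metrics

One model per analyte (PLS1): NIPALS on column-centred spectra and centred
response, no autoscaling (absorbance bands share units, and variance
scaling would inflate noisy water bands). Deflation per component; the
collapsed coefficients $\beta = W(P'W)^{-1}q$ give predictions identical
to the latent-score route (checked to 1e−8). Convergence guard: relative
score change < 1e−10, 500 iterations.

Cross-validation randomly deals objects into 20 near-equal segments under
a recorded seed. Everything data-driven — MSC reference, centering, the
NIPALS fit — is refit inside each fold. This is stricter than common
chemometrics practice, which often fixes the pre-treatment once on the full
data; refitting avoids optimistic leakage and costs little. The LV choice
is the smallest count whose RMSECV is within 2 % of the curve minimum:
"minimise prediction error while avoiding overfitting" as an explicit,
reproducible rule.

Reported metrics: R²c/R²cv, RMSEC/RMSECV, RPD = SD(reference)/RMSECV, and
RMSECV as a percentage of the observed reference range. RPD ~1.4 supports
only coarse screening; ~2 supports quantification.

Band reduction ranks the full-spectrum |β| and picks the top *k* bands
subject to a minimum index separation (default 3 bands ≈ 18 nm) so one
absorption feature does not fill the whole budget; ties break toward the
lower wavelength. The reduced model reruns the identical pipeline on the
column subset with LV ≤ *k*.

# Chemical images

Prediction applies the model's chain to each pixel spectrum individually —
the only reading consistent with mapping at the single-pixel level — then
$\beta$. Per-bean tables carry both the mean of pixel predictions and the
prediction of the bean's mean spectrum; with an identity chain the two are
equal (linearity), with SNV/derivative chains they differ slightly and both
are worth inspecting. Dry-weight conversion divides by (1 − moisture),
using a per-pixel moisture map when supplied and a scalar batch value
otherwise; the moisture calibration itself is an external input, not
re-derived here. Colour bounds default to the 1st–99th percentile of bean
pixels so single hot pixels do not flatten the scale; the numeric map is
always saved losslessly beside the PNG.

# The synthetic study

The generator exists so that every module is testable against known truth
with no instrument data. Its defaults are fixed to the study conditions and
are not tuning knobs:

* **Scene**: 10 beans per cube on a near-black stage; 256 bands over
  980–2500 nm, 16 unusable leading bands; 320 detector samples per line.
  The scene height (96 lines) and bean sizes are this package's choice of a
  realistic layout; tests and examples use further down-sized scenes
  (64 × 160 and smaller), which changes pixel counts per bean but not
  noise, spectra or concentrations.
* **Concentrations** (mg g⁻¹ "as is"): Arabica sucrose 46.7 ± 7.5,
  caffeine 15.7 ± 2.3, trigonelline 8.6 ± 1.8; Robusta 33.6 ± 9.1,
  19.9 ± 4.9, 7.3 ± 1.7; inter-analyte correlations −0.445
  (sucrose–caffeine), 0.395 (sucrose–trigonelline), −0.185
  (caffeine–trigonelline); truncation by rejection (cap 1000 draws, then
  clamping) to the pooled observed ranges 5.3–70.8, 9.2–31.9 and
  3.9–15.0. Moisture 9.4 ± 1 %, implied by the ratio of as-is to
  dry-basis reference means.
* **Spectra**: pixel absorbance = bulk-matrix spectrum + Σ concentration ×
  unit component spectrum. Component profiles are synthetic Gaussian-peak
  constructions at the compounds' absorption features — caffeine
  1668/2250/2425 nm, trigonelline 1668/2269 nm (sharing the 1668 nm band
  with caffeine, a deliberate collinearity), sucrose with a broad
  1460–1700 nm region and a 2070 nm band — because no measured pure
  spectral library ships with the package, and recovery testing needs the
  linear-mixture structure and band overlap, not radiometric realism.
* **Distortions**: bean-level multiplicative scatter (slope SD 0.05,
  offset SD 0.02 au), within-bean linear gradient (±5 % along the major
  axis), band-wise Gaussian noise (SD 0.01 au per pixel), heavy noise on
  the trimmed leading bands, dead detector elements (3 per cube), optional
  crease stripe (+0.3 au). The absorbance is then inverted through the two
  calibration equations into counts (white ~9000 counts with smooth
  spectral and sample patterns, darks 100 counts, sample/white exposures
  4/2 ms).

What passing recovery tests *does* show: the pipeline's calibration,
segmentation, pre-treatment, regression and mapping stages are correct and
consistent end to end. What it does *not* show: real-data performance.
Synthetic beans are exact linear mixtures of four components with mild
scatter; real beans add surface topography, specular effects, moisture and
matrix chemistry far beyond three analytes, and reference-analysis error.
Synthetic cross-validated errors (RMSECV ≈ 0.1–0.8 mg g⁻¹) are therefore
roughly an order of magnitude smaller than those achievable on real bean
sets, and the package's recovery criteria (e.g. R²cv ≥ 0.8, RPD ≥ 2 for
the caffeine-like scenario on 260 beans) are deliberately stated as floors,
not as matches to real-data figures.

# Numerical choices and degenerate inputs

* Masked (NA) elements never enter means; a fully-masked neighbourhood
  leaves a bad pixel masked.
* SNV on a constant spectrum, MSC with slope below 1e−8, zero-variance
  responses and wavelength-grid mismatches raise errors naming the
  offending object rather than producing NaNs.
* Savitzky–Golay requires an odd window exceeding the polynomial order;
  edge windows keep at least `poly + 1` points, so the default 5/2 setting
  fits exactly at the ends.
* All randomness (concentration draws, scene jitter, noise, CV segment
  assignment) flows through explicit seeds; fixtures regenerate
  byte-for-byte from their seed manifest, and sub-seeds are derived by
  small integer offsets.
* Equal-|β| ties in band selection and equal-RMSECV plateaus in LV
  selection resolve toward the lower wavelength and the smaller LV — the
  parsimonious option in both cases.

# Problem sizes

The test suite and the acceptance script generate their data at run time:
the recovery study uses 260 beans (26 cubes of 10), correlation checks use
10 000 draws, law-of-large-numbers checks 5 000; scenes are 64 × 160 pixels
in tests and 96 × 320 in the acceptance script. These sizes make the full
suite run in a few minutes on one CPU while keeping every statistical check
comfortably powered.

# Known limitations

* The crease-exclusion rule is a documented stand-in, not the original
  instrument routine.
* Derivatives assume uniform band spacing; strongly non-uniform grids
  would need wavelength-aware weights.
* No outlier diagnostics, no nonlinear models, and no variable selection
  beyond |β| ranking — deliberately out of scope.
* Touching beans are not split (no watershed); the generator never places
  beans in contact.
* The moisture model for dry-basis work is consumed, never estimated.
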
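---
title: "FTIR imaging chemometrics for oral epithelial lesions: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR imaging chemometrics for oral epithelial lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirstrat)
```

## The problem

Histopathological grading of oral epithelial dysplasia (OED) — the
precancerous middle ground between benign hyperkeratosis (HK) and oral
squamous cell carcinoma (OSCC) — is subjective and a poor predictor of
malignant transformation in individual patients. FTIR hyperspectral
imaging offers an objective alternative: every pixel of a tissue image
carries a full mid-infrared absorbance spectrum whose bands quantify
protein (amide I near 1650 cm⁻¹, amide II near 1548 cm⁻¹), nucleic-acid
phosphate (1240, 1080, 966 cm⁻¹) and carbohydrate (1154, 1030 cm⁻¹)
content. As oral epithelium progresses from HK through OED to OSCC, the
protein bands fall, the phosphate/carbohydrate bands rise, and the amide
II band red-shifts — a biochemical axis a latent-variable classifier can
learn from the benign and malignant extremes and then apply to the
ambiguous middle class.

`ftirstrat` implements that strategy end to end:

1. simulate (or read) 16 × 16-pixel imaging areas of transmission
   spectra;
2. preprocess each area (absorbance conversion, fingerprint region
   1800–950 cm⁻¹, Savitzky–Golay smoothing, EMSC scatter correction,
   AWLS baseline correction, vector normalization, and a 7-point
   second derivative for modeling);
3. quality-control pixels by reduced Hotelling T²/Q-residual outlier
   removal and separate epithelium from stroma by hierarchical
   clustering;
4. average the retained epithelial pixels of each area into a
   representative spectrum and keep the two most heterogeneous
   representatives per sample;
5. train a two-class PLS-DA model (H vs C) with grouped venetian-blinds
   cross-validation;
6. grade each OED sample HK-grade, OSCC-grade or borderline by which
   side of the 0.5 discrimination line its two spectra fall on.

## The discriminant model

PLS-DA is PLS1 regression on a 0/1 class code. With training spectra
\(X\) (rows centered by \(\bar x\)) and \(y \in \{0,1\}\) (H → 0,
C → 1, centered by \(\bar y\)), the NIPALS recursion extracts latent
variables: for each component \(a\),

\[ w_a \propto X_a^\top y_a,\quad t_a = X_a w_a,\quad
   p_a = X_a^\top t_a / t_a^\top t_a,\quad
   q_a = y_a^\top t_a / t_a^\top t_a, \]

followed by deflation \(X_{a+1} = X_a - t_a p_a^\top\),
\(y_{a+1} = y_a - q_a t_a\). This realizes the bilinear decomposition
\(X = T P^\top + E\), \(y = U q^\top + f\). The regression vector is
\(b = W (P^\top W)^{-1} q\), predictions are
\(\hat y = (x - \bar x)^\top b + \bar y\), and a spectrum is called
OSCC when \(\hat y \ge 0.5\) (a tie at exactly 0.5 goes to the
positive class — documented and test-pinned). The number of latent
variables is the smallest count minimizing the cross-validated
misclassification error (ties favor fewer). 0/1 coding was chosen over
symmetric ±1 coding so the conventional 0.5 threshold retains its
meaning.

Support-vector machines with an RBF kernel and gradient-boosted trees
are available as pluggable comparators behind the same fit/predict
contract, tuned by a small grid search under the identical grouped
folds; they delegate to `e1071` and `xgboost`. The PLS-DA model itself
is implemented in full here and is verified in the tests against an
independently coded NIPALS recursion.

## Grouped venetian-blinds cross-validation

Each sample contributes exactly two representative spectra, and both
must live in the same fold — otherwise a classifier can "recognize" a
sample rather than a disease class. Samples are ordered
lexicographically by id and sample \(j\) (0-based) is assigned to fold
\(j \bmod k\) with \(k = 10\); rows inherit their sample's fold. The
grouping invariant is asserted on every run. Pooled held-out scores
give the headline confusion matrix, sensitivity TP/(TP+FN) with OSCC
positive, specificity TN/(TN+FP), and the trapezoidal ROC AUC;
per-fold and calibration (resubstitution) metrics are reported
alongside.

## OED stratification rule

The trained model scores the 2 spectra of each OED sample. With
threshold \(\tau = 0.5\) and borderline half-width \(\delta\)
(default 0):

* HK-grade — both scores below \(\tau - \delta\);
* OSCC-grade — both at or above \(\tau + \delta\);
* borderline — the scores straddle the line, or either falls within
  \(\delta\) of it.

\(\delta = 0\) makes the rule purely side-based, the most literal
reading of "which side of the discrimination line"; the parameter
exists because a user may reasonably want a safety corridor. Grades are
per-sample, never per-spectrum. The absolute score distance between a
sample's two spectra (the "line length" in a discrimination plot) is
reported as an intra-sample heterogeneity proxy.

## What the synthetic generator emulates

No spectra are distributed with this package; a seeded generator stands
in for a biopsy cohort, with ground truth for every pixel and sample.
Its defaults are the study conditions used throughout the tests:

* **Design**: 12 HK, 11 OSCC, 11 OED samples; 3 imaging areas per
  sample; 16 × 16 pixels per area; fingerprint grid 1800 → 950 cm⁻¹ at
  2 cm⁻¹ spacing (426 points). The OED latent grades are fixed at
  6 HK-like, 4 OSCC-like and 1 borderline, the borderline sample
  drawing half its areas from each profile.
* **Spectra**: sums of Gaussian bands. HK and OSCC amplitudes anchor
  the orderings amide I/II/III falling and phosphate/carbohydrate
  rising with progression; the two OED profiles are 0.75/0.25 convex
  mixtures of the anchors, so every ordering is strict and OED scores
  land between the classes. The amide II red shift is an extra
  right-shoulder sub-band at 1540 (OED) and 1534 cm⁻¹ (OSCC) — the
  literature gives the direction and relative size but no magnitude, so
  8 and 14 cm⁻¹ shifts were fixed once. Band FWHM ≥ 8 cm⁻¹ represents
  the 4 cm⁻¹ instrument resolution. No band sits in 1750–1700 cm⁻¹
  (free lipids are removed by deparaffinization). Stroma is a distinct
  collagen-dominated profile (amide I at 1660, collagen triplet at
  1338/1282/1204 cm⁻¹).
* **Distortions** (all in absorbance space, then \(T = 10^{-A}\),
  clipped to \([10^{-6}, 1]\) so the log stays defined): multiplicative
  scatter uniform on (0.85, 1.15); a random quadratic baseline with
  coefficient SDs (0.04, 0.02, 0.01); additive noise SD 0.004 a.u.;
  2 % outlier pixels whose baseline coefficients and noise are ×10 —
  strong enough that the reduced T²/Q rule at threshold 3 flags them.
  Absolute absorbance magnitudes are not documented for any class in
  this field's reports, so amplitudes were chosen for ordering fidelity
  and realistic signal-to-noise (band heights 0.1–1 a.u. against
  0.004 a.u. noise), once, and not revisited.

What the generator deliberately does **not** model: resonant Mie
scattering physics (the EMSC here is the basic polynomial variant),
paraffin residues, atmospheric water-vapor/CO₂ lines, spatial
correlation between neighboring pixels, and pathologist annotation
error. Consequently, passing tests demonstrate that the pipeline
recovers known structure under realistic multiplicative/baseline/noise
artifacts — not that it would survive every failure mode of real
tissue images.

## Numerical and algorithmic choices

* **Savitzky–Golay**: implemented as an explicit projection matrix so a
  whole cohort filters in one multiply. Interior points equal the exact
  sliding polynomial fit (verified to 1e-10 against a per-window
  polyfit oracle and cross-checked against `signal::sgolayfilt`); edge
  points use the first/last full window's polynomial evaluated at the
  edge, so no window shrinkage occurs. Smoothing defaults: window 9,
  order 2 — wide enough to suppress the generator's noise, narrower
  than the narrowest band. Derivative step: the conventional 7-point
  window, order 3, scaled by the grid spacing squared.
* **EMSC**: each row is regressed on an offset, the reference spectrum
  and Legendre polynomials (order 2) in scaled wavenumber; the
  correction divides out the multiplicative coefficient. The reference
  is the mean of the set being corrected unless supplied. Rows with
  multiplicative coefficient below 1e-8 cannot be meaningfully rescaled
  and pass through flagged.
* **AWLS baseline**: an asymmetric iterative polynomial estimate. A
  hard 0/1 reweighting ("points above the fit get weight zero") proved
  unstable during development — on noisy rows the weight sets cycle
  indefinitely, and forcing weights to only shrink collapses the fit
  onto 3-point interpolations with wild extrapolation. The
  implementation therefore iterates by clipping: refit the polynomial
  to `pmin(y, baseline)`, which down-weights above-baseline points by
  anchoring them at the baseline level. The baseline sequence is
  monotone non-increasing, hence always converges; iteration stops when
  the largest per-row change drops below `awls_tol` (5e-5 a.u., scaled
  by the row's magnitude — two orders below typical noise), with a cap
  of 300 iterations and a logged warning for stragglers (in practice a
  handful of extreme outlier pixels, which the T²/Q step removes
  anyway).
* **Vector normalization** is Euclidean (L2); area normalization is the
  other common reading, but L2 is assumed here and applied again after
  differentiation, which destroys the unit norm. Zero-norm rows are an
  error by default; the pixel pipeline drops them (a fully clipped
  outlier pixel carries no information).
* **Pixel QC**: PCA (via `prcomp`) retains the smallest component count
  explaining ≥ 95 % variance, capped at 10 and at the numerical rank.
  T² sums squared scores over retained components normalized by their
  variances; Q is the squared residual norm. Each is divided by its
  95 % limit — T² by the F-distribution relation
  \(k(n-1)/(n-k)\,F_{0.95}(k, n-k)\), Q by the Jackson–Mudholkar
  approximation — and a row is an outlier when either reduced value
  exceeds 3. The original procedure removed "high" points by visual
  inspection; a fixed threshold is the reproducible replacement, and 3×
  the 95 % limit balances ≥ 90 % recall on injected outliers against a
  ≤ 5 % false-positive rate at the default noise (verified over 20
  seeded replicates).
* **Epithelium selection**: Ward.D2 linkage on Euclidean distances, cut
  at k = 2; the majority cluster is kept (areas are placed mostly in
  epithelium), overridable. The split only happens when the top merge
  is at least 3× the second-highest — a homogeneous area is returned
  whole rather than split along noise.
* **Two representatives per sample**: the pair of area representatives
  with maximal Euclidean distance — the most literal deterministic
  operationalization of "best reflect intra-sample heterogeneity".
  Ties break lexicographically by area id.
* **Degenerate inputs**: rank-0 areas (zero variance) skip outlier
  removal; a zero Q-limit with zero residuals yields reduced Q = 0;
  single-class training sets, grid mismatches, ragged CSVs and
  missing ENVI wavelength fields are explicit errors.

## Problem sizes and reproducibility

The default cohort (34 samples × 3 areas × 256 pixels × 426
wavenumbers) runs end to end in well under a minute; the test suite's
replicate studies (20 seeded cohorts for stratification recovery, 20
areas for outlier power) were sized so the whole suite completes in
minutes on a single core while still exercising the full design. One
master seed drives everything; each pipeline stage forks its own
deterministic sub-seed, so stages are independently reproducible and an
identical configuration yields byte-identical artifacts.

## Known limitations

* The generator's class separation is, by construction, favorable:
  perfect CV sensitivity/specificity on synthetic data says the
  pipeline is correct, not that real biopsies separate perfectly.
* Basic EMSC does not model resonant Mie scattering; strongly
  Mie-distorted measurements would need the iterative physics-based
  extension.
* The borderline rule with δ = 0 depends on a single threshold
  crossing; with real, noisier scores a nonzero δ (or a probabilistic
  margin) would be more conservative.
* No multiclass (3-class) model is provided by design: the strategy is
  to train on the unambiguous extremes and let the middle class be
  scored against them.
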
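---
title: "Quantifying hepatic steatosis from multispectral optoacoustic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic steatosis from multispectral optoacoustic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msotlipid)
```

# The measurement and its model

Multispectral optoacoustic tomography acquires one absorption-weighted image
per excitation wavelength. The package's default grid is the standard NIR
protocol, 700–960 nm in 10 nm steps (27 wavelengths), which covers
haemoglobin contrast, the 800 nm oxy/deoxy isosbestic point, and the lipid
absorption peak at 930 nm. Within one acquisition the intensity scale is
arbitrary (a.u.) but shared across wavelengths, which is the property every
statistic below either exploits or must be invariant to.

The analysis model is linear: a measured ROI spectrum is an unknown
non-negative mixture of chromophore reference spectra,

$$ y(\lambda) \;=\; \sum_c \beta_c\, s_c(\lambda) + \varepsilon(\lambda),
\qquad c \in \{\mathrm{Hb}, \mathrm{HbO_2}, \mathrm{Lipid},
\mathrm{H_2O}, \mathrm{ICG}\}. $$

`unmix()` fits $\beta$ by least squares with no intercept: an offset term
would absorb the water baseline ambiguously, and the named chromophores are
the model. The default is the unconstrained fit (plain linear regression);
`constraint = "nonnegative"` is offered because negative a.u. coefficients
are unphysical, at the price of a biased fit near zero. Unmixing always
operates on raw spectra — peak normalisation (`normalize_spectrum()`) is a
visualisation device that destroys the a.u. scale on which TBV comparisons
rely.

Per-ROI unmixing uses the ROI **mean spectrum**. For the unconstrained fit
this equals the mean of per-pixel coefficients by linearity (asserted in the
test suite), so the choice is benign in default mode; under the non-negative
constraint the two conventions genuinely differ and the mean-spectrum route
is the documented one.

## The reference library

The instrument vendor's built-in reference spectra are not public, so the
package ships a literature-shaped compilation
(`inst/extdata/spectral_library.csv`): oxy-/deoxy-haemoglobin
molar-extinction shapes converted to a whole-blood absorption scale
(cm^-1), pure-water absorption, a mammalian-fat shape peaking at 930 nm, and
a plasma ICG shape peaking at 800 nm, linearly resampled onto the 10 nm
grid. Only relative shapes matter for unmixing in arbitrary units. Loading
validates non-negativity, no all-zero column, and Hb/HbO₂ agreement at
800 nm within 5% relative — the isosbestic property that the difference
analysis and the aorta normalisation assume. (Published extinction tables
put the crossing near 797 nm with a ~7% gap at 800 nm; the packaged values
keep the documented 800 nm tolerance.)

## ROI selection

Anatomical ROIs arrive as boolean masks. The manual "fine-tuning on the Hb
image" step of interactive workflows is replaced by a robust-statistics
surrogate, `refine_roi()`: keep pixels whose Hb unmixing value lies within
median ± k·MAD (k = 3 by default, MAD with the 1.4826 consistency constant)
of the in-mask distribution. A blood-rich organ should be Hb-homogeneous;
pixels failing the filter are vessels, artefacts, or depth-corrupted
spectra. If the filter would empty the mask the preliminary mask is returned
with a `fallback` flag rather than failing — an empty ROI is never a useful
answer.

# The difference analysis

The three-wavelength lipid statistic is

$$ D \;=\; \frac{I_{700} - I_{930}}{I_{800}}. $$

$I_{930}$ rises with lipid, $I_{700}$ is blood-dominated and comparatively
stable, and dividing by the isosbestic $I_{800}$ removes the per-acquisition
scale without oxygenation sensitivity. $D$ therefore *falls* as liver lipid
accumulates; it is exactly invariant under global rescaling and touches only
three wavelengths (both properties are tested), which is what makes a
three-wavelength light source sufficient for screening. The printed form of
the formula is parsed as the quotient of the difference, per its prose
definition. The inverse relation to lipid is treated as qualitative: the
tests assert strict monotone decrease of $D$ in lipid fraction over 0–60%,
not proportionality, which the forward model does not support.

The **difference index** divides the kidney readout by the liver readout.
The kidney does not accumulate fat in obesity-driven steatosis, so the ratio
cancels individual variance and flips orientation: it *rises* with
steatosis, which is the orientation the ROC analysis assumes for its
scores. The raw liver readout, being inversely related, is handled with
`invert = TRUE` in `roc_grade()`.

# Grading and classification

`grade_from_fraction()` maps histological fat fraction to grades 0–3 with
thresholds 5%, 33%, 66%. The source convention leaves the upper boundaries
ambiguous except for grade 3 ("> 66%"); for consistency with that one strict
inequality the package assigns 33 to grade 1 and 66 to grade 2, documented
and tested.

The ROC machinery is implemented from the estimators' definitions because
the package fixes conventions that off-the-shelf ROC software varies in:

* **AUROC** is the Mann–Whitney pair estimator (ties 1/2), invariant under
  monotone transforms.
* **Youden cutoffs** are searched over midpoints between adjacent distinct
  scores plus ±∞ sentinels (stable under infinitesimal perturbation, unlike
  observed-value cutoffs), positive prediction meaning score ≥ cutoff; ties
  in J break towards higher sensitivity, then the lower cutoff.
* **DeLong** variance uses the placement-value (structural components)
  estimator; the 95% CI is the normal approximation and is *not* clipped to
  [0, 1] by default, matching how ROC reports conventionally print upper
  bounds like 1.01 for near-perfect classifiers (`clip_ci` restores
  clipping). The paired z-test for two correlated AUROCs uses the
  placement-value covariances.
* No multiple-testing correction is applied anywhere; pairwise tests are
  reported raw, matching common practice in this literature.

The suite cross-checks AUROC and Youden J against brute-force enumeration on
500 random small instances and the DeLong variance, CI and paired test
against `pROC` and against a 2000-replicate stratified bootstrap.

Two-group readout comparisons follow a fixed routing rule
(`group_compare()`): Shapiro–Wilk on each group at α = 0.05; both pass → an
unpaired equal-variance t-test; otherwise Mann–Whitney. Groups with no
internal variation cannot be tested for normality and route to
Mann–Whitney; two completely identical flat groups return p = 1 directly.

# ICG clearance kinetics

Hepatic indocyanine-green time courses are normalised in the documented
order — subtract the pre-injection background (the mean of all samples at
t ≤ 0), then divide by the post-subtraction peak — so the peak is exactly 1
and the baseline maps to ~0. Summaries are deliberately model-light: the
elimination rate is the negative OLS slope of log(normalised) over the last
`tail_points = 5` post-peak samples, half-life is ln 2 / rate, and
`retention_60` interpolates the normalised curve at 60 min, the standard
monitoring window and the headline comparison metric. A full bi-exponential
fit was rejected: the real data follow no declared model, and a tail slope
is robust, assumption-light and sufficient to rank clearance speed. For the
generator's own curves the tail slope recovers the generating excretion
rate within 10% noiseless (the tail begins at ≥ 3 times the peak time, where
the fast exponential has died off) and within 15% median error at 2% noise.

# The synthetic data generator

The generator exists so that every downstream stage has a ground truth. It
emulates, with defaults chosen once as study conditions:

* **Tissue spectra** (`forward_spectrum()`): intensity =
  amplitude × Φ(λ, depth) × mixture absorption, with the 1-D
  diffusion-theory fluence Φ = exp(−μ_eff d),
  μ_eff = √(3 μ_a (μ_a + μ_s′)), μ_s′ = 10 cm⁻¹ constant across λ. The
  analysis applies no fluence correction, so the generator needs only enough
  realism to distort deep-tissue spectra the way attenuation does in vivo.
  At depth 0 the model is exactly linear in fractions — the property the
  machine-precision recovery tests use.
* **Default compositions**: liver = blood volume 0.30 at sO₂ 0.30 (venous
  dominance of the portal system) plus water; kidney = blood 0.25 at
  sO₂ 0.70, water 0.70, at a default depth of 6 mm. The depth matters:
  oxygenated blood absorbs *more* at 930 than at 700 nm, so a zero-depth
  kidney would have a negative difference readout; in vivo, attenuation by
  overlying tissue gives deep organs their descending spectral shape, and
  6 mm of the default fluence model reproduces it. The phantom carrier is
  nearly transparent (5% water), emulating a lipid/solvent dilution series.
* **Noise**: multiplicative Gaussian (default σ = 2%) plus additive Gaussian
  (default σ = 0.5% of the clean signal's peak), both from one seeded
  stream; unspecified by any source, exposed in `noise_model()`.
* **Phantom series** (`make_phantom_series()`): lipid weight f, base weights
  scaled by (1 − f), fractions 0–100% (carrier) or 0–60% (liver base, the
  range steatotic livers realistically reach), three replicate sections per
  fraction.
* **Graded cohorts** (`make_graded_cohort()`): grade-conditional lognormal
  scores, score = median_g · exp(σ_log Z). Lognormal because unmixing
  readouts are positive and right-skewed, spanning three orders of magnitude
  between healthy and grade 3. Defaults: n = 14/11/9/9 for grades 0–3
  (n = 43), linear-score medians 1.3/30/120/675 a.u. anchored to the
  reported healthy and grade 3 levels with interior grades log-spaced
  between them, difference-index medians 0.70/1.00/1.05/1.10 reflecting the
  index's compressed dynamic range above grade 0, σ_log = 0.8.
* **Clearance curves** (`simulate_clearance()`): baseline +
  amplitude·(e^(−k_out t) − e^(−k_in t)) on a 0–60 min grid sampled every
  5 min, k_in = 0.5/min, k_out = 0.05/min by default (peak near 5 min,
  ~90% cleared at 60 min for a healthy liver); impaired excretion is
  simulated by lowering k_out alone (pipeline default 0.02 vs control
  0.08/min, five animals per group).

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: spatial image texture and reconstruction
artefacts, respiration motion, wavelength-dependent scattering, spectral
colouring beyond the single-path fluence factor, inter-animal anatomical
variability beyond the lognormal score spread, and any coupling between
steatosis grade and blood oxygenation. Parameter-recovery results on
synthetic data are a correctness check of the estimators, not an accuracy
claim for in vivo quantification.

# Numerical conventions and degenerate inputs

* Singular unmixing designs (collinear library columns) raise an error
  naming the offending components via QR pivoting; rank is never silently
  dropped.
* `so2` is flagged `NA` when TBV ≤ 0 rather than returning a ratio of
  meaningless sign.
* Empty ROI masks, missing working wavelengths (named in the error),
  non-positive I₈₀₀, zero liver readouts, single-class label vectors and
  undersized groups all fail fast with specific messages; degenerate
  dichotomizations warn and flag rather than fail.
* All simulation randomness flows through seeded generators that save and
  restore the global RNG state; the pipeline derives per-stage sub-seeds
  from one master seed so any stage is reproducible in isolation, and
  reruns are byte-identical.

## Problem sizes

The shipped test suite works at desk scale, chosen as the smallest sizes
that exercise each contract: 500 random instances (n ≤ 12) for the ROC
brute-force oracles, 200 replicates for each noisy-recovery check, a
2000-replicate bootstrap for the DeLong cross-check, and image stacks of a
few hundred pixels. The full suite runs in well under a minute.

# Known limitations

* **Lipid–water collinearity.** Above ~900 nm lipid, water and HbO₂ all
  rise, so in blood- and water-dominated spectra (a liver base) the lipid
  coefficient is poorly conditioned: at 2% multiplicative noise its median
  relative error is ~1.4% in the transparent-carrier phantom design but
  ~30% at a 20% lipid fraction over a liver base. Ranking (Spearman)
  survives; absolute per-animal coefficients at low fractions should be
  treated with caution — consistent with steatosis readouts being used as
  graded scores, not fat fractions.
* **No absolute quantification.** Coefficients are a.u.; converting to fat
  fraction would require fluence correction and co-registered ground truth,
  both out of scope.
* **Stack formats.** Image stacks round-trip through multi-page 32-bit
  float TIFF with a JSON sidecar (wavelengths, scale, masks, provenance) —
  exact to single precision — or a lossless long-format CSV. ROI masks in
  the sidecar are exact.
* The interface is R functions plus this vignette; `run_pipeline()` is the
  single entry point composing simulate → unmix → lipid metrics → ROC → ICG
  stages with structured per-stage error reporting.
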
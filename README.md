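# msotlipid

Label-free lipid quantification and liver-function analysis for
multispectral optoacoustic tomography (MSOT).

## The problem

Hepatic steatosis (fatty liver, NAFLD) is graded today by histopathology,
which needs a biopsy and cannot follow disease in the same animal over time.
MSOT images absorption-weighted contrast at many near-infrared wavelengths
in vivo: haemoglobins dominate 700–900 nm, lipid has a signature absorption
peak near 930 nm, and the oxy/deoxy isosbestic point at 800 nm gives an
oxygenation-insensitive reference channel. This package implements the
analysis side of an MSOT steatosis workup for researchers running such
studies (or developing the methods):

* **Spectral unmixing.** A per-ROI or per-pixel spectrum
  *y(λ)* is decomposed by least squares into reference chromophore spectra,
  *y(λ) ≈ Σ_c β_c s_c(λ)* over *c* ∈ {Hb, HbO₂, Lipid, H₂O, ICG} (no
  intercept; optional non-negativity). Derived blood metrics:
  TBV = β_HbO₂ + β_Hb and sO₂ = β_HbO₂ / TBV, with aorta-referenced
  normalisation for inter-animal comparison.
* **Difference analysis.** The three-wavelength lipid statistic
  (I₇₀₀ − I₉₃₀) / I₈₀₀ — scale-invariant, falls with liver lipid — and the
  kidney/liver **difference index**, which rises with steatosis.
* **Grade classification.** Histological grade assignment
  (grade 0: < 5%, 1: 5–33%, 2: 33–66%, 3: > 66% fat fraction) and full ROC
  machinery: Mann–Whitney AUROC, DeLong variance/CI and paired z-test,
  Youden-index cutoffs with Se/Sp/PPV/NPV, plus Spearman correlation and a
  Shapiro–Wilk-gated t / Mann–Whitney two-group comparison.
* **ICG clearance kinetics.** Baseline subtraction and peak normalisation of
  indocyanine-green time courses, log-linear tail fits for the elimination
  rate and half-life, retention at 60 min, and cohort comparisons.
* **Synthetic data generator.** A seeded forward model (chromophore
  mixtures × diffusion-theory fluence × multiplicative/additive noise),
  phantom dilution series, graded lognormal score cohorts and bi-exponential
  ICG curves, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(msotlipid)

lib <- spectral_library()                      # packaged reference spectra
sp  <- forward_spectrum(liver_model(lipid_fraction = 0.3), lib)

unmix(sp, lib)
#> Spectral unmixing (unconstrained least squares)
#>    Hb  HbO2 Lipid   H2O
#> 0.147 0.063 0.300 0.455
#> TBV: 0.21  sO2: 0.3
#> RMS residual: 1.526e-16

difference_readout(sp)
#> Difference readout: 0.488  (I700 = 1.516, I800 = 0.9077, I930 = 1.073)

cohort <- make_graded_cohort(seed = 1)
roc_grade(cohort, "score_linear", threshold_grade = 2)
#> ROC: score_linear, grades >= 2 (n+ = 18) vs below (n- = 25)
#>   AUROC 0.98 (95% CI 0.95-1.02)
#>   cutoff 77.82  Se 94%  Sp 100%  PPV 100%  NPV 96%

summarize_kinetics(simulate_clearance(clearance_params(k_in = 0.5, k_out = 0.05)))
#> ICG kinetics: peak at 5 min, elimination rate 0.05 /min (t1/2 13.9 min), retention@60 0.0715
```

The unmixing recovers the generating composition exactly (the forward
spectrum is noiseless and at depth 0, so it is exactly representable); the
30% lipid liver lowers the difference readout relative to a lean liver
(0.58 at 0% lipid). The ROC row reads as a grade ≥ 2 classifier on the
simulated cohort; the unclipped DeLong CI can exceed 1 for near-perfect
classifiers, as ROC software conventionally prints it. The ICG summary's
elimination rate equals the generator's excretion rate `k_out` because the
log-linear tail of the bi-exponential curve is dominated by the slower
exponential.

`run_pipeline(pipeline_config(seed = 1), outdir = "out")` composes all
stages end to end and writes the artifact bundle (phantom recovery tables,
cohort and ROC tables, ICG summaries, `results.json`), each output stamped
with package version, seed and config hash; reruns with the same seed are
byte-identical.

## Scope notes

Unmixing coefficients are in arbitrary units; no conversion to absolute
lipid fraction is attempted, and no tomographic reconstruction or fluence
correction is performed. See the methods vignette
(`vignettes/msot-steatosis.Rmd`) for the model assumptions, generator
defaults, numerical conventions and known limitations.
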
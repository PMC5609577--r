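---
title: "Calibrating lipoprotein subclass concentrations from diffusion-edited NMR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating lipoprotein subclass concentrations from diffusion-edited NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liponmr)
```

## The problem

Serum lipoproteins are a continuum of particles conventionally divided by
size into chylomicrons (CM), VLDL, LDL and HDL, and further into subclasses
(here indexed CM01 down to HDL20 by decreasing diameter). The triglyceride
(TG) and cholesterol (CH) content of each subclass is clinically
informative, but the reference assay (size-fractionating HPLC) is slow and
expensive. In a diffusion-edited ^1^H NMR spectrum of serum, the broad lipid
methyl and methylene resonances dominate, and their chemical shift depends
on particle diameter: larger particles resonate slightly downfield. A
multivariate calibration — partial least squares with a single response
(PLS-1) — can therefore map the 1.4–0.6 ppm region of the spectrum onto the
per-subclass TG and CH concentrations measured once by the reference assay,
after which NMR alone suffices for new samples.

`liponmr` implements that calibration pipeline end to end: representative
sample selection, training/test splitting, model fitting and selection,
significance testing, external validation, cross-cohort sanity checks, and
the downstream crossover-trial treatment analysis. Because the original
clinical spectra are not publicly deposited, the package ships a synthetic
spectrum generator that emulates the relevant physics and the two cohort
phenotypes, so every stage of the pipeline runs and is tested on data with
known ground truth.

## Data model

Spectra live on a uniform, descending ppm grid with spacing 0.8/1746 ppm
and a grid point exactly at 1.4 ppm. Two fixed feature windows define the
X matrices of the calibration:

* the **TG window**: 1746 consecutive points from 1.4 ppm upfield,
  covering the lipid methylene and methyl signals down to 0.6 ppm;
* the **CH window**: the final 961 points of the TG window
  (≈1.04–0.6 ppm), i.e. the methyl signal only.

The two printed point counts (1746 over 0.80 ppm and 961 over ≈0.44 ppm)
are not exactly proportional, so they cannot both be closed ppm intervals
on one uniform grid; anchoring the TG window at the 1.4 ppm grid point and
taking the CH window as its upfield tail reproduces both counts exactly and
keeps CH ⊂ TG. Whether these windows are closed or half-open intervals on
the processed grid is not determined by the source material; this is the
convention adopted here. Chemical-shift registration uses the standard
serum anchor, the left line of the alanine doublet at 1.49 ppm, via an
integer-point circular shift (no interpolation — the simplest scheme
consistent with automatic alignment, and exactly invertible, which the
round-trip tests exploit). The default search half-width (0.008 ppm) stays
below the doublet splitting so the right-hand line can never capture the
maximum.

Concentrations are held in a samples × (class, species) table in mg/dL or
mmol/L; conversion uses the molar masses 385 g/mol (CH) and 884 g/mol (TG),
`mmol/L = mg/dL × 10 / M`. The subclass registry stores the particle
diameters of the 15 modeled subclasses as published; the five subclasses
without a published diameter (LDL12, LDL13, HDL14, HDL19, HDL20) get
log-linear extrapolations within their category — each category's printed
diameters shrink by a near-constant ratio, so the log scale is the natural
one — and are flagged `interpolated`. The censored bound for CM01
("> 90 nm") is stored as a point value of 95 nm, also flagged. Totals carry
size ranges as metadata only and are never used as peak positions.

## The synthetic cohorts

`simulate_cohort()` draws per-sample subclass concentrations and renders
one spectrum per sample:

* **Concentrations** are log-normal per (subclass, species), matching each
  preset's mean and coefficient of variation, with a Gaussian copula
  giving equicorrelation 0.5 among the members of a category. Log-normal
  marginals guarantee non-negativity and the right skew that motivates the
  conditional square-root response transform.
* **Spectra** are superpositions of unit-area Lorentzian lines (HWHM
  0.012 ppm), one methyl and one methylene line per subclass, with centers
  `0.70 + 0.055·ln(d/9.8)` and `1.18 + 0.040·ln(d/9.8)` ppm for diameter
  `d` in nm. CH contributes 85% of its signal area to the methyl line and
  15% to the methylene; TG splits 40/60. This concentrates the CH
  information in the methyl-only CH window, which is why the CH models can
  be restricted to it. Constant baseline, additive Gaussian noise
  (default SD 1, against peak heights of order 10^2^–10^3^ — high-SNR
  serum NMR), and a small alanine doublet at 1.49/1.478 ppm for alignment
  complete the forward model.

Two presets define the cohort phenotypes. `low_hdl_cm` has its means
anchored to the published placebo least-squares means of the low-HDL
theobromine cohort (converted to mg/dL): chylomicrons present,
triglyceride-rich large VLDL, low cholesterol in the large HDL subclasses.
`hyperchol` encodes the contrasting hypercholesterolemic phenotype:
essentially no chylomicrons, lower TG in large VLDL, higher cholesterol in
HDL15–17. Subclasses without published values and the coefficients of
variation (0.45 CM, 0.35 VLDL, 0.25 LDL, 0.20 HDL) were fixed once at
values typical for fasting serum lipid panels; they are simulator inputs,
not estimates. The presets are constrained only qualitatively by the
published phenotype contrast, and the shipped CSV
(`inst/extdata/phenotype_presets.csv`) is meant to be edited.

What the simulator deliberately omits: the full small-molecule serum
background (sugars, amino acids beyond the alanine anchor), phase/baseline
artifacts, between-category concentration correlations, and any
non-linearity between concentration and signal. Passing tests therefore
demonstrate that the pipeline's statistics and wiring are correct under a
faithful linear forward model — not that the calibration would achieve the
same figures of merit on real serum.

## The calibration engine

For each of the 48 (class, species) pairs (24 classes × TG/CH):

1. **Split.** The cohort is split once by the Kennard–Stone max–min
   algorithm on the TG window (default 80 training / 42 test for n = 122).
   Ties break to the lowest sample index, making the split deterministic.
2. **Transform.** If the training response has absolute sample skewness
   above 1.0, the model is fitted to √y and predictions are squared back
   (negative square-root-scale predictions clipped to zero; no
   retransformation bias correction).
3. **Model.** Mean-centered NIPALS PLS-1. The number of latent variables
   (search range 1–15) is chosen by 10-fold cross-validation with a
   parsimony rule: the smallest count whose CV-RMSE is within 2% of the
   minimum. The searched range is wider than the 5–12 typically selected,
   and the parsimony rule makes the choice deterministic.
4. **Significance.** A response-permutation test: the observed statistic
   is the 10-fold CV-Q², the null statistics are the same quantity with
   the response freshly permuted each of B repetitions (same folds, same
   latent-variable count). The add-one estimator
   p = (#{null ≥ observed}+1)/(B+1) means that at B = 1000 the p < 0.001
   threshold is reached only by beating every permutation. Folds are fixed
   per model and permutations are fresh per repetition.
5. **Validation.** Q² = 1 − PRESS/TSS, RMSE, CV% = 100·RMSE/mean(y), and
   Pearson R, on the original mg/dL scale; training-set figures come from
   the cross-validated predictions, not refit residuals. These are the
   standard chemometric definitions, adopted because the source deferred
   the formulas to earlier work.

Numerical choices worth noting: the per-fold training block is rotated
into its row space by a thin SVD before PLS fitting — scores and
predictions depend on X only through that basis, so the result is exact
while every permutation refit becomes an n × n problem instead of
n × 1746; component extraction stops (and `fit_pls` rejects the request)
when the deflated cross-covariance norm falls below 10^−12^ of its initial
scale, which is what "exceeding the rank" means operationally; predictions
outside a model's training concentration range are flagged rather than
clipped, since the calibration is only claimed valid inside that range.

## Cross-cohort bias

Applying a panel trained on one phenotype to spectra from the other is the
package's built-in failure-mode demonstration. `cross_predict()` plus
`bias_report()` summarise, per model, the mean signed error, the
predicted-vs-observed regression line, and the fraction of out-of-range
predictions. With a chylomicron-free training cohort, the CM resonances in
low-HDL-phenotype spectra project onto whatever the foreign model's
coefficients happen to do in that region; in the shipped configuration the
large-VLDL cholesterol predictions come out systematically underestimated,
and crossed-cohort bias magnitudes exceed the matched-cohort baseline for
the large majority of modeled classes. Bias is summarised in mg/dL rather
than relative error so zero-concentration classes stay well defined. No
correction or calibration transfer is attempted — the point is the sanity
check, not a fix.

## The crossover treatment analysis

`simulate_crossover_study()` generates a balanced two-period crossover
(baselines D1/D57, post-treatment visits D25/D28 and D81/D84) with a
log-scale subject random effect (SD 0.15), log-scale visit noise
(SD 0.05), and a configurable multiplicative treatment effect per outcome.
`treatment_effects()` then:

* screens for outliers by Hotelling-T² on the first two PCA components of
  the unit-variance-scaled profile matrix (99% F-limit), escalating to
  whole-subject exclusion when more than half of a subject's samples are
  flagged;
* fits, per outcome, a REML linear mixed model with fixed effects
  treatment, same-period baseline, gender, age, BMI and visit, and random
  intercepts for subject and for period within subject. The nested term is
  a deliberate addition to the bare "subjects random" structure: the
  same-period baseline covariate carries one realisation of measurement
  noise that both visits of the period share, so without a period-level
  variance component the residuals stay correlated within period and the
  standard error of the (period-level) treatment contrast is
  anticonservative — simulation puts the α = 0.05 type-I rate near 9%
  without the term and at the nominal 5% with it;
* reports least-squares means (continuous covariates at their means,
  categorical factors at balanced margins), the percent difference
  100·(active − placebo)/placebo, and the Satterthwaite two-sided
  treatment p-value.

"Baseline" enters as the subject's same-period pre-treatment concentration,
a continuous covariate (an ANCOVA reading): the published tables describe
the means as *corrected for* baseline, which implies covariate adjustment
rather than a two-level day factor. Visits are a fixed two-level factor;
age and BMI are taken once per subject; outcomes are analysed
untransformed; and no multiplicity adjustment is applied across the 36
outcomes, matching per-outcome reporting at p < 0.05. With only two arms
the Dunnett-type post-hoc adjustment is the identity; `dunnett_p()`
implements the general equicoordinate multivariate-t version so the
operation generalises to several active arms. A singular mixed fit falls
back to a subject-fixed-effects model with a warning (the subject-constant
covariates then drop out).

On the simulator's terms the estimator is essentially unbiased: injected
−5% and +10% effects are recovered to well under one percentage point when
averaged over replicate studies of 40 subjects, and the null type-I rate
at α = 0.05 sits inside its binomial band — both are asserted by the test
suite at exactly those settings. The percent-difference arithmetic itself
is pinned to the published table values (−5.24% for total-LDL CH, −5.48%
for LDL09 CH).

## Problem sizes and defaults

The shipped defaults mirror the study conditions: cohorts of n = 122 split
80/42, 10 CV folds, B = 1000 permutations at α = 0.001, latent variables
searched over 1–15, crossover studies of 40 subjects. The test suite and
the acceptance script run the same code at reduced Monte-Carlo depth
(B = 99–199 permutations; 24–200 replicate studies; cohorts of 30–122) —
these sizes are the package's chosen trade-off between statistical
resolution and turnaround, and each test states its own. Note that at
B = 199 the permutation floor 1/200 cannot clear α = 0.001; significance
flags at the published threshold require B ≥ 999.

## Known limitations

* The simulator's phenotype presets are qualitative stand-ins; absolute
  figures of merit (Q², RMSE) on synthetic cohorts say nothing about real
  serum performance.
* The summation identity "category total = sum of member subclasses" is
  enforced only for simulator-produced tables; for reference-assay data
  the totals may be calibrated independently, and the package does not
  assume either way.
* PLS predictions shrink toward the training mean, so small per-class
  biases remain even in matched-cohort application; tests bound them
  rather than assert exact zero.
* Alignment is integer-point circular shifting; sub-point shifts and
  lineshape changes are out of scope, as are phase/baseline correction and
  any treatment of the water region.
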
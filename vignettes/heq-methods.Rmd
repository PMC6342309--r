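---
title: "Homology-based emphysema quantification and lung-cancer risk models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based emphysema quantification and lung-cancer risk models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heqct)
```

## The problem

Densitometric emphysema indices such as the low-attenuation area
percentage (LAA%) summarize *how much* of the lung falls below an
attenuation threshold, but they are blind to *how* that low-attenuation
tissue is arranged. Topological descriptors fill that gap: if the
thresholded low-attenuation set of a 2-D CT slice is treated as a binary
image, its zeroth and first Betti numbers count, respectively, the
number of low-attenuation regions (`b0`) and the number of normal-lung
islands completely surrounded by low-attenuation tissue (`b1`). This
package implements that homology-based emphysema quantification (HEQ)
and the downstream question it was designed for: after adjusting for
age, sex and smoking history, is the topological descriptor associated
with lung-cancer risk in patients under nodule workup, and does it
discriminate better than LAA%?

## Quantification pipeline

For each patient, three axial slices representing the upper, middle and
lower lung fields are analyzed. Slice selection is deliberately simple
and mask-driven: the cranio-caudal extent of the lung is the run from
the first to the last slice containing any lung-mask pixel, and slices
are taken at fractional positions (default 0.25, 0.50, 0.75, exposed in
`run_config()` and `select_slices()`) of that extent, rounded to the
nearest index. Anatomic-landmark-based selection would need structures
the pipeline does not model; the fractional rule is deterministic and
reproducible from the mask alone.

Each selected slice is binarized at the analysis thresholds −950, −910
and −880 HU: a pixel maps to 0 (low attenuation) iff it lies inside the
lung mask *and* its attenuation is strictly below the threshold; ties
and everything else (normal lung, outside lung) map to 1. The strict
inequality means a pixel exactly at the threshold counts as normal
lung. Pooling the three slices,

LAA% = 100 × (Σ low-attenuation lung pixels) / (Σ lung pixels).

The per-patient Betti numbers are the sums of the per-slice values, by
parallel construction with the pooled LAA% definition. (A stacked
composite would give the same numbers: regions on different slices can
never touch in a per-slice 2-D computation.) Per-slice values are
retained in the `per_slice` field for diagnostics.

## Topology engine

`b0` is the number of connected components of the 0 set under
8-connectivity; `b1` is the number of 4-connected components of the 1
set that do not touch the image border. Because every outside-lung
pixel is 1 and connects to the border, enclosed islands can only be
normal-lung pixels ringed by low-attenuation tissue, so the mask is not
needed at topology time. The (8, 4) foreground/background pairing is
the standard digital-topology dual under which the Euler identity
`b0 − b1 = χ` holds without exception; χ is computed independently by
cell counting on the cubical complex of the 0 set (vertices − edges +
faces of the closed unit squares). The pairing is a configuration knob
(`connectivity = c(4, 8)` swaps it) because the opposite convention is
also used in the literature; the package default is (8, 4). Labelling
is a compiled union-find pass; the test suite checks it against an
independently written breadth-first flood fill on hundreds of random
grids and against `EBImage::bwlabel` (which is 4-connected) for the
component counts.

Degenerate inputs are defined, not special-cased: an empty 0 set has
`b0 = b1 = 0` and `χ = 0`, and `b1 = 0` whenever `b0 = 0`.

## Statistical pipeline

Univariate screening compares each variable between cancer and benign
groups: Welch's unequal-variance *t*-test for continuous variables
(Student's is a switch, `var_equal = TRUE`, since either could have
produced a published screening table) and the chi-squared test with
Yates continuity correction for the 2×2 tables (sex, malignant tumor
history). No multiplicity correction is applied, matching the screening
role of the table. The analysis threshold is the one minimizing the b1
p-value, with ties broken by the smaller LAA% p-value and then by the
higher HU threshold.

Four logistic models are fitted by maximum likelihood (IRLS via
`stats::glm`, log-likelihood tolerance 1e−8, at most 50 iterations):
*base* (male sex, age, Brinkman index), *laa* (base + LAA% at the
selected threshold), *heq* (base + b1 at the selected threshold), and
*heq_b* (base + b1 binarized at the empirical cutoff 5100, strict
`> 5100`). Sex enters as the male indicator so the male coefficient is
interpretable directly; covariates are never standardized, so the
Brinkman and b1 coefficients live on their natural per-unit scales
(~1e−4). Wald standard errors, p-values and AIC are reported, and
converged fits that push probabilities to numerical 0/1 are rejected as
(quasi-)separated rather than reported with meaningless standard
errors. The 5100 cutoff is a configuration default; no cutoff search is
run in reproduction analyses because the cutoff is taken as given.

AUC uses the Mann–Whitney estimator with ties counted one half
(midranks), which equals exhaustive case–control pair counting exactly.
Correlated AUCs are compared with DeLong's test implemented from
placement values; the implementation exposes the 2×2 covariance of the
two AUCs and is cross-checked in the tests against `pROC::roc.test`
and, for the single-AUC variance, against a bootstrap. Cross-validation
is stratified by outcome, k = 10 by default, driven entirely by the
configured seed; the pooled out-of-fold probabilities give one
patient-level prediction each, so a single cross-validated ROC exists
and DeLong's test can be applied to cross-validated models. The
original study's fold assignments are unknowable, so only stochastic
agreement (across seeds) with published cross-validated AUCs can ever
be expected.

## Synthetic data: what it emulates and what it does not

The phantom generator plants ground truth by construction: a two-ellipse
lung mask, `k` low-attenuation regions per slice of which `m` are
annuli enclosing a normal-parenchyma core, pairwise separated by at
least one normal pixel (8-neighbour sense), Gaussian i.i.d. HU noise
around −780 (parenchyma) and −980 (holes) with sd 15. Both means sit
~6.7 sd from the −880 HU construction threshold (a ≥3 sd margin is
enforced at spec validation), so thresholding recovers the planted
geometry with overwhelming probability; recovery is *asserted* after
generation — the binarized slice must equal the planted set exactly and
its Betti numbers must equal (k, m) — and a failing slice is
regenerated and counted. Annuli are used for enclosed islands because
they make the `b1` ground truth exact rather than estimated. Grids are
96×96 with 0.7 mm pixels, a deliberate scale-down of 512×512 clinical
slices that preserves every topological and densitometric property the
tests assert.

The cohort generator draws age from a clamped normal (66.8 ± 12.4 y),
sex as a margin (317/576 male in the surrogate) or Bernoulli, Brinkman
index from a zero-inflated log-normal (35% never-smokers; log-normal
parameters chosen to give mean ≈ 647 and sd ≈ 829), and the emphysema
metrics from a single latent severity factor with per-metric loadings
(b1 loadings 0.6–0.8, b0 at higher thresholds negative, LAA% 0.45).
The three LAA% columns share one disturbance, which makes per-patient
monotonicity across −950/−910/−880 HU hold by construction. The outcome
is Bernoulli with logit linear in male sex (−0.438), age (0.0260/y),
Brinkman index (2.94e−4) and b1 at −880 HU (1.04e−4) — coefficient
scales of published unstandardized fits in this setting — with the
intercept calibrated by root-finding so the expected prevalence is
283/576.

What passing tests on these synthetics do **not** show: real CT texture
(noise is i.i.d. Gaussian; no reconstruction kernel, dose, or spatial
correlation effects), real joint dependence between thresholds and
between LAA% and b1 beyond a one-factor structure, and heavy tails or
mixture structure in the b1 distribution. In particular, the
surrogate's binarized-b1 model is *not* separately calibrated: under a
one-factor Gaussian b1, the implied binarized coefficient is smaller
than a continuous-model-equivalent real cohort can produce, so
surrogate odds ratios for the binarized term are expected to undershoot
values estimated on real data. Conclusions about real cohorts require
the real per-patient table, which the reproduction pipeline ingests
unchanged (`read_cohort()` with a `column_map` for arbitrary source
headers, then `run_reproduction()`).

## Numerical choices and degenerate inputs

* Strict `<` at the HU threshold and strict `>` at the b1 cutoff; both
  boundary values go to the reference class.
* Slice indices are 1-based (R convention) throughout; slice order is
  cranio-caudal ascending.
* HU values outside [−1100, 3100] are rejected at ingestion rather than
  clamped; DICOM rescale handling is delegated to the NIfTI reader's
  scl_slope/scl_inter support (DICOM series themselves are out of scope
  of this build and raise a clear format error).
* Rows missing a modelling covariate (typically the Brinkman index) are
  flagged at ingestion and excluded at fit time with a logged count,
  never silently dropped at read time.
* A variable constant in both outcome groups screens at p = 1 with a
  degenerate flag instead of erroring.
* DeLong's test with zero variance of the AUC difference (e.g. a model
  compared with itself) returns z = 0, p = 1 by definition.
* Fold assignment, and only fold assignment, consumes the configured
  seed during `run_reproduction()`; identical cohort + config give
  bitwise-identical reports.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at sizes chosen to
exercise every property at desk scale: random topology grids up to
64×64 (200 grids against the flood-fill oracle), the phantom matrix
k = 0..10 × m = 0..min(k, 5), cohorts of 576 (surrogate analyses) to
50,000 (the bi-normal AUC identity, where the closed form
Φ(β/√2) needs large-sample bias to vanish), and 1000 null replicates
for the DeLong type-I-error calibration. These sizes are the package's
own trade-off between statistical resolution and a test suite that
stays pleasant to run.

## Known limitations

Strictly three 2-D slices at three fixed thresholds: no persistent
homology across a continuous filtration, no 3-D (26-connectivity)
homology, no whole-volume quantification mode. Lung segmentation is an
input, not a capability. No kernel/dose harmonization. The screening
table is uncorrected for multiplicity by design. The surrogate cohort
supports engineering validation and scale-faithful demonstration, not
clinical inference.
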
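# heqct — homology-based emphysema quantification and lung-cancer risk models

`heqct` quantifies pulmonary emphysema on chest CT two ways and asks
whether either predicts lung-cancer status in patients under nodule
workup:

* **LAA%** — the classical densitometric index: the percentage of lung
  pixels with attenuation strictly below a Hounsfield-unit threshold
  (−950, −910, −880 HU), pooled over three axial slices (upper, middle,
  lower lung fields).
* **HEQ** — a topological descriptor of the same binarized images. With
  the convention 0 = low-attenuation lung pixel, 1 = normal lung or
  outside lung, the Betti numbers of the 0 set are
  *b*₀ = number of low-attenuation regions (8-connected components) and
  *b*₁ = number of normal-lung islands completely surrounded by
  low-attenuation tissue (4-connected components of the 1 set not
  touching the border). The package computes them exactly and verifies
  the Euler identity *b*₀ − *b*₁ = χ against an independent
  cell-counting computation of the Euler characteristic.

Downstream, four logistic models of cancer vs benign outcome are
fitted and compared: **base** (male sex, age, Brinkman smoking index),
**laa** (base + LAA%), **heq** (base + *b*₁), and **heq_b** (base +
*b*₁ binarized at 5100). Model comparison uses AIC, ROC/AUC
(Mann–Whitney estimator), DeLong's test for correlated AUCs, stratified
10-fold cross-validation with pooled out-of-fold predictions, and the
odds ratio of the binarized *b*₁ term. A synthetic-data module supplies
lung phantoms with planted topology and cohorts with a known generative
model, so the whole pipeline is testable end to end without clinical
data.

Intended users: quantitative-imaging and clinical-epidemiology
researchers who want a tested, fully reproducible reference
implementation of topology-based emphysema scoring and its risk-model
evaluation.

## Worked example

Quantify a synthetic phantom whose topology is known by construction
(5 low-attenuation regions per slice, 2 of them annuli enclosing a
normal island):

```r
library(heqct)
ph <- generate_phantom(phantom_spec(n_components = 5, n_enclosed = 2, seed = 7))
quantify_patient(ph$volume, ph$masks)
#> <emphysema_metrics: slices 1/2/3, lung area 4342 mm^2>
#>   threshold_hu laa_pct b0 b1
#> 1         -950    5.57 15  8
#> 2         -910    5.70 15  6
#> 3         -880    5.70 15  6
```

At the construction threshold (−880 HU) the recovered per-patient Betti
numbers are exactly 3 × 5 = 15 components and 3 × 2 = 6 enclosed
islands (three slices summed), and LAA% equals the planted
low-attenuation fraction. At −950 HU the noisier hole interiors split
off two extra enclosed islands — the kind of threshold sensitivity the
three-threshold screening is designed to expose.

Run the complete risk-model analysis on the synthetic surrogate cohort
(576 patients, published covariate scales, outcome generated from the
HEQ-model coefficients):

```r
co  <- surrogate_study_cohort(seed = 1)
rep <- run_reproduction(co, run_config(seed = 1))
rep
#> Cohort: 576 patients (317 male), 277 cancer / 299 benign
#> Analysis threshold: -880 HU
#>
#> Models (apparent / cross-validated AUC, AIC):
#>   base   AUC 0.616 / 0.605   AIC 779.7
#>   laa    AUC 0.618 / 0.604   AIC 780.3
#>   heq    AUC 0.636 / 0.619   AIC 773.7
#>   heq_b  AUC 0.618 / 0.604   AIC 778.9
#>
#> DeLong comparisons (apparent):
#>   base vs laa: p = 0.8416
#>   base vs heq: p = 0.1142
#>   laa vs heq: p = 0.1261
#>   heq vs heq_b: p = 0.06698
#>
#> Cross-validated laa vs heq: p = 0.2217
#> Odds ratio, binarized b1: 1.47 (0.93-2.32)
```

Reading the output: screening selects −880 HU (smallest *b*₁ p-value);
the heq model has the lowest AIC of the three continuous-covariate
models and the best apparent and cross-validated AUC, i.e. the planted
topological signal is recovered over and above age, sex and smoking.
Cross-validated AUCs sit below their apparent counterparts, as they
should.

The same analysis as a stepwise workflow lives under `analysis/`
(`01_phantoms.R`, `02_cohort.R`, `03_risk_models.R`), each step writing
its tables under `results/`.

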
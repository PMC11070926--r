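# ionrbe

Dose–response and RBE inference for ion-beam radiobiology experiments with
a censored binary endpoint, plus amorphous-track RBE prediction models.

The package targets the analysis chain of preclinical normal-tissue studies
in which groups of animals (classically the rat cervical spinal cord)
receive graded single or split doses of an ion beam at several positions of
a spread-out Bragg peak (SOBP), are followed for a fixed horizon (300 days)
for a binary endpoint (paresis grade II), and the effectiveness of the beam
is quantified against a photon reference. It is aimed at medical physicists
and biostatisticians who need the full chain — from animal-level records to
model benchmark tables — reproducible and testable without animal data.

## What it computes

* **Actuarial response rates** — product-limit estimate of endpoint
  incidence by the horizon per dose group, Greenwood variance, and the
  *effective sample size* `n_eff = p(1-p)/Var(p)` that lets censored groups
  enter a binomial likelihood as fractional counts.
* **Logistic dose–response** — ML fit of `p(D) = 1/(1+exp(-(b0+b1 D)))` on
  effective counts; `ED50 = -b0/b1` with delta-method SE, **Fieller 90 %
  confidence limits**, and the 25 %-of-dose-gap fallback SE when the fit
  separates.
* **LQ / BED generalized regression** — joint logistic fit in the
  biologically effective dose `BED = D (1 + d/(α/β))` across fractionation
  schedules with α/β free (log-scale), yielding BED50, α/β, and
  `RBE_max = BED50_photon / BED50_ion`, the RBE in the zero-dose limit.
  A closed-form α/β from a single/split ED50 pair is included:
  `α/β = (ED1² − ED2²/2)/(ED2 − ED1)`.
* **RBE with error propagation** — `RBE = ED50_photon/ED50_ion`, SE from
  independent relative variances, Fieller or normal CLs; weighted quadratic
  RBE–LET trends and LQ-based RBE vs dose-per-fraction curves.
* **Track models** — LEM I in the published low-dose single-track
  approximation (amorphous 1/r² track, photon local-effect curve with
  threshold `D_t`) and the modified MKM (Kiefer–Chatterjee track,
  saturation-corrected dose-mean specific energy `z*₁D`), with mixed-field
  averaging and a predicted-vs-measured deviation table.
* **Synthetic cohorts** — a generator reproducing the published study
  design (four LET positions 26/66/98/141 keV/µm, 5 animals per dose
  level, single and split schedules, 10 controls, 280 animals, log-normal
  latencies, exponential intercurrent censoring) from a configurable
  logistic/BED truth, so every stage is testable offline.

## Worked example

```r
library(ionrbe)

# published split-dose summaries: photon 34.3 +/- 0.7 Gy, oxygen
# 21.7 +/- 0.4 Gy at 26 keV/um
rbe_ratio(list(ed50 = 34.3, se = 0.7), list(ed50 = 21.7, se = 0.4))
#> RBE = 1.581 +/- 0.043 (90% CL 1.511 - 1.654, fieller)

alpha_beta_from_ed50_pair(17.2, 21.7)   # iso-effect pair solve, Gy
#> [1] 13.42111
bed(13.5, 1, 29.5)                      # BED50 at 98 keV/um, Gy
#> [1] 19.67797
```

The RBE of 1.58 means the photon dose must be 58 % higher than the oxygen
dose for the same 50 % paresis risk; the α/β of 13.4 Gy says the cord's
sensitivity to fractionation is much weaker under oxygen ions than under
photons (2.8 Gy), and BED50 places the 50 % point on the common LQ effect
scale.

End-to-end on a synthetic cohort drawn from the published truth:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$ed50_table[res$ed50_table$n_fractions == 2, c(1, 3, 4, 8:11)]
#>  let_value   ed50 ed50_se   rbe rbe_se cl_low cl_high
#>         26 22.359   0.374 1.534  0.040  1.469   1.602
#>         66 17.071   0.442 2.009  0.066  1.904   2.122
#>         98 15.403   0.333 2.227  0.066  2.121   2.339
#>        141 17.184   0.363 1.996  0.059  1.902   2.095
```

compared with the published 21.7/17.0/15.5/17.2 Gy and RBE
1.58/2.01/2.21/1.99 — the simulated chain reproduces the study's
statistical structure at its actual group sizes.

A minimal CLI wraps the same steps
(`inst/cli/ionrbe simulate|fit-dr|fit-lq|rbe|predict|report`).

## Documentation

`vignettes/rbe-inference.Rmd` describes the statistical model, the track
models, every stated-world simulation default, numerical choices, and the
known limitations (including why the low-dose LEM I approximation cannot
show an overkill turnover below 200 keV/µm).
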
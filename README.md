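# PatternSeverity

Quantitative severity assessment for a two-factor traditional Chinese
medicine (TCM) pattern — liver stagnation with spleen deficiency — in
diarrhea-predominant irritable bowel syndrome, from a 9-item polytomous
symptom questionnaire. The package is aimed at psychometricians and
clinical-epidemiology researchers validating short patient-reported scales
whose items are driven by more than one correlated latent severity.

## The model

Respondent severities are a latent vector `θ = (θ₁, θ₂)` (liver-stagnation
and spleen-deficiency factors) with a standard bivariate normal prior and a
free correlation ρ. Each item j has four ordered categories (0 = none … 3 =
serious). Under the multidimensional graded response model (MGRM) the
probability of answering category *t or above* is

    P*_jt(θ) = F(a_j · θ + d_jt),      t = 1..3,   d_j1 > d_j2 > d_j3,

with `F` the standard normal (probit, the default) or logistic CDF,
`a_j` the item's discrimination vector (zero entries fixed by the
simple-structure loading pattern: items 1–5 load only on factor 1,
items 6–9 only on factor 2), and `d_jt` the boundary ("easiness")
parameters. Exact-category probabilities are the telescoping differences
`P_jt = P*_jt − P*_j,t+1`. The package provides:

* **mgrm core** — category/boundary probabilities, the multidimensional
  discrimination index `MDISC_j = ‖a_j‖₂`, directional Fisher information,
  item/test information grids, ICC traces, and EAP severity scores;
* **estimation** — marginal maximum likelihood by EM with tensor
  Gauss–Hermite (deterministic default) or quasi-Monte-Carlo integration,
  confirmatory simple-structure constraints, a free latent correlation, and
  multi-start protection against the multimodality induced by sparse extreme
  categories;
* **CFA** — maximum-likelihood confirmatory factor analysis of the
  unidimensional vs two-factor structure with χ²/df/p, CFI,
  `RMSEA = √(max(χ²−df,0)/(df(N−1)))`, and `AIC = χ² + 2q`;
* **classical statistics** — Cronbach's α with item diagnostics and a
  demographics percentage table;
* **synthetic data** — seeded generator of respondent cohorts from the
  packaged item bank (the scale's fitted parameters ship as a plain-text
  fixture in `inst/extdata/lssd_bank.txt`), so the entire pipeline is
  testable without clinical data.

## Worked example

```r
library(PatternSeverity)

bank <- lssdBank()                       # packaged 9-item two-factor bank
round(mdisc(bank), 2)
#>   i1   i2   i3   i4   i5   i6   i7   i8   i9
#> 2.03 2.19 1.29 0.84 1.12 2.21 1.48 0.94 0.98

sim <- simulateStudy(n = 344, seed = 2)  # synthetic cohort at the study size
rep <- runReport(sim@responses, bank, outputDir = "out")
```

`out/report.txt` then reads (abridged):

```
Reliability: Cronbach's alpha = 0.782 (9 items, 344 complete cases)

Confirmatory factor analysis (ML), N = 344
index          one-factor   two-factor
chi^2              248.15        59.88
df                     27           26
CFI                  0.76         0.96
RMSEA                0.15         0.06
AIC                302.15       115.88

Graded response model (probit link): converged after 64 EM iterations (tol 1.0e-04)
  marginal logLik = -1572.540, latent correlation = 0.484
 item loading1 loading2    a1    a2     d1     d2     d3 MDISC
   i1    0.653    0.000 2.284 0.000 -0.141 -2.604 -5.408 2.284
   ...
```

Reading it: α ≈ 0.78 says the nine items are internally consistent as a
scale; the two-factor CFA clearly beats the unidimensional one on every
index (the generating structure *is* two-factor); the EM fit recovers the
generating slopes (item 1's true a₁ = 2.03) and latent correlation
(truth 0.5); `NA` boundaries mark categories never observed in this cohort,
which the fitter collapses and records. `out/test_information.csv` holds the
test-information surface over the severity plane and
`out/icc_curves.csv` the per-item category traces.

A command-line front end with `simulate`, `ctt`, `fit-cfa`, `fit-mirt`,
`score` and `report` subcommands is installed at
`system.file("scripts", "pattern-tool.R", package = "PatternSeverity")`.

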
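---
title: "Measuring a two-factor symptom pattern: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring a two-factor symptom pattern: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatternSeverity)
```

## The measurement problem

A nine-item interview scale grades the severity of the liver-stagnation /
spleen-deficiency pattern in diarrhea-predominant irritable bowel syndrome.
Every item has four ordered categories (0 none, 1 mild, 2 middle, 3
serious). Five items describe mental/emotional symptoms (irritability,
depression, discomfort aggravated by mental disorders, contracture
sensation, sighing) and four describe abdominal symptoms (rumbling, flatus,
anorexia, relief after defecation). The working theory holds that two
correlated latent severities drive these blocks, so a unidimensional sum
score is structurally wrong and classical test theory alone cannot calibrate
the items. The package therefore combines three layers:

1. **Classical statistics** (Cronbach's alpha, demographics tables) for
   scale-level reliability and sample description.
2. **Confirmatory factor analysis** to adjudicate one- versus two-factor
   structure on the score covariance matrix.
3. **A multidimensional graded response model (MGRM)** for item calibration
   and per-respondent severity scoring on the two-factor structure.

## The graded response model

For item $j$ with boundaries $d_{j1} > \dots > d_{jm_j}$ and discrimination
vector $a_j$, the probability of endorsing category $t$ *or above* at
severity $\theta \in \mathbb{R}^2$ is $P^*_{jt}(\theta) = F(a_j^\top\theta +
d_{jt})$, with $P^*_{j0} \equiv 1$, $P^*_{j,m_j+1} \equiv 0$, and exact
categories $P_{jt} = P^*_{jt} - P^*_{j,t+1}$. Both links are supported: the
probit (normal-ogive) form is the default, matching the integral form of the
model statement; the printed parameter metric of the source software family
is ambiguous between probit and logistic, so the link is recorded in every
object and is switchable everywhere (`lssdBank("logistic")` re-reads the
same numbers on the logistic metric). The latent prior is
$N(0, \Sigma(\rho))$ with unit variances — this fixes the scale and location
of $\theta$, so all discriminations are identified free parameters and no
marker item is needed.

Summaries derived from the model:

* **MDISC** $= \lVert a_j\rVert_2$, the overall discriminating power of an
  item; above 1 counts as high quality, 0.5–1 as medium. Under the scale's
  simple structure it equals the single nonzero slope.
* **Directional information** $I_j(\theta, u) = (a_j^\top u)^2 \sum_t
  (f(z_{jt}) - f(z_{j,t+1}))^2 / P_{jt}$ for a unit vector $u$; per item the
  default direction is its own loading axis. Test information is the sum of
  item informations, exported on a rectangular $\theta$ grid (default
  $[-4, 4]$ per axis, step 0.1 — both configurable; information surfaces of
  strongly skewed banks can extend their hump beyond $+4$, so the range is a
  knob, not a constant).
* **ICC traces** along an item's own factor with the other coordinate at the
  prior mean 0 (the natural reference point; nothing in the data fixes any
  other choice).
* **EAP scores**: posterior mean and SD of $\theta$ under the fitted bank,
  computed on the same quadrature rule as estimation. Missing responses drop
  their likelihood term; an all-missing record returns the prior mean and SD,
  flagged.

Degenerate all-zero-discrimination items are representable (simulation
studies need null items) but are rejected by `mdisc()` and `iccCurves()`,
and contribute zero information.

## Estimation

`fitMgrm()` maximizes the marginal likelihood by EM.

**E-step.** Integration uses a tensor Gauss–Hermite rule, 21 nodes per
dimension by default (441 nodes for two factors) — deterministic, so fits
and reports are bit-reproducible. A quasi-Monte-Carlo rule (radical-inverse
Halton-type sequence with a seeded random shift, 2000 points by default)
is available as an alternative for higher dimensions. A correlated prior is
handled by mapping the standard-normal nodes through the Cholesky factor of
$\Sigma(\rho)$, which preserves the full polynomial accuracy of the rule at
any $\rho$. (Reweighting fixed nodes by the density ratio — the obvious
alternative — loses about two orders of magnitude of accuracy by $\rho =
0.5$ because the ratio grows exponentially at corner nodes; the package does
not use it.)

**M-step, items.** Each item's expected complete-data log-likelihood is
maximized over its free slope and all boundaries by bounded quasi-Newton
(L-BFGS-B, box $\pm 25$) with the analytic gradient, falling back to an
unbounded BFGS run (clamped into the box) if the bounded search stalls.
Category probabilities inside the M-step are floored at $10^{-10}$: far
below anything data can distinguish, but essential numerically — without a
floor at this level, categories whose mass underflows produce gradients of
order $10^{250}$ that silently stall the line search. Boundary ordering is
checked after each update and re-sorted with a warning if violated (a
rounding-level event); estimates pinned at the box, and categories with
near-zero expected counts, are flagged in the fit.

**M-step, correlation.** With two factors, $\rho$ is updated by
one-dimensional maximization of the unit-variance Gaussian expected
log-likelihood at the pooled posterior second moment — the exact constrained
M-step, which keeps the EM ascent property that the package also tests
(log-likelihood never decreases by more than $10^{-6}$ per iteration with
the deterministic rule). For more than two factors the pooled moment is
rescaled to a correlation matrix (nearest-positive-definite repair with a
warning if needed). The correlation is estimated by default and can be fixed.

**Starting values and multimodality.** The marginal likelihood of graded
models with very negative boundaries (rare extreme categories) is genuinely
multimodal: EM runs from different starts reach different stationary points
whose log-likelihoods differ by tens of units. The package therefore runs
EM from (a) item-specific starts — boundaries from the inverse link of the
marginal cumulative category proportions, slopes from a quick linear CFA of
the score covariance mapped through $a = \lambda/\sqrt{1-\lambda^2}$ — and
(b) a flat neutral start (all free slopes 1), keeping the run with the best
final log-likelihood. `startScales` adds rescaled-slope restarts if desired;
`startAtBank = TRUE` bypasses all of this for self-consistency experiments.
A flat-start-only design was tried first and abandoned: on skewed data it
reproducibly converges to a basin tens of log-units below the one found from
data-driven starts.

**Convergence.** The loop stops when the largest absolute change over all
free parameters (including $\rho$) falls below `tol` (default $10^{-4}$) or
at `maxIter` (default 500; `maxIter = 0` returns the starting values,
unconverged, for pipeline testing). Iteration counts are reported, never
asserted — EM path lengths are data- and start-dependent.

**Empty categories.** The graded model is undefined for categories that are
never observed, so these are collapsed before fitting: observed categories
are relabeled consecutively, the item's boundary count shrinks, and the
remap is recorded in the result (`collapseMap`) and logged. At moderate
sample sizes the packaged bank's most extreme boundaries (around $-5$ to
$-7$ on the probit scale) correspond to per-category expectations of a
handful of respondents, so collapses are routine, not exceptional.

**Standard errors** (optional, `computeSE = TRUE`) use the
outer-product-of-scores (BHHH) approximation with per-respondent scores by
central finite differences of the individual marginal log-likelihoods —
adequate for reporting, deliberately outside the convergence loop.

**Small-sample behaviour.** At a few hundred respondents, maximum likelihood
for items whose top category is observed once or twice can legitimately
prefer near-degenerate solutions (slope inflated, boundary at the search
box). The fitter does not regularize these away — there is no prior in the
model — but flags them; readers of a flagged fit should treat that item's
parameters as unidentified at the available sample size.

## Confirmatory factor analysis

`fitCfa()` minimizes the normal-theory discrepancy $F = \log|\Sigma| +
\mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$ over free loadings (one per item,
simple structure, factor variances fixed at 1), log-parameterized residual
variances, and the factor correlation ($\tanh$-parameterized), using BFGS
with multiple starts. Conventions, chosen to match the arithmetic of the
published index table they mirror:

* $\chi^2 = (N-1)\,F_{\min}$ (the multiplier convention of the software
  family that popularized these tables; both RMSEA values round identically
  under $N$ or $N-1$, so the choice is documented rather than consequential);
* a saturated mean structure is counted in the free-parameter total $q$
  (9 intercepts + 9 loadings + 9 residuals + 1 factor correlation for the
  two-factor model: $q = 28$; 27 for the unidimensional), giving
  $df = p(p+3)/2 - q = 26$ and $27$ and $AIC = \chi^2 + 2q$ — this is the
  only $(q, df)$ accounting under which both published AIC values follow
  exactly from the published $\chi^2$ values;
* $RMSEA = \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$, CFI against the
  independence baseline ($F_{base} = \sum\log s_{ii} - \log|S|$,
  $df_{base} = p(p-1)/2$), clipped to $[0,1]$ with a warning if the baseline
  is better-defined than the model;
* input is a covariance matrix plus $N$ (two-stage), with
  `covFromResponses()` computing $S$ from listwise-complete rows treating
  categories as numeric scores. This reproduces the plain ML-on-ordinal
  practice of the original analysis; it is *not* upgraded to polychoric
  correlations, which would answer a different question.

Residual variances are floored at a small fraction of the observed variance
(Heywood protection) and flagged when pinned. Exact p-values are always
printed; significance-star conventions are left to report layers.

## Classical statistics

`cronbachAlpha()` uses listwise deletion (mirroring the exclusion of
incomplete questionnaires in the emulated design) and $N-1$ variance
denominators, with corrected item-total correlations and
alpha-if-item-deleted. Zero-variance items error by default and can be
dropped explicitly. `demographicsSummary()` renders counts as percentages at
2 decimals, round-half-up by default with a truncation mode — published
tables mix the two (one reference cell is reproducible only by truncation),
so the mode is explicit and the count-sum bookkeeping is checked and
flagged, never silently corrected.

## The synthetic-data generator

`simulateStudy()` emulates the statistical structure of the emulated
cross-sectional study: by default 344 respondents; severities drawn from the
standard bivariate normal with correlation 0.5 (the theory asserts the two
factors correlate but no value is published; 0.5 is the package's
documented, configurable stand-in — recovery tests treat it as
truth-to-recover, never as a reference value); responses drawn from the
packaged item bank (`inst/extdata/lssd_bank.txt`, the fitted discrimination
and boundary table transcribed verbatim; the blank first slope of item 9 is
fixed at 0, which the simple-structure pattern forces anyway); optional
completely-at-random missingness, present solely to exercise
listwise-deletion code paths — the emulated design excluded incomplete
questionnaires rather than imputing them. Everything is reproducible
bit-for-bit from the configuration and seed.

What the generator deliberately does **not** emulate: interviewer effects,
item-wording misinterpretation, demographic covariates, informative
missingness, or any departure from the MGRM itself. Passing recovery tests
therefore show that the estimator inverts its own generative model at the
stated sizes — they cannot show that the clinical data satisfy that model.

## Problem sizes in the test suite

The suite exercises oracle comparisons at small sizes (dense-grid
integration oracles at $n = 50$, a four-parameter grid-search oracle at
$n = 150$), distributional checks at $n$ up to $10^5$ draws, parameter
recovery at $n = 500$, $2000$ and $4000$ (one cohort each, package-default
seeds), and the model-comparison direction check on 20 replicate cohorts of
$n = 344$. These sizes were chosen as the smallest at which each property is
comfortably identified — recovery RMSEs at $n=2000$ sit well inside their
asserted bounds, and the boundary-parameter RMSE is dominated by boundaries
around $-5$ or below, whose per-cohort information is a handful of
respondents.

## Known limitations

* No priors/regularization in the MGRM: small-sample degenerate solutions
  are flagged, not prevented.
* Standard errors are BHHH approximations, not observed-information or
  sandwich estimates.
* CFA is plain ML on numeric scores; no robust (mean/variance-adjusted)
  corrections, no polychoric input, by design.
* Exploratory rotation, bifactor structures, Rasch-family models, and
  computerized adaptive testing are out of scope.
* Test–retest and alternate-form reliability are intentionally absent: the
  emulated study could not perform them, and the generator has no
  within-respondent dynamics to support them.
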
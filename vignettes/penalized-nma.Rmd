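---
title: "Penalized-likelihood network meta-analysis for rare events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized-likelihood network meta-analysis for rare events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firthnma)
```

## The model

`firthnma` analyses a connected network of `N` trials comparing `T`
treatments with a binary outcome, observed as arm-level counts: `r_ik` events
among `n_ik` participants in arm `k` of study `i`. The common-effect logistic
NMA model is

$$\operatorname{logit} p_{ik} = \alpha_i + d_k, \qquad
  r_{ik} \sim \operatorname{Bin}(n_{ik},\, p_{ik}),$$

where `alpha_i` is a per-study nuisance intercept and `d_k` the log odds
ratio of treatment `k` versus a single global reference (`d_ref = 0`). Under
consistency every pairwise contrast is a difference of basic parameters,
`d_{ab} = d_b - d_a`. Writing the model as a logistic regression with the 0/1
design matrix `Z` (one row per arm; `N` study columns then `T - 1` treatment
columns; dimensions `sum(A_i) x (N + T - 1)`) the Fisher information is
`I = Z'WZ` with `W = diag{n_ik p_ik (1 - p_ik)}`, and `Z` has full column
rank exactly when the treatment network is connected — which is why
`nma_design()` refuses disconnected networks up front.

With rare events the MLE of this model is biased away from the null and, in
the presence of zero-event arms, can be infinite (separation). The package
therefore maximizes Firth's penalized log-likelihood

$$\ell^*(\alpha, d) = \ell(\alpha, d) + \tfrac12 \log \lvert I(\alpha, d)\rvert,$$

the Jeffreys-prior penalty, which removes the leading-order bias of the MLE
and guarantees finite estimates and standard errors for every dataset —
including trials with zero events in *all* arms, which carry penalty
information and are retained by default (`drop_all_zero_studies()` exists for
sensitivity analyses). Fitted probabilities of such arms are pulled toward
1/2; in a single saturated 2x2 table the penalized fit coincides exactly with
adding 1/2 to each cell, `p = (r + 1/2)/(n + 1)`, which the unit tests assert
against a grid-search oracle.

## Estimation

`nma_fit()` runs Newton iterations on the Firth-modified score

$$U^*(\theta) = Z'\bigl(r - n \circ p + h \circ (\tfrac12 - p)\bigr),$$

where `h` is the diagonal of the weighted hat matrix
`W^{1/2} Z I^{-1} Z' W^{1/2}` — the closed form of the gradient of `l*` for
binomial-logit models. Steps are halved whenever `l*` decreases;
initialization is `theta = 0` (all fitted probabilities 1/2), which is
deterministic and sits comfortably inside the parameter space. Convergence
requires both `max |U*| < 1e-8` and `max |delta theta| < 1e-8` within 100
iterations; these defaults are stricter than any downstream tolerance and are
exposed as arguments. `log|I|` is computed from a Cholesky factor; a
factorization failure is reported as a disconnected/singular network rather
than silently regularized.

The unpenalized comparator (`method = "ml"`) delegates the optimization to
`stats::glm` on the same design. Separation is declared when the largest
absolute coefficient exceeds 15 or the information matrix's condition number
exceeds 1e12; the divergent estimates are returned *flagged*, never silently.
The two fits agree to below 1e-3 on event-rich data (the penalty is
`O(1/n)`), which the tests check on counts of 10^5.

## Confidence intervals

Wald intervals use the square roots of the diagonal of `I^{-1}` at the
optimum. Profile intervals for a contrast `d0` solve

$$2\bigl[\ell^*(\hat\alpha, \hat d) - \ell^*_{\text{profile}}(d_0)\bigr]
  = \chi^2_{1,\,0.95},$$

where the profile re-maximizes *all* other parameters with the contrast held
fixed and the penalty is recomputed from the full information matrix at every
constrained iterate. Rather than constrained-optimization machinery, the
package rotates the parameterization so the contrast of interest is a
coordinate (refitting with `t1` as reference when needed) and holds that
coordinate fixed inside the same Newton routine. Bounds are bracketed from
the Wald limits outward (doubling the bracket up to 8 times) and root-found
to 1e-6 on the deviance scale; at the returned bounds the profiled deviance
equals the chi-square quantile to that tolerance, and on large balanced data
profile and Wald limits agree to 0.01. Only two-sided equal-tailed intervals
are provided.

League tables (`nma_league()`) propagate Wald variances through
`Var(d_b - d_a) = Var(d_b) + Var(d_a) - 2 Cov`, and profile entries are
profiled directly in the rotated parameterization. All league entries are
invariant (to 1e-10) under a change of fitted reference.

## Multiplicative heterogeneity

Additive between-study heterogeneity does not combine with the Firth penalty,
which needs closed-form likelihood moments, so heterogeneity is handled
multiplicatively in a second stage: the arm variances `v_ik = n p (1-p)` are
scaled by a single overdispersion factor `phi >= 1`, estimated from the
Pearson statistic

$$P = \sum_{i,k} \frac{(r_{ik} - n_{ik}\hat p_{ik})^2}{n_{ik}\hat p_{ik}(1 - \hat p_{ik})},
\qquad \hat\phi_P = P/m, \qquad m = (T - 1) + (N - 1),$$

with a skewness correction in the denominator,
`phi_hat = max(1, phi_P / (1 + s_bar))`, where `s_bar` is the mean over arms
of `s_ik = (dv/dp)(r - n p)/v` with `dv/dp = n(1 - 2p)`. Point estimates are
untouched; every standard error is scaled by `sqrt(phi_hat)`
(`nma_inflate()`), so Wald intervals widen accordingly. Profile intervals
under inflation are not defined and not offered.

Three numerical choices deserve note. First, `m = (T-1) + (N-1)` is not the
GLM residual degree count `sum(A_i) - (N + T - 1)`; both conventions are
implemented (`df = "nma"` / `df = "glm"`), with the former the default.
Second, in sparse networks the correction term is strongly negative — every
zero-event arm contributes roughly `-n p / (p(1-p))`-scaled residuals — and
`1 + s_bar` is frequently non-positive, where the ratio form is undefined; the
package then falls back to the plain Pearson estimator `max(1, P/m)` with a
warning rather than reporting a negative dispersion. Third, `phi_hat` is
clipped at 1: underdispersion is never modelled, so the adjustment can only
widen intervals. Because `phi_hat` depends on the data only through the
fitted probabilities, it is invariant to the choice of reference treatment.

## Comparators

The simulation engine needs the classical baselines. `nma_iv()` implements
contrast-level inverse-variance NMA by generalized least squares: each study
contributes its arms' log odds ratios against the study's first arm, with the
shared-baseline within-study covariance; studies with any zero cell receive a
0.5 correction to *all four* cells of the affected table (the conventional
reading of per-study correction), and all-zero-event studies — which carry no
contrast information — are excluded and reported, with a connectivity check
after exclusion. The random-effects variant estimates a common `tau²` by the
generalized DerSimonian–Laird moment estimator on the network Q statistic,
with the consistent heterogeneity structure (`tau²` variance, `tau²/2`
within-study covariance); `tau² = 0` reproduces the common-effect fit
exactly, and on a single pairwise comparison both variants agree with
`metafor`'s fixed-effect and DL estimates to 1e-8 (asserted in tests as an
independent cross-check, not used in the implementation).

## The synthetic-data generator

`nma_simulate()` emulates randomized trial networks under controlled
conditions. Per study: one arm size is drawn uniformly on integer
`[n_min, n_max]` and shared by all arms (trials are balanced by design); a
control-group risk `p_i1` is drawn uniformly on `[risk_min, risk_max]`
regardless of whether the reference treatment is in the study; true log odds
ratios versus treatment 1 are fixed at equal spacings ending at 1
(`d_k = k/(T-1)`, e.g. 0.25/0.5/0.75/1 for five treatments); arm
probabilities follow from the control odds times `exp(d)`; events are
binomial. Under heterogeneity (`tau = 0.1`) the study-level log odds ratios
get a normal random effect with SD `tau` and pairwise correlation 1/2 across
contrasts of one study — implemented as a shared plus an idiosyncratic
`N(0, tau²/2)` component, the standard consistent random-effects structure;
the latent draws are exposed (`return_latent = TRUE`) so the calibration (SD
0.1, correlation 0.5) is directly testable. Two designs are supported:
complete two-arm grids (`studies_per_comparison` trials for every pair) and
all-arm multi-arm studies. The packaged grid (`nma_scenarios()`,
`inst/extdata/scenarios.yaml`) spans 33 configurations — 3/5/8 treatments,
small (30–60) and large (100–200) arms, 2/4/8 studies per comparison,
control risks from 0.1%–0.3% (an extreme-rarity setting built to produce
all-zero-event trials) up to 5%–10%, with and without heterogeneity. Under
the sparsest mainstream setting (scenario 1) the generator averages three
events per arm.

What the generator does *not* emulate: unequal arm sizes within a trial,
incomplete network designs, non-uniform risk distributions, and any
treatment-by-study interaction beyond the exchangeable random effect. Results
on simulated data therefore speak to estimator behaviour under a correctly
specified sparse binomial model, not to robustness against structural
misspecification.

## The evaluation harness

`nma_run_scenario()` generates replicate `j` with seed `base_seed + j`, so
any replicate is reproducible in isolation and aggregate results are
independent of execution order. Per replicate it fits the requested methods
and records basic-parameter estimates and intervals; mean bias is averaged
over contrasts within a replicate and then over replicates, and the reported
Monte-Carlo standard error is the SD of per-replicate mean bias over
`sqrt(reps)` (both aggregation orders give the same mean; the MCSE refers to
this one). A replicate where a method fails — non-convergence, flagged
separation, an error, or any standard error above 1e8 (an implausibility
screen) — is excluded for that method and counted in `n_failed`. For
penalized fits the dispersion estimate is recorded and the percentage of
replicates with `phi_hat > 1` reported.

Problem sizes used by the packaged checks were chosen to keep a full run on
one CPU in minutes while leaving Monte-Carlo error small relative to the
effects of interest: 200 replicates for bias and coverage (MCSE of mean bias
about 0.01–0.02; binomial SE of a 95% coverage estimate about 1.5 points) and
1000 replicates for the dispersion-detection frequencies (binomial SE under
1.6 points).

## Known limitations

* Additive (`tau²`) random effects inside the penalized model are out of
  scope — the penalty requires closed-form information, which the mixed
  logistic model lacks; the multiplicative adjustment is a deliberately
  cruder substitute and has limited power to detect mild heterogeneity in
  very sparse networks (in the extreme-rarity scenario it clips to 1
  essentially always).
* The skewness-corrected dispersion estimator is fragile in sparse data: the
  correction's published form scales with `n`, which drives `1 + s_bar`
  negative and triggers the plain-Pearson fallback in most sparse datasets.
  Fletcher's original mean-scale correction behaves differently (and is
  available by computing `s` on the mean scale externally), but neither
  variant is fully satisfactory below a handful of events per arm; the
  detection frequencies reported by the acceptance script should be read
  with that in mind.
* Ranking measures (SUCRA, P-scores), inconsistency diagnostics, and
  contrast-level (logOR + SE) input are not provided.
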
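---
title: "Bayesian quantile regression for child BMI: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian quantile regression for child BMI: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqrbmi)
```

## The problem

Mean regression summarizes how covariates shift the center of a child's
body mass index (BMI, weight in kg over squared height in m).  For
nutritional surveillance the tails matter more than the center: the
children at risk are those in the lowest and highest BMI quantiles.
Quantile regression models the conditional tau-quantile of the outcome
as a linear function of covariates,

$$Q_y(\tau \mid x) = x'\beta(\tau), \qquad 0 < \tau < 1,$$

so each coefficient vector describes a different stratum of the
conditional distribution.  This package fits that model in a Bayesian
way for a panel of levels (by default tau in {0.05, 0.25, 0.5, 0.75,
0.85, 0.95}), reporting posterior means with equal-tailed 95% credible
intervals and flagging a covariate as significant at a level when its
interval excludes zero.

## Working likelihood and the Gibbs sampler

The frequentist estimator minimizes the check loss
$\rho_\tau(w) = w(\tau - I(w<0))$.  Minimizing that loss is equivalent
to maximizing a likelihood in which the error follows the asymmetric
Laplace distribution (ALD) with density
$f(w) = \tau(1-\tau)\exp\{-\rho_\tau(w)\}$, whose tau-quantile sits at
zero.  We therefore use the ALD as a *working* likelihood: the
posterior concentrates around the check-loss minimizer whether or not
the data noise is truly asymmetric Laplace.

The ALD admits an exponential-normal scale mixture,
$$\varepsilon = \gamma l + h m \sqrt{l}, \qquad
  l \sim \mathrm{Exp}(1),\; m \sim N(0,1),$$
with $\gamma = (1-2\tau)/(\tau(1-\tau))$ and
$h = \sqrt{2/(\tau(1-\tau))}$.  Conditional on the latent $l_i$ the
model is Gaussian, which gives a two-block Gibbs sampler with exact
draws:

* **Coefficients** $\beta \mid y, l$ are multivariate normal with
  precision $\Omega_0^{-1} + \sum_i x_i x_i'/(h^2 l_i)$ and matching
  mean, under a multivariate normal prior
  $N(\beta_0, \Omega_0)$.
* **Latents** $l_i \mid y, \beta$ follow a generalized inverse
  Gaussian law $GIG(1/2, |y_i - x_i'\beta|/h, \sqrt{\gamma^2/h^2+2})$.

The GIG(1/2) draw is exact and rejection-free: the reciprocal of a
GIG(1/2, a, b) variable is inverse Gaussian with mean $b/a$ and shape
$b^2$, so we draw the reciprocal by the classic
transformation-with-root-selection method and invert.  Its closed-form
mean $(a/b)(1 + 1/(ab))$ anchors the distributional tests.

### Scale handling

The mixture above carries no free scale parameter, and the default
sampler fixes the scale at 1.  An optional extension
(`estimate_scale = TRUE` in `run_gibbs()`) places a diffuse
inverse-gamma prior on a scale sigma and updates it from its conjugate
full conditional each sweep; it is off by default because the fixed
scale is the cleaner operationalization of the working-likelihood
model, and because posterior means are insensitive to it (only the
spread of the working posterior changes).

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iterations` | 10000 | total Gibbs sweeps |
| `burn_in` | 1000 | initial sweeps discarded |
| `thin` | 5 | keep every 5th retained sweep (1800 retained draws) |
| `beta_mean`, `beta_cov` | 0, 100 I | diffuse normal prior on the kg/m² scale |
| `level` | 0.95 | credible level of the equal-tailed intervals |

The prior default is diffuse relative to BMI effect sizes (single
coefficients rarely exceed 2 kg/m²); with thousands of observations the
likelihood dominates.  Users can override mean and covariance per fit.

## Numerical choices

* Coefficients initialize at the least-squares solution and latents at
  1; least squares is deterministic and shortens burn-in.
* The Gaussian draw factorizes the precision matrix by Cholesky and
  solves triangular systems; no explicit inverse is ever formed, and a
  singular precision raises an error rather than being regularized.
* A residual below 1e-10 in magnitude is floored before forming the
  GIG parameters, because a zero first parameter makes the order-1/2
  draw improper.
* Latent draws are clamped to [1e-12, 1e12]: in extreme-tau sweeps the
  inverse-Gaussian root can underflow by floating-point cancellation,
  and an infinite latent would poison the next Gaussian sweep with
  0 × Inf.
* Multi-quantile runs derive one seed per chain as
  `seed + 7919 * (index - 1)` from the master seed, so each chain is
  independently reproducible.
* Credible intervals are equal-tailed empirical quantiles, not highest
  posterior density: they match the symmetric presentation conventional
  in quantile-regression coefficient tables.
* Empirical percentiles use sorted-order linear interpolation (type 7),
  the dominant software default; it gives the conventional median 50.5
  for the integers 1..100.
* Printed percentages round half *up* to one decimal, matching survey
  report conventions rather than R's banker's rounding.

## The synthetic generator

The survey microdata behind the motivating analysis (the 2019 Ethiopia
Mini Demographic and Health Survey; about 5,323 under-five children) is
access-controlled and not packaged, so every downstream stage is
exercised on synthetic tables that reproduce the *structure* the
analysis assumes:

* 13 categorical covariates with the published marginal proportions
  (e.g. 51.1% male, 76.9% rural, wealth-index shares 33.9/17.4/13.9/
  13.0/21.8) and the reference categories of the published coefficient
  table;
* child age discrete-uniform on 0–59 months and maternal age on 15–49
  years, the printed ranges;
* a right-skewed continuous BMI outcome whose median sits near
  15.3 kg/m², echoing the scale of the published percentile table.

Regional shares are not printed in the source frequency table; the
defaults are plausible Mini-DHS-like shares with small regions
oversampled, chosen once and fixed.

Covariates are drawn independently — there is no copula linking, say,
region and wealth.  Because the regression conditions on the design,
this does not affect the correctness of sampler tests, but it is a
fidelity limitation: passing tests demonstrate that the machinery
recovers known truths under the survey's marginal structure, not that
the generator reproduces the survey's joint distribution, cluster
design, or spatial structure.  Survey weights are likewise out of
scope, matching the unweighted model.

Recovery fixtures use a deliberately small design (intercept, a
centered age score on [-1, 1], a sex dummy) with homoscedastic ALD
noise of scale 0.5, so that at n = 2000 the posterior's own spread is
well inside the recovery tolerances; the fixture returns the exact true
coefficient map at all six default levels.  A location-scale variant
($y = 1 + x + (1+0.5x)z$, $z \sim N(0,1)$, $x \in [0,2]$) provides an
analytic truth that varies with tau: the true slope at level tau is
$1 + 0.5\,\Phi^{-1}(\tau)$.

## What the tests measure — and problem sizes

The suite checks, among others:

* **Closed-form layers.**  ALD and GIG densities integrate to 1; the
  mixture sampler matches the piecewise-exponential closed-form ALD by
  Kolmogorov–Smirnov distance at n = 10^4; GIG(1/2) moments match
  Bessel-ratio closed forms at n = 10^5.
* **Sampler-vs-oracle.**  With a flat prior on n = 200, p = 3 data,
  posterior means at all six levels sit within 3 posterior standard
  deviations of a direct Nelder–Mead minimizer of the check loss.
* **Recovery.**  Matched-noise fixtures at n = 2000 with the full
  10000/1000/5 schedule recover the generating coefficients within 0.1
  at central levels and 0.2 in the tails.  For the location-scale
  slope the check averages over 3 replicate fixtures: a single
  dataset's tail-quantile estimate has sampling standard deviation
  near 0.12 (the direct check-loss minimizer deviates from the
  analytic slope by the same amount as the sampler does), so
  replicate averaging isolates sampler error from estimator noise at
  the same n and tolerance.
* **Calibration.**  95% intervals for the median slope cover the truth
  in at least 42 of 50 replicates at n = 500 (with a shortened
  2000/500/2 schedule to keep the loop fast).
* **Descriptive layer.**  Frequency percentages reproduce the
  published table values exactly at one decimal from the printed
  counts; the 5/85/95-percentile classifier partitions 10^5 continuous
  draws into fractions (5, 80, 10, 5)% within half a point.

Chain lengths in tests are scaled to each check's precision needs: full
schedules where tolerances are tight, shortened schedules for
replicated loops.

## Known limitations

* The working-likelihood posterior spread is not an exact frequentist
  standard error; interval calibration is verified empirically at the
  median but degrades toward extreme tau, as is inherent to
  fixed-scale ALD posteriors.
* Convergence reporting is advisory (`convergence_heuristics()`): the
  intended assessment is visual, from the exported trace, density and
  autocorrelation data/plots.
* No survey weights, no cluster/spatial random effects, no model
  comparison (DIC/WAIC), and no WHO growth-standard z-scores: the
  weight-status classifier is within-sample percentile-based by
  design.
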
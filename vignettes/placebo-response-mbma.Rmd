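---
title: "Modelling the placebo response in primary Sjögren's syndrome trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the placebo response in primary Sjögren's syndrome trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug trials in primary Sjögren's syndrome (PSS) show large placebo
responses on the ESSDAI disease-activity scale, and placebo arms are
small (often under 20 subjects). Judging a new drug — especially in a
single-arm study with no concurrent control — requires knowing what the
placebo response alone would have done at the same baseline severity and
follow-up time. placeboMBMA implements a model-based meta-analysis
(MBMA) of placebo-arm aggregate data: trial-level change-from-baseline
ESSDAI scores pooled across randomized placebo-controlled PSS trials are
described by a nonlinear mixed-effects time-course model, which is then
used as a *virtual placebo control*.

## The model

For trial $i$ observed at week $t_j$ with $N_{ij}$ contributing
subjects, the observed mean change from baseline is

$$E_{ij} = -\mathrm{Emax}_i\,\frac{t_j}{\mathrm{ET50}_i + t_j}
  \;+\; \frac{\epsilon_{ij}}{\sqrt{N_{ij}}},
  \qquad \epsilon_{ij} \sim N(0, \sigma^2),$$

a saturating Emax time course on the improvement (negative) side.
$\mathrm{Emax}_i$ is the trial's asymptotic maximum placebo response in
ESSDAI points and $\mathrm{ET50}_i$ the week at which half of it is
reached ("onset time"). The residual acts on the *arm-level mean*, so
its standard deviation shrinks with $\sqrt{N_{ij}}$: large arms pin the
curve down, tiny arms are allowed to scatter.

Inter-trial variability enters additively on Emax and exponentially on
ET50 (keeping it positive):

$$\mathrm{Emax}_i = \theta_{Emax} + \textstyle\sum_c \beta_c\,(x_{ic} - \bar x_c) + \eta_{1i},
  \qquad \mathrm{ET50}_i = \theta_{ET50}\, e^{\eta_{2i}},$$

with $\eta_{1i} \sim N(0, \omega_{Emax}^2)$,
$\eta_{2i} \sim N(0, \omega_{ET50}^2)$, independent. Covariates $x_c$
(baseline ESSDAI in the retained model) enter Emax linearly, centered at
the corpus median so that $\theta_{Emax}$ is the typical maximum
response of a median trial. The centering constant is stored inside the
parameter object, making fitted models portable across datasets.

The package ships the published final-model estimates as
`default_parameters()`: $\theta_{Emax} = 4.44$ points at reference
baseline 10.1, baseline coefficient $0.552$ points per ESSDAI point,
$\theta_{ET50} = 12.2$ weeks, $\omega_{Emax} = 0.563$,
$\omega_{ET50} = 0.794$, $\sigma = 1.661$. A low enough baseline makes
the covariate line cross zero (at ESSDAI $\approx 2.06$); it is not
clamped, mirroring the linearity assumption.

The inter-trial rows of published parameter tables can denote SDs or
variances; we read them as SDs (the common convention when reported next
to an RSE percentage) and expose `omega_scale = "variance"` as a
sensitivity switch.

## Estimation

The marginal likelihood integrates the two random effects out per trial.
`fit_model()` maximizes a Laplace approximation taken at the per-trial
mode of the joint log-density — the deterministic, testable member of
the FOCE family. Two properties make it checkable:

* `ofv_laplace()` is *algebraically identical* to one-node adaptive
  Gauss–Hermite quadrature, and `ofv_quadrature()` with many nodes is an
  independent brute-force oracle for the same integral;
* with both $\omega$'s zero the objective collapses to the closed-form
  weighted least-squares deviance
  $\sum_{ij} [N_{ij}(y_{ij}-\hat y_{ij})^2/\sigma^2 +
  \log(\sigma^2/N_{ij})]$.

The reported objective function value (OFV) excludes the constant
$n\log 2\pi$; every decision built on it (the $\chi^2$ covariate
cutoffs) uses OFV *differences*, which are unaffected.

The inner problem — the mode of the joint density in
$(\eta_1, \eta_2)$ — exploits that the mean curve is linear in
$\eta_1$: for any $\eta_2$ the optimal $\eta_1$ is closed-form, so the
mode is located by a deterministic profile over a 21-point $\eta_2$ grid
(spanning $\pm 5\,\omega_{ET50}$) followed by damped Newton refinement
with analytic derivatives. Determinism here matters: warm-starting the
inner search from previous iterations makes the outer objective
history-dependent and defeats gradient-based optimizers.

The outer search runs `nlminb` on a transformed scale (log for ET50, the
$\omega$'s and $\sigma$; identity for $\theta_{Emax}$ and covariate
coefficients, whose signs are unconstrained) under wide box constraints.
Because the Laplace objective has small kinks where a trial's inner mode
switches basins, `nlminb` sometimes stops with an uncertified "false
convergence"; the fit then alternates full Nelder–Mead polish runs with
`nlminb` restarts and accepts the point once a full polish run improves
the OFV by less than 0.05. Starting values are data-driven: minus the
mean last-visit change for $\theta_{Emax}$, half the median follow-up
for $\theta_{ET50}$, 0.3 for the $\omega$'s, and the scaled residual SD
of a naive curve for $\sigma$.

Parameter uncertainty comes from the inverse central-finite-difference
Hessian of OFV/2 at the optimum (transformed scale), delta-method
back-transformed to natural-scale relative standard errors. Empirical
Bayes estimates (EBEs) are the per-trial posterior modes at the final
estimates.

## Covariate selection

Candidates (age, % male, treatment duration, time since diagnosis,
baseline ESSDAI, % on base therapy) are screened under the published
rules: a covariate missing in ≥ 40% of trials (inclusive, per trial —
the trial arm is the analysis unit) is excluded and remaining missing
values are median-imputed (`prepare_covariates()`). A candidate is
significant univariately or enters in forward selection when it lowers
the OFV by more than 3.84 ($\chi^2_1$, $P<0.05$) and survives backward
elimination when its removal raises the OFV by at least 6.63
($P<0.01$). Ties in forward selection break by listed order, a
non-convergent candidate fit counts as $\Delta\mathrm{OFV} = 0$
(conservative), and every candidate fit is warm-started from the nested
model it extends, so $\Delta\mathrm{OFV} \ge 0$ by construction. The
functional form for continuous candidates is linear-centered (the form
for non-baseline covariates is not prescribed; this is configurable in
principle but the linear form is the default and only built-in). The
step log records every fit so the search can be replayed
decision-by-decision.

## Model qualification

* **Goodness of fit** (`gof_table()`): population predictions (PRED,
  random effects at zero), individual predictions (IPRED, at the EBEs),
  and conditional weighted residuals (CWRES) via the standard FOCE
  linearization about the EBEs — residuals decorrelated by the Cholesky
  inverse of $F\Omega F' + \mathrm{diag}(\sigma^2/N)$. With
  $\omega = 0$, CWRES reduces exactly to
  $(y - \mathrm{pred})\sqrt{N}/\sigma$.
* **Leave-one-out** (`leave_one_out()`): one full refit per omitted
  trial, reported as parameter ranges and relative deviations — a
  qualitative influence diagnostic, not a variance estimator.
* **Visual predictive check** (`vpc()`): the original design (visit
  weeks, arm sizes, covariates) is re-simulated at the estimates
  (1000 replicates by default) and 2.5/50/97.5 percentile bands are
  formed at the nominal visit weeks, with no smoothing — the corpus
  shares a sparse common visit grid, so nominal-time bins are exact.
* **Sampling importance resampling** (`sir()`): a single SIR iteration
  with a multivariate-normal proposal at the estimates, covariance
  inflated by 1.5, importance weights
  $\propto e^{-\Delta\mathrm{OFV}/2}/q(\theta)$, and resampling without
  replacement (1000 of 5000 by default). The proposal size and inflation
  are package defaults — the published analysis reports only the
  resample count — and an effective sample size below 50 raises an
  error advising more inflation. Per-dimension proposal SDs are capped
  (default 2 on the transformed scale, correlations preserved): an
  omega estimated at the zero boundary leaves the OFV flat in its
  direction and the covariance unbounded there, and an uncapped
  proposal would give the importance weights unbounded variance. On an exactly quadratic OFV surface
  SIR reproduces the Wald intervals, which is how the tests check it.

## Typical-response simulation and the virtual placebo control

`typical_table()` evaluates the deterministic typical response on a
baseline-by-time grid. `typical_ci()` draws the *fixed effects only*
(on the transformed scale, from the asymptotic normal with the fit
covariance, so ET50 stays positive; or independent normals from the
RSEs with lognormal ET50 when no covariance is available, 10,000 draws
by default) and reports percentile bands. Inter-trial variability is
deliberately excluded: the band describes the uncertainty of the
*typical* (population-median) response, not the spread of a new trial.
An important consequence: the band is a confidence band for a median,
and single-arm comparisons against it ask whether the observed response
is compatible with the typical placebo response, not with the full
distribution of hypothetical placebo trials.

`compare_single_arm()` builds that band at the external trial's own
baseline over its own visit weeks and flags each observed mean change.
The efficacy verdict is one-sided — `exceeds-placebo` only when a point
falls *below* the lower band limit (more improvement than placebo
explains); points above the upper limit are flagged `possible_harm`
separately, because a drug arm doing worse than placebo is a safety
observation, not an efficacy one. Observed standard errors are carried
for display but do not enter the containment rule, which compares point
estimates to the band.

## The synthetic-data generator

`sample_design()` + `simulate_dataset()` generate corpora with exactly
the statistical structure the analysis assumes, so every downstream
stage is testable without any external data. Design distributions match
the published corpus summary: arm sizes log-uniform on [4, 95] (median
$\sqrt{4 \times 95} \approx 19.5$, matching the reported median 19),
durations uniform over {12, 16, 24, 28, 48} weeks (median 24), baseline
ESSDAI uniform over [2.5, 13.1], age, % male, time since diagnosis and
% base therapy uniform over their reported ranges, and visit schedules
of 2–4 follow-ups drawn from the {4, 8, 12, 16, 24, 28, 36, 48}-week
grid truncated at the duration (published PSS trials typically report
2–5 ESSDAI follow-ups). Only median/min/max are published for the
design quantities, so uniform (log-uniform for the clearly skewed arm
sizes) over the printed range is the least-committal choice; a
triangular alternative at the median was rejected as adding a shape
assumption the data cannot support.

What the generator does *not* emulate: dropout and attrition (the
per-timepoint N is constant within a trial; a missing N in real data is
last-observation-carried-forward), active-arm effects,
correlation between the two random effects (no correlation parameter is
published), the skew of the real baseline distribution (median 10.1 is
nearer the top of the range than the uniform's 7.8), and digitization
error from figure extraction. Passing tests therefore demonstrate
internal consistency of estimator and generator under the stated model,
not robustness to those real-data features.

## Problem sizes used in the checks

The replicate studies behind the statistical guarantees use 20 corpora
of 13 trials at the published-parameter truth for recovery, selection
power and coverage; a 60-trial corpus for the VPC self-consistency
check (binomial tolerance at its observation count); 3-trial corpora as
quadrature-oracle fixtures; and reduced Monte-Carlo sizes (hundreds of
SIR proposals, hundreds of band draws) in unit tests where only
determinism or shape is at stake. Defaults in the functions themselves
stay at the published analysis sizes (1000 VPC simulations, 1000 SIR
resamples, 10,000 typical-response draws).

## Known limitations

* At the published corpus size (13 small trials, sparse visits, large
  inter-trial variability) the forward/backward search retains the true
  baseline effect in only about 70% of simulated replicates — with only
  13 trials the $\chi^2_1$ test is underpowered for an effect whose
  signal-to-noise at the trial level is near one. Covariate decisions
  at this scale should be read as evidence, not proof.
* $\theta_{ET50}$ is weakly identified when most trials end near or
  before the half-time (relative errors of 20–40% per replicate are
  normal); its published RSE (35%) says the same about the real corpus.
* The Laplace approximation is checked against quadrature to ~0.1 OFV
  on small corpora at the published variability; analyses needing finer
  likelihood accuracy can fit with `approx = "quadrature"` at higher
  cost.
* Aggregate (arm-level) data cannot separate within-trial from
  between-trial covariate effects; covariate coefficients are
  trial-level associations.
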
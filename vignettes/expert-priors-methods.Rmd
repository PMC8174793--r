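---
title: "Expert-elicited priors for daily response propensity prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-elicited priors for daily response propensity prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propelicit)
```

## The problem

Responsive survey designs alter field protocols mid-collection based on
case-level predictions — most commonly the probability that an active
case responds to the screener interview at its next contact attempt.
Fitting the prediction model only to the paradata accumulated so far is
fragile: the early weeks of a collection period are sparse and often
unrepresentative of how the quarter as a whole will look, so early- and
mid-collection predictions can be badly off. A Bayesian fix is to carry
information from outside the current collection — historical quarters
when they exist, and, when they do not (new surveys, redesigns),
structured elicitation from experienced survey managers.

propelicit implements the full pipeline: converting experts' elicited
attempt-level response rates into pooled normal priors on
logistic-regression coefficients, fitting the discrete-time propensity
model under maximum likelihood or under expert/historical priors,
replaying a collection period day by day, and scoring each method's
daily predictions against the end-of-collection benchmark.

## The model

Contact attempts are stacked into a person-attempt file. For case $i$
attempted on day $d$ with covariate row $X_{id}$ (fixed frame/household
covariates plus time-varying attempt history), the response indicator
is Bernoulli with

$$\hat p_{id} = \frac{\exp\left(\sum_{v=0}^{V}\beta_v X_{idv}\right)}
{1+\exp\left(\sum_{v=0}^{V}\beta_v X_{idv}\right)},$$

and the likelihood is the product of the per-attempt Bernoulli terms
(`log_likelihood()`, `fit_propensity()`). This discrete-time
event-history formulation means "one more attempt" is itself a
covariate (`attempt_number`), alongside derived statuses for prior
contact (never / ever / on the previous attempt) and expressed concerns
(none / ever / on the previous attempt / strong concerns ever). When
several statuses apply the most specific or most severe label wins;
ties between same-day attempts are broken by attempt index.

### From elicited rates to priors

Experts are asked for attempt-level response *rates* per category of
each categorical predictor, and for rate *changes* per unit of each
continuous predictor. Each expert's answers become coefficients via the
log odds ratio against that expert's own reference-category answer,

$$\hat\beta_{ijk} = \ln\frac{\hat p_{ijk}/(1-\hat p_{ijk})}
{\hat p_{ijR}/(1-\hat p_{ijR})},$$

and, for unit changes, against the overall attempt-level baseline rate
(24% by default): `categorical_beta(0.85, 0.70)` gives 0.8873,
`continuous_beta(0.05, 0.24)` gives 0.2573. Converting each expert
first and pooling afterwards is what makes a dispersion estimate
possible at all: the pooled prior for a coefficient is the arithmetic
mean of the per-expert coefficients with standard error
$\mathrm{sd}/\sqrt{n}$ (`pool_betas()`). Pooling is performed on the
log-odds scale, where a normality assumption is far more defensible
than on the bounded rate scale.

`build_prior_table()` assembles the diagonal normal prior:

* coefficients contributed by fewer than three experts get a diffuse
  fallback $N(0, 10^2)$ — the model still needs every coefficient, but
  such items carry essentially no elicited information;
* the intercept, which is not elicited item-wise, is anchored at
  $\mathrm{logit}(0.24)$ with SD 0.5 — informative about the overall
  level, weak relative to even a few hundred records;
* pooled SEs of exactly zero (unanimous panels) are floored at $10^{-3}$
  so the prior stays proper;
* elicited rates at the boundary of $(0,1)$ are clipped to
  $[0.005, 0.995]$ with a warning rather than discarding the expert;
* an optional pseudo sample size $m$ rescales SEs by $\sqrt{n}/\sqrt{m}$
  for sensitivity analyses of prior strength.

Between-coefficient covariance of the elicited answers is deliberately
ignored (a 20-expert panel cannot estimate it); the historical
comparator keeps its full covariance precisely because historical fits
can.

### Posterior estimation

With independent normal priors $\beta_v \sim N(\mu_v, \sigma_v^2)$ the
log-posterior is the log-likelihood minus the Gaussian penalty
$\tfrac12(\beta-\mu)'\Sigma^{-1}(\beta-\mu)$. `fit_propensity()`
maximises it by Newton–Raphson with step-halving (start at the prior
mean, or zero for the MLE; convergence when the score's max absolute
entry falls below $10^{-8}$ or the relative objective change below
$10^{-10}$; at most 100 iterations), and reports the inverse observed
information as the covariance — a Laplace approximation for the
Bayesian fits. The mode-plus-Laplace route was chosen over posterior
sampling as the default because the daily replay refits each method up
to 78 times per quarter and determinism keeps results exactly
reproducible; for logistic likelihoods with normal priors the two agree
closely, which a random-walk Metropolis option (`method = "mcmc"`)
cross-checks.

Early-quarter data are sparse and frequently separable, where a pure
MLE diverges. `fit_propensity()` then refits under a weak ridge
pseudo-prior $N(0, 10^2)$ and flags the fit (`ridged = TRUE`); the flag
propagates into replay outputs. This is an unavoidable deviation from
pure maximum likelihood on such days.

### The historical comparator

`build_pwp_prior()` reconstructs a precision-weighted prior from
historical quarters: per-quarter full MLEs pooled by inverse-variance
weighting, prior precision the sum of per-quarter precisions (optionally
deflated by $\kappa \ge 1$), full covariance retained. The published
description of this method leaves the exact construction to earlier
work; inverse-variance pooling of per-quarter fits is the natural
reading of "precision-weighted", and a stacked single fit over the
concatenated quarters remains available through `fit_propensity()`
directly.

### The daily replay and its scoring

`fit_target()` fits the full quarter by MLE and evaluates each case's
predicted response probability at its *last* observed contact attempt —
the benchmark $\rho_i$. `replay_daily()` then refits each method on the
records accumulated through each day $d = 7, \dots, 84$ (78 daily fits)
and predicts the next-attempt propensity $\hat\rho_{im}$ for every case
active on day $d$: attempted at least once, not yet responded, not
finalized. Cases never attempted by day $d$ are excluded — there is no
history from which to derive their time-varying covariates. Note the
deliberate asymmetry, which mirrors how such systems are used in
production: the daily prediction stands at next-attempt covariates
while the benchmark stands at final-attempt covariates.

Daily bias is $\bar{(\hat\rho - \rho)}$ and daily RMSE
$\sqrt{\overline{(\hat\rho-\rho)^2}}$ over the day's active set
(`evaluate_day()`, `evaluate_replay()`); RMSE $\ge$ |bias| always.
`phase_summary()` condenses the daily series into the three collection
phases — early (days 7–30, 24 days), middle (31–60, 30 days), late
(61–84, 24 days) — as five-number summaries plus means, the numbers
behind phase boxplots (`autoplot()`). Quartiles use linear
interpolation between order statistics (type 7); days with no active
cases or failed fits are recorded as missing and excluded, with
`n_days` reporting the coverage. In-sample fit statistics for the
benchmark model (ROC–AUC via pROC, Nagelkerke pseudo-$R^2$ from the
log-likelihoods) come from `fit_metrics()`, computed over all attempt
records by default.

## The synthetic test bed

Production paradata of this kind are restricted, so the package ships a
generator (`simulate_quarter()`) whose defaults define the study
conditions used throughout the tests:

* 84-day quarter; first attempts spread uniformly over days 1–7;
  inter-attempt gaps $1+\mathrm{Geometric}$ with a **day-dependent
  mean**: 6 days at mid-quarter, with the day-1 gap 20 times the day-84
  gap (`attempt_gap_ramp`). This emulates assignment ramp-up early and
  a closeout push late, and gives the sparse-early / dense-late record
  accumulation characteristic of these field operations: roughly a
  third of a quarter's attempt records exist by day 30 and two thirds
  by day 60.
* per-attempt response from the discrete-time logistic truth
  (`sim_beta_true()`, intercept at $\mathrm{logit}(0.24)$), with
  event flags (contact, concerns, strong concerns) drawn per attempt
  and the time-varying covariates derived causally from them;
* a per-quarter **early-period drift**: a random coefficient deviation
  $\delta \sim N(0, 0.15^2)$ applied with weight declining linearly to
  zero by day 60. Early-collection data thus follow a process that
  differs quarter by quarter and settles onto the long-run coefficients
  as collection proceeds — the early-data unrepresentativeness that
  motivates informative priors;
* simulated expert panels (`simulate_expert_panel()`): 20 experts
  (two organizations, three experience bands), each answer perturbed on
  the log-odds scale by an expert-level offset (SD 0.15, which cancels
  within an expert's own odds ratios, mimicking a consistent personal
  anchor) and an answer-level error (SD 0.2), with 10% item
  nonresponse. With both SDs at zero the conversion-and-pooling
  pipeline recovers the generating coefficients to machine precision —
  a strict round-trip identity the tests assert at $10^{-12}$.

Two design points deserve emphasis. First, the back-loaded attempt
schedule and the early drift are not cosmetic: with a front-loaded,
within-quarter-stationary generator, the day-$d$ MLE is nested in the
benchmark's own data, and no prior centered on the long-run truth can
systematically beat it by mid-collection — the methods tie. The regime
in which informative priors pay off is precisely the one where the
mid-collection likelihood is still weak or misaligned relative to the
final fit, and the generator's defaults place the test bed in that
regime deliberately. Users can verify the tie themselves by setting
`attempt_gap_ramp = 1, early_drift_sd = 0`. Second, the generator is
still an idealisation: real paradata carry interviewer effects,
case-level unobserved heterogeneity, seasonal structure and protocol
interventions that it does not emulate, so passing tests demonstrate
correctness of the machinery and qualitative behaviour under the
stated conditions — not performance guarantees on any particular
survey.

Parameter-recovery checks run with `early_drift_sd = 0`: recovery of
the generating coefficients by the full-quarter MLE is only a defined
notion when the model is well-specified, which the drift intentionally
breaks.

## Simulation sizes and numerical choices

The test suite exercises the full pipeline at sizes chosen to keep a
complete run affordable while leaving Monte-Carlo margins wide:
parameter recovery uses 100 replicated quarters of 1,200 cases
(3-SE coverage asserted at ≥ 90%, against a nominal ~99.7%); the
expert-versus-standard comparison uses five replicated 800-case
quarters with the default truth-centered panels, asserting the
mid-phase mean-RMSE ordering with a one-sided Monte-Carlo allowance of
0.005 and the late-phase convergence of the two methods; the replay
geometry check runs one 5,000-case quarter. Seeds are fixed
throughout; per-component seeds are derived deterministically so any
single generator can be re-run in isolation.

Degenerate inputs are handled explicitly rather than defensively:
empty designs are flagged and yield the prior itself under a Bayesian
fit (and an error without one); a single-contributor pooled SE is
undefined and routes to the diffuse fallback; single-class responses
make the AUC undefined (`NA` with a warning); days with empty risk
sets are recorded and excluded from summaries.

## Known limitations

* The covariate list is configuration, not inference: no variable
  selection is performed, and the shipped NSFG-style schema is a
  reconstruction, not the production predictor set.
* Arithmetic pooling only; no consensus procedures, no per-expert
  distribution elicitation, no heavy-tailed (e.g. $t$) priors.
* No interviewer or clustering structure, no cost model, and no
  modelling of the interventions a responsive design would trigger —
  the package evaluates prediction quality, not downstream decisions.
* The precision-weighted historical prior is a reconstruction from its
  description (see above); per-quarter pooling is the default and a
  stacked fit the alternative.
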
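---
title: "Dynamic and relative survival models for hazard extrapolation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic and relative survival models for hazard extrapolation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in **drsurv**, the
assumptions behind them, the numerical choices that matter, and what the
package's synthetic-data machinery does and does not emulate.

## The additive relative-survival decomposition

Survival extrapolation for health technology assessment must say something
about mortality decades beyond the trial's follow-up. A purely
disease-driven model can extrapolate a hazard that falls below the
all-cause mortality of the age-matched general population, which is rarely
credible for serious disease. Additive relative-survival (excess hazard)
models avoid this by decomposing the overall hazard as

$$h(t) = p(t) + \lambda_E(t),$$

where $p(t)$ is the general-population (background) hazard, known from a
life table, and $\lambda_E(t)$ is the disease-specific *excess* hazard to
be modelled. Because $\lambda_E \ge 0$ in the extrapolated phase for every
model in this package, the modelled overall hazard never falls below
population mortality, and overall survival factorizes as
$S(t) = S_{\text{pop}}(t)\,\exp\{-\Lambda_E(t)\}$.

### Background hazard from a life table

A life table supplies annual death probabilities $q_a$ per year of age.
For a cohort aged $a_0$ at time zero, the package's default convention is a
*uniform distribution of deaths within each year of age*: at age $a + f$
(integer $a$, $f \in [0,1)$),

$$p(t) = \frac{q_a}{1 - f\,q_a},$$

which rises within the age-year and has the closed-form cumulative hazard
$-\log(1 - f q_a)$ per partial year. A piecewise-constant alternative
($p = -\log(1-q_a)$ across the year) is available via the `convention`
argument of `pop_hazard()`, but it is not the default because the
uniform-deaths form is also what the simulation generator uses when it
samples population survival times, keeping the two layers consistent.
Times beyond the final tabulated age are a hard error rather than a silent
tail extrapolation: an invented tail would corrupt exactly the
hazard-floor semantics the relative models exist to provide.
`synthetic_life_table()` builds tables from the Gompertz–Makeham law
$p(\text{age}) = \lambda + \alpha e^{\beta\,\text{age}}$; the defaults
($\lambda = 5\times10^{-4}$, $\alpha = 3\times10^{-5}$, $\beta = 0.092$)
give roughly 1% annual mortality at age 63 doubling every 7.5 years,
resembling a recent high-income national life table at adult ages.

## Parametric and spline excess-hazard models

`fit_parametric()` covers the exponential, Weibull, Gompertz, log-normal
and log-logistic families, either on the overall hazard or as excess
hazards. The log-logistic parameterization is
$h(t) = (b/a)(t/a)^{b-1} / \{1 + (t/a)^b\}$ with scale $a > 0$ and shape
$b > 0$; for $b > 1$ the hazard rises then falls, the shape that motivates
its use for cancer-trial hazards. The subject-level log-likelihood of a
relative fit is

$$\ell = \sum_i \left[ d_i \log\{p(t_i) + \lambda_E(t_i)\}
  - \Lambda_E(t_i) - \Lambda_{\text{pop}}(t_i) \right].$$

The $\Lambda_{\text{pop}}$ term is parameter-free and does not move the
maximizer, but the package keeps it in the *reported* log-likelihood so
that AIC values are comparable between relative and non-relative fits of
the same data. Optimization is BFGS on log-transformed positive parameters
(the Gompertz shape and log-normal location stay unconstrained), started
from the crude event rate with shape 1, with five jittered restarts before
a failure is declared — excess-hazard likelihoods with few events are prone
to local optima. Standard errors come from the observed information;
hazard-curve bands use the delta method. The plain exponential fit uses
its closed-form MLE (events over person-time) directly.

Model comparison uses AIC and the *inverse evidence ratio*
$\mathrm{IER}_m = \exp\{-\tfrac12(\mathrm{AIC}_m - \mathrm{AIC}_{\min})\}$,
an interpretable $(0, 1]$ rescaling on which the best-fitting model scores
exactly 100%.

### Spline models: NRS and FCM

Two flexible excess-hazard models put a restricted cubic spline on the log
cumulative excess hazard in log time, $\log \Lambda_E(t) = s(\log t;
\gamma)$, so $\lambda_E(t) = \Lambda_E(t)\, s'(\log t)/t$:

* the **Nelson-type relative survival model (NRS)** uses the natural-spline
  basis, linear beyond the boundary knots, so the extrapolated log
  cumulative excess hazard continues its fitted log-linear trend;
* the **flexible cure model (FCM)** additionally constrains the spline to
  zero slope beyond the final knot. The cumulative excess hazard then
  plateaus, the extrapolated excess hazard is exactly zero, and
  $\pi = \exp\{-\Lambda_E(\infty)\}$ is a cure fraction.

The FCM constraint is implemented by reparameterizing the basis: the free
linear term is removed and each remaining natural-spline column $v_j$ is
replaced by $v_j - s_j x$, where $s_j$ is that column's slope beyond the
final knot, so the constrained space is exactly "cubic splines with zero
derivative after the last knot". Default knots are two internal knots at
the 33rd/67th centiles of log event times with boundary knots at the
extremes — the "up to 2 internal knots" convention of the case-study
models; knot placement is configurable because no single choice suits all
follow-up patterns. Starting values regress the log Nelson–Aalen excess
cumulative hazard on the basis, which in particular keeps the FCM away
from the saddle at $\gamma = 0$. Negative fitted excess hazard between
knots is permitted where no event lies (standard for this model class);
the hard population floor is applied by `cap_hazard_at_population()` when
curves are handed to the economic model.

## Dynamic survival models

The package's central model class treats the hazard as a time series.
Follow-up is discretized (`discretize()`; default one-month intervals
covering all observed time, with zero-exposure trailing intervals dropped)
into death counts $d_j$ and person-years $e_j$ with interval midpoints
$t_j$. Writing $x_j = \log t_j$ and $\Delta_j = x_{j+1} - x_j$, the
observation model is $d_j \sim \text{Poisson}(e_j h_j)$ with

* DSM: $h_j = e^{\eta_j}$ (log overall hazard), or
* DRSM: $h_j = p_j + e^{\eta_j}$ (log *excess* hazard plus the population
  hazard at the midpoint),

and the state $\eta_j$ evolves on the log-time scale:

| structure | evolution | extrapolation behaviour |
|---|---|---|
| local level | $\eta_{j+1} = \eta_j + w_j$ | constant (excess) hazard |
| local trend | $\eta_{j+1} = \eta_j + \delta_j \Delta_j + w_j$, $\delta_{j+1} = \delta_j + v_j$ | trend continued indefinitely |
| damped trend | as local trend with $\delta_{j+1} = \phi^{\Delta_j}\delta_j + v_j$ | trend attenuates geometrically |

with $w_j \sim N(0, \sigma_\ell^2\Delta_j)$ and $v_j \sim N(0,
\sigma_\tau^2\Delta_j)$. Placing the dynamics on log time makes the
zero-innovation local trend *exactly* a linear model of the log hazard in
log time — the classical log-log linearity that standard parametric models
impose globally, here relaxed locally. Damping as $\phi^{\Delta_j}$ per
log-time step (rather than per interval) makes inference invariant to
re-discretization. For a DRSM with a negative trend the excess hazard
decays towards zero and the overall hazard approaches population
mortality from above; it can never cross it, because $e^{\eta} > 0$ by
construction, in every posterior draw.

Priors are weakly informative and scale-aware: $\eta_1 \sim N(\log
\hat{r}, 2^2)$ around the crude (excess) rate, $\delta_1 \sim N(0,1)$,
half-$N(0,1)$ on both innovation scales, and $\phi \sim U(0.5, 1)$
(estimable or fixable). A DRSM whose population hazard exceeds the crude
hazard in at least half the intervals triggers a
weak-identification warning rather than an error.

### Inference engines

Two engines sit behind the same `fit_dsm()` contract:

* **MCMC** (default): Gibbs/slice sampling via JAGS (rjags), 2 chains of
  1000 retained draws after 1000 warmup iterations, with split-$\hat R$
  reported for every parameter and a warning above 1.05. Seeded chains
  make runs exactly reproducible.
* **Laplace**: a marginal (nested) Laplace approximation. Conditional on
  the hyperparameters $\psi = (\log\sigma_\ell, \log\sigma_\tau,
  \text{logit-type }\phi)$, the states form a Gaussian Markov field with a
  Poisson observation layer; their conditional posterior is approximated
  by a Gaussian at its mode (Fisher-scoring Newton with the expected
  Poisson curvature $e_j e^{2\eta_j}/h_j$, which keeps the Hessian
  positive definite for the DRSM), and the hyperparameter marginal by the
  Laplace integral. Hyperparameter uncertainty is propagated by sampling
  $\psi$ from its Gaussian marginal approximation and refreshing the state
  mode before each conditional state draw.

A *joint* MAP over states and scales is deliberately avoided: the
hierarchical funnel drives the scales to zero and collapses the state
uncertainty — an early implementation did exactly that and produced absurdly
narrow trend intervals on constant-hazard data. The marginal construction
is the standard remedy. The Laplace engine is roughly two orders of
magnitude faster than MCMC and is what the simulation-study machinery uses;
its approximation quality is checked in the test suite against known-truth
recovery, MCMC agreement on the same data, and interval calibration across
seeded replicates.

Extrapolation propagates each posterior draw through the transition
equations *with fresh innovations*, so forecast fans widen with horizon;
point forecasts (innovations off) are available for the deterministic
reductions. With both innovation scales fixed at zero the entire state
path is a function of the initial states, and `fit_dsm()` switches to an
exact low-dimensional fit of that reduction.

`information_criterion()` reports a DIC-style score (deviance at the
posterior mean of the states plus twice an effective-parameter term) for
comparing dynamic fits on the same interval data. It is documented as
*not* comparable with the subject-level AIC of the parametric and spline
models, which is why the two comparisons are kept in separate functions.

## The simulation study

`dgm_spec()` defines the data-generating mechanism: for each subject,
three latent times — a log-logistic excess time, a population survival
time sampled from the life table under uniform deaths within year, and a
censoring time uniform on $[c_{lo}, c_{hi}]$ — of which the observed record
is the minimum, with event status accordingly. Defaults: $a = 0.8$,
$b = 1.8$ (a hazard that peaks near 8 months at about 1.1/year and then
declines — the shape of an aggressive-cancer trial arm), the synthetic
Gompertz–Makeham table with start age 63, censoring $U(5,6)$ years,
$n = 300$ per replicate, 200 replicates. The estimand is the log of the
time-varying overall hazard; hazard estimates are capped at 1 before
logging (applied to the point estimate, not per posterior draw) so that a
few wild extrapolations cannot dominate the summaries.

The evaluation grid is monthly midpoints to a 20-year horizon, with
summaries reported overall and split into within-sample ($t \le c_{hi}$)
and extrapolation regions. Per-replicate time averages are formed first;
their across-replicate mean and normal-approximation 95% confidence
intervals give the reported time-averaged bias and MSE. Model failures are
excluded listwise per model and counted; a model failing on more than 20%
of replicates triggers a prominent warning.

`dgm_truth()` returns the closed-form truth (log-logistic plus background
hazard) or a Monte-Carlo estimate from $N$ uncensored simulated deaths.
The Monte-Carlo mode uses a local log-linear Poisson (local-likelihood)
hazard estimator with an adaptive bandwidth that widens symmetrically
around each grid point until at least 6000 deaths contribute: a plain
binned occurrence/exposure ratio is either Poisson-noisy in the sparse
tail or first-order biased when smoothed, and the local-linear form in
log time removes that bias where the log hazard is locally log-linear.

The test suite runs a scaled-down version of the full study (50
replicates, all five models, Laplace engine) and checks the *ordering*
that matters scientifically: the correctly specified log-logistic model
attains the lowest time-averaged MSE, and in the extrapolation region the
cure model's bias sits below the Nelson model's (the FCM forces the excess
hazard to zero and so underestimates a tail whose true excess is still
positive, while the NRS continues a log-linear cumulative-hazard trend and
overestimates it). Reproducing the published digits of any particular
study would require that study's fitted generator parameters and life
table, which are not part of this package; the ordering and sign pattern
are the reproducible content.

## The economic model

`evaluate_ce()` implements a three-state partitioned-survival model:
stable = PFS survival, progressed = OS − PFS survival (floored at zero
with a warning when independently fitted curves cross), dead = the
complement. QALYs and costs are trapezoid integrals of discounted
occupancy over a 20-year horizon with a one-week cycle by default —
trapezoid integration of occupancy between cycle points is equivalent to a
half-cycle correction in the limit and has a clean quadrature
interpretation (halving the cycle moves QALYs by well under 0.5% for
smooth inputs). Utilities default to 0.750 (SD 0.236) for stable and
0.592 (SD 0.315) for progressed disease, the values used in the
lung-cancer appraisal this package's models were built around. The
discount rate defaults to 3.5%/year for both costs and effects (the UK
HTA reference case) and is configurable. PSA draws utilities from Beta
and costs from Gamma distributions matched by the method of moments, with
2000 iterations by default; the ICER is labelled as dominant, dominated,
or undefined when incremental QALYs are zero.

`cap_hazard_at_population()` supplies the post-hoc flooring operator
$h'(t) = \max\{h(t), p(t)\}$ used to repair non-relative extrapolations;
relative models never need it, which is their point.

## Numerical choices and degenerate inputs

* Ties: a censoring recorded at exactly a death time is treated as
  occurring after the death (standard convention), and a death at an
  interval edge belongs to the interval ending there.
* Interval counts conserve total deaths and person-time exactly; both are
  asserted to $10^{-9}$ in the tests.
* All-censored datasets are a hard error for every fitting function.
* Hessians that fail to factor are ridge-regularized with an escalating
  jitter before posterior draws are attempted; persistent failure is a
  flagged error, never a silent fallback.
* Seeds: every stochastic routine takes an explicit seed; the simulation
  study derives one substream per replicate from the master seed
  (`seed * 10007 + 131 * replicate` modulo $2^{31}-1$) so single
  replicates can be re-run in isolation. Routines that draw internally
  save and restore the caller's RNG state.

### Problem sizes used in the shipped checks

The test suite exercises the models at sizes chosen to make the
statistical assertions sharp but the suite practical to run routinely:
parameter recovery at $n = 20{,}000$ subjects (3-SE checks need small
SEs), interval-calibration and information-score studies at 20 seeded
replicates of a few hundred subjects with coarse discretization, the
scaled-down simulation study at 50 replicates of $n = 300$, and
Monte-Carlo truth at $N = 10^6$ draws. These are the package's own
reference conditions; all of them are plain function arguments, and users
reproducing a published study should set the sizes that study reports.

## What the synthetic data do and do not emulate

The generator reproduces the *structure* of a relative-survival trial
dataset: an additive excess + background hazard, administrative censoring
in a fixed window, and a unimodal excess hazard with a turning point
inside follow-up. It does not emulate covariate effects on the excess
hazard (age, sex, treatment interactions), informative censoring,
delayed-entry/left truncation, reporting lags, or mis-specified life
tables (e.g. a sex-mix mismatch between cohort and table). Passing tests
therefore demonstrate correctness of the estimators under the stated
mechanism, not robustness to those real-data complications; the package's
Discussion-level caveat is that relative-survival extrapolation inherits
the quality of the life table it is given.

## Known limitations

* Cohort-level background hazard only: one life-table curve per fit, no
  subject-specific expected mortality.
* No covariate regression on the excess hazard; separate fits per arm or
  a fixed hazard ratio are the supported ways to represent a treatment
  effect, and a time-varying treatment effect on the excess hazard is out
  of scope.
* The dynamic-model information score is engine-consistent but
  approximate (posterior-mean plug-in); model choice between dynamic
  structures is better guided by the trend path and extrapolation
  behaviour than by small score differences.
* The Laplace engine's Gaussian approximations can understate tail
  uncertainty when interval death counts are very small; the MCMC engine
  is the reference when the two disagree.
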
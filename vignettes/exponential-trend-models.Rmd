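---
title: "Exponential trend models for split-belt treadmill symmetry series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential trend models for split-belt treadmill symmetry series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitbeltfit)
```

## The problem

Walking on a split-belt treadmill with the two belts at different speeds
perturbs gait. Over successive strides people adapt: the per-stride step
length symmetry

$$y(n) = \frac{l_f(n) - l_s(n)}{l_f(n) + l_s(n)}$$

(fast-leg minus slow-leg step length, normalised to their sum; 0 is
perfect symmetry) drifts toward a plateau, and drifts back once the
belts are tied again (de-adaptation). The timecourse of that change is
the quantity of scientific interest, and it is conventionally modelled
as an exponential trend in the stride index $n = 1, \dots, N$ with
additive Gaussian noise:

- single exponential: $y(n) = a e^{bn} + c + \epsilon(n)$,
- double exponential: $y(n) = a_s e^{b_s n} + a_f e^{b_f n} + c
  + \epsilon(n)$,

with $\epsilon(n) \sim N(0, \sigma_\epsilon^2)$ independent over
strides. Only decaying trends ($b < 0$) are meaningful: a growing
exponential never settles, which contradicts what adaptation data look
like. The double model splits the trend into a slow and a fast process
($b_f < b_s$, so the fast process vanishes first); with opposite-sign
amplitudes it can also represent an *overshoot*, a swing of the series
past its asymptote.

## Common-language parameters

Raw regression parameters are awkward to discuss across studies, so
every fit is also reported on a transformed scale
(`to_common_language()`, `common_language_table()`):

| quantity | single | double |
|---|---|---|
| asymmetry at beginning | $a + c$ | $a_s + a_f + c$ |
| total change | $a$ | $a_s + a_f$ |
| strides to ~50% change | $\lfloor \ln 2 / |b| \rfloor$ | one per process |
| asymmetry at end | $c$ | $c$ |
| overshoot $y_{crit}$ | — | $f_2(n_{crit})$ when $a_s a_f < 0$ |
| residual SD | $s$ | $s$ |

The overshoot location comes from setting $f_2'(n) = 0$:
$n_{crit} = \ln(-a_s b_s / (a_f b_f)) / (b_f - b_s)$, defined only when
the amplitudes have opposite signs. `overshoot()` reports `ncrit` as a
real number and flags whether it falls inside the observed stride range
— an extremum outside $[1, N]$ is not observable in the data. A fitted
amplitude of exactly zero is flagged as the degenerate boundary case (a
double model no better than a single one).

The residual scale is $s = \sqrt{SSE / (N - p)}$ with $p$ the number of
free regression parameters. This is the estimator that enters the
variance matrix of the linearized intervals; we use it as the reported
"residual SD" as well, as it is the only residual-scale estimator the
model family defines.

## Parameter bounds and direction detection

Because symmetry lives in $[-1, 1]$, every parameter can be boxed
(`make_bounds()`): $c \in [-1, 1]$; rates in $[-\ln 2, 0]$ (a 50%
change within a single stride is already an implausibly fast decay);
the single-model amplitude in $[0, 2]$ or $[-2, 0]$ depending on the
approach direction; and the double-model amplitudes in sign-patterned
unit boxes, with one variant admitting an overshoot (opposite signs)
and one not. The box makes a global, initialisation-free search
feasible — the point of the whole design.

The approach direction is detected from the sign of the difference
between the mean of the first and last 50 strides
(`detect_direction()`; windows shrink to $\lfloor N/2 \rfloor$ for
short series so they never overlap). This heuristic fails precisely
when a large overshoot or heavy noise makes the two window means
similar. For that reason `fit_exp(direction = "race")` fits under both
direction bound sets and keeps the cheaper solution; an exact tie in
the window means triggers the race automatically. The bundled
`adaptation2` example (an overshoot series) is a reproducible instance
where the 50-stride rule picks the wrong direction and racing repairs
it, so the example workflows use `direction = "race"`.

## Fitting: penalised least squares, swarm + local refinement

The single model minimises the plain sum of squared errors over its
box. The double model adds two penalty terms:

$$\lambda_1 \max(0,\; b_f - b_s + \delta)^2 +
  \lambda_2 \max(0,\; |a_s + a_f| - 2)^2 + \sum_n (y(n) - f_2(n))^2$$

with $\lambda_1 = \lambda_2 = 10^3$ and $\delta = 10^{-3}$, so that the
slow/fast labelling ($b_f < b_s$, with at least $\delta$ separation)
and the total-change range are enforced softly: at $b_f = b_s$ the
first penalty contributes exactly
$10^3 \cdot (10^{-3})^2 = 10^{-3}$ — large enough for the search to
feel, small enough not to wall off the feasible set. The reported `sse`
always excludes the penalties (AIC and the profile statistic consume
the pure residual sum of squares); the penalty value at the optimum is
reported separately and is at most $10^{-3}$ in a feasible solution.

Nonlinear least squares for exponentials is multimodal, and
gradient-descent fits are notoriously sensitive to the initial guess.
The fit therefore runs in two stages (`fit_exp()`):

1. a global-best particle swarm over the box (default 100 particles,
   standard constriction coefficients 0.7298/1.49618/1.49618,
   velocities clamped to the box range, particles clamped to bounds
   with zeroed velocity), stopped once the relative best-cost
   improvement stays below `global_tol = 1e-3` for 20 iterations —
   deliberately coarse;
2. bounded quasi-Newton refinement (L-BFGS-B with analytic gradients)
   from the swarm's best point, cost tolerance `local_tol = 1e-6`. The
   refinement call is restarted from its own solution until the cost is
   stationary (relative gain below 1e-12, at most 25 rounds), because a
   single run's stopping test can strand accuracy near a near-perfect
   fit.

The procedure is repeated twice (`restarts = 2`) from fresh random
swarms, and — for the double model — for both the overshoot and
no-overshoot bound variants; the smallest final cost wins, with exact
ties (within 1e-12) resolved in favour of the simpler no-overshoot
variant. Every random draw derives deterministically from the master
seed (`fit_config(seed = )`): restart $r$ under bound variant $v$ uses
a multiplicatively hashed sub-seed of $(\mathrm{seed}, v, r)$, so
identical seeds and inputs reproduce results bit for bit while distinct
restarts use unrelated streams. The global stage can still, rarely,
leave every restart in a poor basin — the known cost of a stochastic
global search; re-running with a different seed, more restarts, or a
larger `stall_iters` exposes such cases, and fits worth reporting
should be checked this way.

Bound-set entries with `lower == upper` pin a parameter and remove it
from the search; this powers both reduced models (e.g. a pure-mean fit)
and the inner re-optimisations of the profile intervals.

## Model comparison and inference

$R^2$ is a poor goodness-of-fit measure for nonlinear regression, so
model comparison uses $AIC = 2k + N \ln SSE$ with $k$ counting the
estimated parameters *including* the residual variance (4 for the
single, 6 for the double model), and the conservative rule: select the
double model only when $AIC_{double} - AIC_{single} < -2$, strictly
(`select_model()`; a delta of exactly $-2$ keeps the single model).
Residual plots (`residual_diagnostics()`) check the constant-variance
and normality assumptions that both AIC and the intervals rely on.

Two interval constructions are provided:

- **Linearized** (`ci_linearized()`):
  $\hat\theta_j \pm \hat V_{jj}^{1/2} t_{N-p,1-\alpha/2}$ with
  $\hat V = s^2 (J^\top J)^{-1}$ and the analytic Jacobian rows
  $[e^{bn},\; a n e^{bn},\; 1]$ (doubled for the double model). Cheap,
  but trusts the linear approximation.
- **Profile / exact** (`ci_profile()`): endpoints solve
  $(N-p)(\tilde S(\theta_j^*) - S(\hat\theta))/S(\hat\theta) =
  F_{1-\alpha}(1, N-p)$, where $\tilde S$ re-optimises all other
  parameters with the $j$-th fixed. Roots are bracketed between each
  box bound and the estimate; when the statistic does not cross the
  quantile at the bound, the bracket extends to $\pm 100$, and an
  endpoint with still no crossing is *undefined* ("UD") — exactly how
  an unbounded overshoot confidence limit should read. The root finder
  is `uniroot` at tolerance $10^{-8}$ relative to the bracket; the
  inner re-optimisations warm-start from the full fit and from the
  previous profile point, keeping whichever is cheaper, and use only
  the local refinement stage (the full objective is smooth in the
  neighbourhood the profile traverses).

For the pure-mean model the two constructions coincide exactly (the
$F(1,\nu) = t_\nu^2$ identity); this closed form is a test fixture.
No multiple-comparison correction is applied anywhere; comparisons
between fits use the no-overlap rule (`compare_intervals()`): disjoint
intervals are read as a significant difference, any overlap — or an
undefined endpoint that cannot exclude overlap — is not.

**Transformed-quantity intervals.** Quantities that are monotone in a
single parameter inherit a profile interval by transforming its
endpoints: the final asymmetry ($c$), the single-model total change
($a$), and the strides-to-50% counts (floored after transforming the
rate interval; a rate interval touching 0 yields an unbounded "UD"
stride endpoint). For multi-parameter transforms (initial asymmetry,
double-model total change, overshoot) it is ambiguous what "the"
profile interval should be without choosing a reparameterisation, so
`common_language_table()` reports delta-method linearized intervals for
those and marks the profile column "UD". This is a documented
limitation, not an oversight.

## The synthetic-series generator

Trial data of this kind are rarely deposited, so `simulate_series()`
generates series with exactly the structure the models assume:
$y(n) = f(n;\theta)\; [+ A\sin(2\pi n/T)]\; + \epsilon(n)$. A spec
whose trend (plus sinusoid amplitude) $\pm 4\sigma$ could leave
$[-1, 1]$ is rejected rather than clipped — clipping would silently
break the Gaussian assumption. The four bundled specs
(`default_specs()`) emulate group-averaged adaptation (N = 750) and
de-adaptation (N = 500) series over two sessions: double-exponential
trends with slow half-lives of tens to a couple of hundred strides,
fast half-lives of a few strides, residual SD 5–7 × 10⁻³, and one
adaptation spec with opposite-sign amplitudes (overshoot ≈ 0.05 above
its plateau of 0.03). These magnitudes are realistic for group-averaged
split-belt data; they emulate published magnitudes and do not replicate
any particular dataset.

What passing tests on such data do show: the optimiser finds the
generating parameters, the intervals cover at close to nominal rate,
and the AIC rule discriminates one- from two-timescale truths. What
they cannot show: behaviour under the features real participant series
have and the model lacks — cyclic residual trends (the generator can
inject a sinusoid to study exactly this failure mode: the fitted
exponential model's residual periodogram then peaks at the injected
frequency), autocorrelated noise, or heteroscedasticity across strides.
The residual diagnostics exist to catch those in real data.

## Numerical choices and problem sizes

- Swarm hyperparameters (size 100, iteration cap 1000, stall window 20)
  are exposed in `fit_config()`; the defaults converge in well under
  100 iterations on series of this length.
- Monte-Carlo suites in the package's tests use 750-stride series with
  $\sigma = 0.006$, 50–100 seeds for selection/coverage experiments,
  and 20 series for the nesting check; the acceptance script uses 100
  recovery replicates. These sizes give stable medians and coverage
  proportions (binomial SE ≈ 2–4 points) at desk-scale runtimes.
- Degenerate inputs: series shorter than the free parameter count are
  rejected (the residual variance would be undefined); constant series
  fit cleanly (amplitude pinned near zero); perfect fits raise an error
  in `aic_exp()` (the log-SSE form has no finite value) and degrade
  gracefully to zero-width intervals elsewhere.
- Exact zero mean-difference in direction detection triggers the
  both-directions race rather than an arbitrary choice.

## Known limitations

- The 50-stride direction rule can fail on overshoot-bearing or noisy
  series; racing doubles the fit cost but removes the failure mode.
- Profile intervals for multi-parameter transforms are not provided
  (see above); the linearized delta-method intervals stand in.
- The noise model is iid Gaussian; cyclic or autoregressive residual
  structure is diagnosed but not modelled.
- Inference is per-series; no participant-level mixed-effects pooling.

## A worked example

```{r example, eval = FALSE}
spec <- default_specs()$adaptation1
y <- simulate_series(spec, seed = 2)
report <- run_fit(y, model = "auto", seed = 2, direction = "race")
print(report)
```
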
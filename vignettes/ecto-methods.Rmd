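---
title: "Entropy-initiated coupled-trait ODE modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-initiated coupled-trait ODE modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecto)
```

## The modelling problem

Longitudinal cohort surveys measure ordered-categorical (Likert) items at a
small number of widely spaced waves. Rather than modelling item responses
directly, `ecto` compresses each item's wave-level response distribution
into its Shannon entropy in bits,

$$H_j(t) = -\sum_i p_i \log_2 p_i, \qquad p_i = x_i \Big/ \sum_k x_k,$$

normalizes by the theoretical maximum $\log_2 n$ for an $n$-category item,
and (optionally) pools normalized item entropies into a cohort index
$H^*(t) \in [0,1]$. Entropy here is a population-level dispersion summary:
it says how broadly responses spread over categories at a wave, not how any
individual varies. Items are allowed different category counts — the count
is taken from the data, never hard-coded — and entropies are always
reported in bits (no natural-log variant is exposed).

The entropy trajectories are then treated as dynamical observables. Two
traits are mapped onto the states $N$ (primary) and $P$ (secondary) of an
autonomous three-state system with a latent stress component $E$:

$$\frac{dN}{dt} = \mu N - \big(\alpha N + \beta^2 P\big) N, \qquad
\frac{dP}{dt} = \mu P - \beta P \, \frac{c_1 P + c_2 N + c_3 E}{G}, \qquad
\frac{dE}{dt} = \gamma E \, \frac{N}{N + K}.$$

The square on $\beta$ makes the cross-coupling in the $N$ equation a
nonnegative damping for either sign of $\beta$; the kernel $N/(N+K)$
saturates stress amplification at high $N$. $N(t_0)$ is set to the first
observed entropy value of the $N$-mapped trait, $P(t_0)$ likewise by
default, and $E(t_0)$ is a small positive baseline that can be estimated.
After initialization the system receives no further inputs.

### Parameters, units and defaults

| Parameter | Meaning | Default bounds |
|---|---|---|
| $\mu$ (per yr) | shared baseline influx/persistence of $N$ and $P$ | $[0, 1]$ |
| $\alpha$ | self-limitation of $N$ | $[0, 5]$ |
| $\beta$ | cross-coupling (squared in the $N$ equation) | $[-2, 2]$ |
| $\gamma$ (per yr) | stress amplification rate | $[0, 1]$ |
| $c_1, c_2, c_3$ | metabolic-cost weights | $[0, 20]$ |
| $K$ | stress-kernel saturation constant | $[10^{-3}, 10]$ |
| $G$ | capacity normalization | $[10^{-3}, 10]$ |
| $A$, $\omega$ (rad/yr) | forcing amplitude and frequency | $[0,5]$, $[0, 2\pi]$ |
| $P_0, E_0$ | fittable initial states | $[10^{-4}, 1]$ |

The bounds bracket every parameter value we use in demonstrations with
ample margin; no published source fixes them, so they are a package
convention. $G$ is never specified numerically in the source framework —
it only "sets the capacity scale" — so it defaults to 1 and may be fixed
or freed. The sinusoidal forcing variant adds $A \sin(\omega (t - t_0))$
to the stress component *inside* the cost aggregate (scaled by $c_3$),
leaving the $E$ equation itself unforced; confining the forcing to the
cost term follows the variant's description, and whether $E$'s own ODE
should also be forced is genuinely open — we chose the narrower reading.

### The uncoupled null model

The baseline used for structural contrasts removes every $N \leftrightarrow
P$ pathway: $\beta = c_2 = c_3 = 0$, so $N$ follows a pure logistic law and
$P$ pure exponential persistence while $E$ evolves inertly. This preserves
the initialization and functional class while deleting all coupling, which
is exactly what a "does coupling buy anything?" comparison needs.

## Estimation

Free parameters minimize the summed squared error of both traits at the
observation waves. The optimizer is bounded `L-BFGS-B` with forward-
difference gradients (step $10^{-6}$ per parameter — large enough to sit
well above the $10^{-8}$ relative integration tolerance so difference
quotients are not noise-dominated, small enough for accurate curvature),
restarted from `n_starts` uniform-in-bounds random initializations drawn
sequentially from a seeded stream. Candidate starts whose objective
already sits at the blow-up penalty give a box-bounded quasi-Newton method
a zero gradient and would be wasted, so each is redrawn (up to 20 draws);
because draws are sequential, extending `n_starts` under the same seed
extends the same start sequence, making the best SSE monotone in
`n_starts`. Trial points whose integration fails or exceeds the $10^{12}$
state guard receive a large finite penalty ($10^6$) instead of an
exception, so multistart can continue past pathological corners of the box.

Defaults are `n_starts = 32`, seed 20260319. Fitting is done on the
normalized scale by default (`scale = "norm"`); fitting raw bits is
available because published error metrics for such models are sometimes
ambiguous about scale. The reduced specification
(`ecto_spec_reduced()`) frees $(\mu, \alpha, \gamma, E_0, \beta, c_1)$ and
fixes $c_2 = 0.21$, $c_3 = 0$, $K = 0.5$, $G = 1$ — reference values from
a demonstration parameterization; the source of the reduced fit does not
state its fixed values, so this is a documented convention, not a
reconstruction. Note that with $c_3 = 0$ the stress channel influences
nothing, so $\gamma$ and $E_0$ are structurally unidentifiable in the
reduced fit; they remain in the free set for fidelity to its definition
and simply occupy flat directions.

### Numerical integration

Integration uses deSolve's Dormand–Prince 4(5) adaptive Runge–Kutta with
relative tolerance $10^{-8}$ and absolute $10^{-10}$, with the right-hand
side compiled in C. The model is non-stiff throughout the parameter ranges
used. The test suite verifies the integrator against closed-form
single-channel solutions (exponential, hyperbolic decay
$N_0/(1+\alpha N_0 t)$, exponential stress growth) at $10^{-7}$ and
against an independent fixed-step classical RK4 oracle (step $10^{-3}$ yr
over 25 years) at $10^{-6}$.

## Validation tools

- **Metrics.** RMSE; $R^2 = 1 - \mathrm{SSE}/\mathrm{SStot}$ about the
  observed mean (negative when a fit is worse than a constant — squared
  Pearson is deliberately *not* used); Pearson $r$ with a two-sided
  $t$-test on $n-2$ degrees of freedom (the conventional test; with only
  two points $r$ is reported and the p-value is `NA`); and dynamic time
  warping in its minimal textbook form — absolute-difference local cost,
  unconstrained window, boundary-matched, no path normalization — checked
  in the tests against exhaustive warping-path enumeration.
- **Leave-one-wave-out.** Each wave is held out, the model refit on the
  rest, and the wave predicted by forward simulation from the original
  time origin. Holding out the *first* wave breaks the data-pinned
  initialization, so for that fold $N_0$ and $P_0$ become bounded free
  parameters. Aggregate LOO RMSE pools squared held-out residuals across
  folds before taking the root. Failed folds are flagged and excluded with
  a warning.
- **Sensitivity.** Each free parameter is perturbed $\pm 10\%$ (clamped to
  bounds and flagged if it escapes); total RMSE is re-evaluated either
  with the other parameters held (`perturb_only`) or re-optimized
  (`perturb_refit_others`). Both modes exist because "refitting as needed"
  is underdetermined in the framework's description.

## Synthetic data: what it emulates and what it does not

`generate_likert_waves()` draws multinomial counts from distributions
constructed to hit target entropies exactly. The inverse entropy map uses
a one-parameter exponential tilt over linear category scores,
$p_i(\theta) \propto e^{-\theta (i-1)/(k-1)}$: entropy is strictly
monotone in $\theta$, so root-finding always converges (tolerance
$10^{-6}$ bits). Default conditions mirror the cohorts the framework was
demonstrated on: 5-category items, six waves over 23 years
(0, 3, 9, 13, 19, 23), ~1700 initial respondents declining to about one
third by the final wave (missing-completely-at-random attrition applied to
totals only), per-item entropy paths starting in 1.9–2.3 bits and
declining linearly by 0.05–0.15 bits. The generator does **not** emulate
item covariance, twin/family structure, or informative dropout, so
passing tests say nothing about robustness to nonrandom missingness.

`generate_trajectory_data()` simulates a known parameterization and adds
iid Gaussian noise. The reference truth (`ecto_reference_truth()`) is
$\mu=0.1, \alpha=0.098, \beta=0.2, \gamma=0.15, c_1=0.5, c_2=0.2, c_3=1,
K=0.5, G=1$ from $(N_0, P_0, E_0) = (0.9, 0.9, 0.05)$: a gently declining
coupled system chosen so that states stay within the normalized-entropy
range across the six-wave design and — crucially — the stress pathway is
active ($c_3 > 0$), making $\alpha$, $\beta$ and $\gamma$ all observable.
(Demonstration parameterizations with $c_3 = 0$ leave $\gamma$
structurally invisible and would make recovery experiments meaningless.)

The recovery experiment frees $(\alpha, \beta, \gamma)$ with the rest
fixed at truth, noise sd 0.005 on the normalized scale, 20 seeded
replicates; the structural contrast fits coupled and uncoupled
specifications with equal free-parameter budgets (four each; the
baseline's $\gamma$ and $E_0$ freedoms are structurally inert, which makes
the comparison conservative) on coupled-generated data with noise sd 0.01.

## Problem sizes and determinism

The test suite and the acceptance script use: 32 multistart draws for the
dental fits, 4 for synthetic refits, 3 per leave-one-out fold, 20
replicates for recovery and contrast experiments, and 10 replicates for
the LOO-degradation check. All randomness flows through explicit integer
seeds; RNG state is saved and restored around every seeded draw, so
library calls never perturb a caller's stream, and identical
configuration plus seed reproduces results bit-for-bit.

## Known limitations

- Four to six waves cannot identify eleven parameters; full fits are
  intentionally over-parameterized SSE minimizations whose value is the
  fitted trajectory, not the coefficient vector. Only the multistart SSE
  distribution and the sensitivity scan speak to identifiability, and
  only locally.
- The wave spacing of the bundled dental fixture (one year per academic
  stage) and its category count (5) are conventions carried as
  overridable metadata, not published facts.
- One wave-count inconsistency is inherited from the source cohort
  description (six waves, five listed years); the readers therefore
  impose no fixed wave count anywhere.
- Deterministic, autonomous dynamics only: no stochastic differential
  variant, no time-varying covariates, no individual-level model.
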
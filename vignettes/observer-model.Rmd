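---
title: "The effort-sensitive Bayesian observer behind comreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The effort-sensitive Bayesian observer behind comreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comreach)
library(dplyr)
```

## The task and the scientific question

A subject reaches to the balance point of a visual dumbbell: two disks
24 cm apart joined by a thin bar. On a third of trials the disks are
equal and the target is the bar midpoint (low uncertainty); otherwise
the radius ratio is drawn log-normally (mean log 1.5, SD 0.1 in log
space) and the target location requires a nonlinear judgment (high
uncertainty). During the reach the cursor is hidden; on some trials it
reappears displaced by a covert perturbation `b` (mean ±0.5 or ±1.5 cm,
SD 0.2 cm, truncated at 2.5 SD). The subject then has ample time to
adjust before the final cursor position is scored with
`Score(Δs) = Round(10 exp(−Δs²/2σ²_score))`, where the length scale
`σ_score = 1/sqrt(2 ln 20) ≈ 0.41` cm is fixed by requiring a maximum of
10 and a nonzero score exactly up to 1 cm.

The scientific question is why people correct fully for the perturbation
when the target is certain but only partially when it is not, even with
unlimited time. The package implements a Bayesian observer in which the
answer is an effort term in the loss function: when the posterior over
the target is wide, the expected score gain from adjusting is small and
the effort cost wins, so corrections are left incomplete — a
minimal-intervention account of online error correction.

## The observer model

**Perception.** The observer estimates the log radius ratio
`ρ = log(r₂/r₁)`. A measurement `ρ_m ~ N(ρ, σ²_ρ)` is combined with a
prior equal to the stimulus statistics: a mixture of a delta at 0
(weight 1/3) and Gaussians at ±log 1.5 with SD 0.1. Conjugate algebra
gives a Gaussian-mixture posterior whose delta components stay deltas
(`sd = 0` encodes them exactly; no jitter is ever added). Posterior
component weights are proportional to prior weight times the predictive
density of `ρ_m`; these closed forms are validated in the tests against
direct numerical integration of the measurement model times the prior
(tolerance 1e-8).

**Mapping to the target.** Mass proportional to `radius^D` at the bar
ends gives the balance point `f_D(ρ) = (ℓ/2) tanh(Dρ/2)`, which is the
closed form of the mass-weighted average; `D = 2` is veridical for
disks but the observer's exponent is a free parameter. The posterior is
pushed through `f_D` component by component. Because `f_D` is nonlinear
the image of a Gaussian is not Gaussian; each output component keeps
the exact first two moments of the mapped component, computed by
31-node Gauss–Hermite quadrature rather than linearization, which is
faithful where `f_D` curves (means acquire a curvature correction that
the tests check against dense numerical moments).

**Decision.** Endpoints are chosen under an inverted-Gaussian error
loss with scale `σ_err` tied to the score length scale. The preliminary
endpoint maximizes the posterior-expected error gain; after the reach
arrives at `r0 = s_pre + b`, the final endpoint maximizes

    α · exp(−(ŝ − r0)² / 2σ²_adj) + E_post[exp(−(ŝ − s)² / 2σ²_err)],

an effort (adjustment) term plus the error term. With `α = 0` the two
stages coincide; large `α` pins the endpoint at `r0`. A wide posterior
flattens the error term, so the same `α` leaves more of the
perturbation uncorrected on high-uncertainty trials — the model's core
mechanism, covered by a property test showing the uncorrected fraction
grows monotonically with posterior width. Gaussian motor noise
`σ_motor` is added to the final choice.

**Response probability.** The likelihood of a response marginalizes the
decision over the unobserved measurement with 61-node Gauss–Hermite
quadrature in `ρ_m`. The density normalizes by construction; tests
check quadrature-vs-sampler agreement (Kolmogorov–Smirnov distance
below 0.02 at n = 10⁴) and agreement with a Rao–Blackwellized
Monte-Carlo estimate of the marginal.

## Numerical choices

- **1-D endpoint optimization.** The objectives are smooth but can be
  multimodal (mixture posteriors), so both endpoint stages use a
  deterministic dense grid over the bar (0.01 cm in the user-facing
  functions) with one parabolic refinement step; near-ties resolve
  toward the smaller |ŝ| and flat objectives return the midpoint of the
  maximizing set with a diagnostic flag. Tests compare against
  brute-force 0.001 cm grids.
- **Per-node decision caches inside the likelihood.** The likelihood of
  a candidate parameter vector needs the two-stage decision at every
  quadrature node of every trial. An early design interpolated decisions
  from a `(ρ_m, r0)` lattice, but the (α, σ_adj) likelihood ridge turned
  out to be shallower than the interpolation error, which visibly tilted
  estimates; the released scheme is interpolation-free. For each
  candidate mapping exponent `D`, every node's preliminary endpoint and
  its expected-error-gain curve are computed exactly on the decision
  grid and the curve is cached over a window around the endpoint
  (`[s_pre + min(b,0) − m, s_pre + max(b,0) + m]` with margin
  `m = 3` cm — wide enough that no adjusted optimum ever leaves it, as
  an explicit test verifies against full-bar searches across extreme
  effort weights). Candidate `(α, σ_adj)` values then only pay for
  adding the adjustment term to the cached curves. Gaussian rows are
  evaluated by a multiplicative recurrence (two `exp` calls per row
  instead of one per grid point), checked against the plain evaluation
  to 1e-13.
- **Maximum likelihood.** `σ_ρ` comes from a separate fit of the
  training session (no perturbations, feedback on every trial), where
  the adjustment cost is inert and `α` is fixed at 0 while `D` and
  `σ_motor` are profiled nuisance parameters; only `σ_ρ` is carried to
  the test-session fit. The test fit profiles `D` by a coarse-then-fine
  1-D search; at each `D` the adjustment-loss parameters are optimized
  by Nelder–Mead in the ridge-aligned coordinates `(log(α/σ²_adj),
  log σ_adj)` — the likelihood forms a banana-shaped ridge along which
  the near-`r0` curvature `α/σ²_adj` is well identified while `σ_adj`
  itself is only weakly identified, and aligning the ridge with a
  coordinate axis is what lets a derivative-free simplex traverse it —
  from Latin-hypercube restarts warm-started along the `D` search, plus
  a dedicated `α = 0` (full-correction) branch at every `D`. `σ_motor`
  is profiled by a 1-D search for every candidate, matching its role as
  a residual scale. Fits reaching the upper `σ_adj` bound are reported
  as flat-adjustment observers (`σ_adj = ∞`), and estimates pinned at
  the `σ_ρ` search boundary are flagged, never silently returned.

## The synthetic cohort

`generate_session()` reproduces the experiment's design exactly: 120
feedback training trials, then 576 test trials (192 standard, 192 small
and 192 large perturbations). Stimulus and perturbation draws follow
the stated distributions; the side of the larger disk and perturbation
signs are counterbalanced exactly within blocks (36 test trials; 12
training trials, since 120 is not divisible by 36), and trial
composition within a block is exact rather than binomial so that
counterbalancing holds at the block level. The base radius is drawn
first and the log-normal ratio multiplies it to form the larger disk on
the counterbalanced side. Display jitter is generated and stored for
fidelity but all analysis coordinates are midpoint-relative, so it is
inert downstream. Missed-trial re-presentation and all kinematics
(trajectories, exit positions, adjustment times) are out of scope: a
trial is an endpoint.

What the generator does *not* emulate: learning or adaptation across
trials, trial-to-trial dependencies, lapses, and any within-movement
feedback dynamics. Passing tests therefore show that the pipeline and
fits behave correctly in the model's own world — including the
stationarity assumptions real subjects may violate — not that the model
is true of any particular dataset.

A note on realized statistics: a cohort simulated at the group-level
fitted parameters reproduces the *pattern* of the behavioral findings
(near-full correction at low uncertainty, partial at high, no material
score cost of the uncorrected errors) but not every printed magnitude;
for example the model's single residual scale `σ_motor` makes
low-uncertainty responses more variable than real subjects' were. That
is a property of the fitted model itself, visible in its own world.

## Fitting and recovery at desk scale

Parameter recovery — simulate a 16-subject cohort at the group
parameter values (`σ_ρ = 0.063`, `D = 1.94`, `α = 3.1`,
`σ_adj = 2.8` cm, `σ_motor = 0.76` cm), refit every subject, and
compare group means to truth — is the package's primary validation of
the fitting machinery and runs in the acceptance test suite. The
(α, σ_adj) pair deserves comment: their likelihood ridge is shallow
(hundreds of trials barely distinguish `σ_adj = 2.8` from much larger
values), so individual maximum-likelihood estimates scatter
*multiplicatively* along the ridge, with a minority reaching the
flat-adjustment region; this mirrors the boundary fits (`σ_adj → ∞`)
reported for some subjects in this paradigm. Because of that
multiplicative scatter the recovery check summarizes the two loss
scale parameters geometrically (on the log scale they are searched on,
over all subjects — excluding boundary fits would select the low side
of the ridge and bias the summary), while `σ_ρ`, `D` and `σ_motor`,
whose estimates are tight and symmetric, are summarized
arithmetically; each must cover truth within two between-subject
standard errors.
Problem sizes used in the tests (restart counts, Monte-Carlo sizes,
one-subject fixtures for the cheaper checks) are chosen so the whole
suite runs comfortably on a laptop core.

## Known limitations

- The adjustment-loss shape is only weakly constrained by endpoint
  data; the power-law variant is included precisely because it is
  empirically indistinguishable from the inverted-Gaussian form.
- The ideal-observer benchmark treats "full compensation for movement
  error" as `σ_motor = 0`.
- The miscalibrated-cursor control is parameterized minimally (a gain
  on the perceived correction distance); richer miscalibration models
  would still share its defining failure, uncertainty-independent
  slopes.
- The MAT import adapter discovers container layouts heuristically and
  refuses, with a listing, anything it cannot interpret; it never
  guesses.

## A worked example

```{r example, eval = FALSE}
params <- group_fit_params()
cohort <- simulate_cohort(params, n_subjects = 4, seed = 1)
test <- filter(cohort, phase == "test")

slope_regression(test) |>
  group_by(uncertainty_class) |>
  summarise(slope = mean(slope))

fit <- fit_test(filter(test, subject_id == "S01"), sigma_rho = 0.063)
tidy(fit)
```
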
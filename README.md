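# comreach

Bayesian observer models of uncertainty-dependent error correction in a
center-of-mass reaching task.

## The problem

People reaching to the balance point of a visual dumbbell (two disks on
a 24 cm bar) correct covert perturbations of the cursor *fully* when
the target is certain (equal disks: line bisection) but only
*partially* when it is uncertain (unequal disks) — even with unlimited
time to adjust, and in a way that costs them essentially no points.
`comreach` implements the model that explains this: a Bayesian observer
whose loss function contains an effort (adjustment) cost alongside the
task's error cost, so corrections are worth making only insofar as the
posterior over the target says they will pay off — a minimal-
intervention account of online error correction.

The package is aimed at computational sensorimotor researchers who want
to simulate the paradigm, fit the observer to trial tables, run the
full residual-error/slope/score analysis pipeline, and stress-test the
model against its standard alternatives.

## The model

A trial shows disks with log radius ratio `ρ = log(r₂/r₁)`. The
observer receives `ρ_m ~ N(ρ, σ²_ρ)`, combines it with the trimodal
stimulus prior (delta at 0 with weight 1/3; Gaussians at ±log 1.5, SD
0.1), and maps beliefs to center-of-mass space through
`f_D(ρ) = (ℓ/2) tanh(Dρ/2)` (masses ∝ radiusᴰ). Endpoints minimize an
inverted-Gaussian error loss with scale `σ_err` tied to the scoring
rule `Score(Δs) = Round(10 e^{−Δs²/2σ²_score})`, `σ_score = 1/√(2 ln 20)`.
After the reach arrives at `r0 = s*_pre + b` (perturbation `b`), the
final position maximizes

    α exp(−(ŝ − r0)²/2σ²_adj) + E_post[exp(−(ŝ − s)²/2σ²_err)],

and Gaussian motor noise `σ_motor` is added. The response likelihood
marginalizes the two-stage decision over `ρ_m` (Gauss–Hermite
quadrature); per-subject fits are maximum likelihood with `σ_ρ`
estimated from the training session. Alternative observers (quadratic
error loss, power-law adjustment loss, miscalibrated cursor) are
included as the standard controls.

## A worked example

```r
library(comreach)
library(dplyr)

params <- group_fit_params()     # sigma_rho 0.063, D 1.94, alpha 3.1,
                                 # sigma_adj 2.8 cm, sigma_motor 0.76 cm
cohort <- simulate_cohort(params, n_subjects = 16, seed = 101)
test   <- filter(cohort, phase == "test")

slope_regression(test) |>
  group_by(uncertainty_class) |>
  summarise(slope = mean(slope), se = sd(slope) / sqrt(n()))
#> # A tibble: 2 × 3
#>   uncertainty_class  slope     se
#>   <chr>              <dbl>  <dbl>
#> 1 high              0.225  0.0104
#> 2 low               0.0713 0.0139
```

The slope is the fraction of the perturbation left uncorrected: near
zero on equal-disk (low-uncertainty) trials, several times larger on
unequal-disk (high-uncertainty) trials — the signature of an effort
cost weighted against posterior width. The ideal-observer benchmark
(veridical `D = 2`, no effort cost, no motor noise) bounds achievable
scores:

```r
expected_score(ideal_observer_params(0.063), "low",  n_sim = 1e5, seed = 1)
#>   mean_score 9.88
expected_score(ideal_observer_params(0.063), "high", n_sim = 1e5, seed = 2)
#>   mean_score 5.90
```

Fitting a subject and inspecting the estimates:

```r
fit <- fit_test(filter(test, subject_id == "S01"),
                sigma_rho = 0.063)
tidy(fit)
```

See `vignettes/observer-model.Rmd` for the model's assumptions, the
numerical scheme behind the likelihood, and what the synthetic cohort
does and does not emulate.

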
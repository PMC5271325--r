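# Shared fixtures, built in code. Heavier objects are memoized so that
# several test files can reuse the same simulated cohort.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small simulated subject at the group-level parameter values
fixture_subject <- function() {
  memo("subject", {
    ses <- generate_session(subject_id = "S01", seed = 401)
    simulate_responses(ses, group_fit_params(), seed = 402)
  })
}

# random Gaussian mixtures in com space, for optimizer property tests
random_com_mixture <- function() {
  k <- sample(1:3, 1)
  gaussian_mixture(
    weight = runif(k, 0.1, 1),
    mean = runif(k, -6, 6),
    sd = c(0, runif(k, 0.1, 2))[sample(c(1, rep(2, 9)), k, replace = TRUE)],
    space = "com"
  )
}

# brute-force dense-grid argmax, independent of the package's optimizer
brute_argmax <- function(f, lower, upper, step = 0.001) {
  grid <- seq(lower, upper, by = step)
  grid[which.max(f(grid))]
}

fast_ctrl <- function(...) {
  args <- utils::modifyList(list(n_restarts = 2, maxit = 60), list(...))
  do.call(fit_control, args)
}

# a small full-correction (alpha = 0) cohort for null-pattern checks
fixture_null_cohort <- function() {
  memo("null_cohort", {
    p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                          sigma_adj = Inf, sigma_motor = 0.5)
    simulate_cohort(p0, n_subjects = 4, seed = 403) |>
      dplyr::filter(phase == "test")
  })
}
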
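test_that("the marginal likelihood collapses correctly without sensory
           noise", {
  p <- observer_params(sigma_rho = 1e-8, dim_d = 2.2, alpha = 0,
                       sigma_adj = Inf, sigma_motor = 0.6)
  trials <- tibble::tibble(rho = c(-0.3, 0, 0.4), b_cm = 0,
                           r_cm = c(-3, 0.5, 4.2))
  ll <- trial_loglik(trials, p)
  expect_equal(ll, dnorm(trials$r_cm, com_map(trials$rho, 2.2), 0.6,
                         log = TRUE), tolerance = 1e-6)
})

test_that("per-trial likelihoods integrate to one over the response", {
  set.seed(91)
  for (i in 1:4) {
    p <- observer_params(sigma_rho = runif(1, 0.03, 0.12),
                         dim_d = runif(1, 1.5, 2.5),
                         alpha = runif(1, 0, 4), sigma_adj = runif(1, 1, 4),
                         sigma_motor = runif(1, 0.4, 1))
    rho <- runif(1, -0.6, 0.6)
    b <- sample(c(-1.5, 0, 1.5), 1)
    total <- integrate(function(r) {
      exp(trial_loglik(tibble::tibble(rho = rho, b_cm = b, r_cm = r), p))
    }, -13, 13, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
})

test_that("the quadrature likelihood matches a Monte-Carlo estimate", {
  # oracle: Rao-Blackwellized MC marginalization over the internal
  # measurement, independent of the quadrature path
  set.seed(92)
  p <- group_fit_params()
  for (i in 1:6) {
    rho <- runif(1, -0.6, 0.6)
    b <- sample(c(-1.5, -0.5, 0, 0.5, 1.5), 1)
    r <- runif(1, com_map(rho, 2) - 2, com_map(rho, 2) + 2)
    n_mc <- 20000
    rm <- rnorm(n_mc, rho, p$sigma_rho)
    dec <- comreach:::decide_trials_cpp(rm, rep(b, n_mc), p)
    contrib <- dnorm(r, dec$s_star, p$sigma_motor)
    mc <- mean(contrib)
    mc_se <- sd(contrib) / sqrt(n_mc)
    ll <- trial_loglik(tibble::tibble(rho = rho, b_cm = b, r_cm = r), p)
    # the quadrature integrand jumps where the posterior mode switches,
    # so Gauss-Hermite carries a small residual bias there: allow Monte
    # Carlo noise plus a few percent of the density value
    expect_lt(abs(exp(ll) - mc), 4 * mc_se + 0.05 * mc + 1e-4)
  }
})

test_that("the likelihood is invariant under a left/right flip", {
  p <- group_fit_params()
  trials <- tibble::tibble(rho = c(0.4, -0.2, 0), b_cm = c(1.5, -0.5, 0.5),
                           r_cm = c(4.5, -2.2, 0.7))
  flipped <- dplyr::mutate(trials, rho = -rho, b_cm = -b_cm, r_cm = -r_cm)
  expect_equal(trial_loglik(trials, p), trial_loglik(flipped, p),
               tolerance = 1e-8)
})

test_that("the windowed node cache reproduces the exact decision path", {
  resp <- dplyr::filter(fixture_subject(), phase == "test")
  sub <- resp[seq(1, 576, by = 7), ]
  p <- group_fit_params()
  ctrl <- fit_control()
  lay <- comreach:::node_layout(sub, p$sigma_rho, ctrl$n_nodes)
  setup <- comreach:::node_setup(lay, p$sigma_rho, p$dim_d, p$sigma_err,
                                 task_geometry(), prior_log_ratio(), ctrl)
  ss <- comreach:::cpp_star_from_setup(setup, lay$b, p$alpha,
                                       p$inv_sigma_adj,
                                       ctrl$window_margin)
  ll_win <- sum(comreach:::cpp_density_from_star(sub$r_cm, ss, lay$gh$w,
                                                 p$sigma_motor))
  ll_exact <- sum(trial_loglik(sub, p))
  expect_equal(ll_win / nrow(sub), ll_exact / nrow(sub), tolerance = 1e-3)

  # the windowed endpoints themselves match the full-bar decisions
  dec <- comreach:::decide_trials_cpp(lay$rho_m, lay$b, p)
  expect_lt(stats::median(abs(ss - dec$s_star)), 0.01)
  expect_lt(mean(abs(ss - dec$s_star) > 0.05), 0.01)
})

test_that("training fits recover sensory noise from feedback trials", {
  ses <- generate_session(seed = 93)
  train <- dplyr::filter(ses, phase == "training")
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                       sigma_adj = Inf, sigma_motor = 0.76)
  resp <- simulate_responses(train, p, seed = 94)
  ft <- fit_training(resp, control = fast_ctrl(), seed = 95)
  expect_false(ft$boundary)
  expect_gt(ft$params$sigma_rho, 0.03)
  expect_lt(ft$params$sigma_rho, 0.11)
  expect_equal(ft$params$dim_d, 2, tolerance = 0.25)
  expect_true(all(c("alpha", "sigma_adj") %in% ft$fixed_fields))

  # near-noiseless data pin the estimate at the boundary, flagged
  quiet <- simulate_responses(train, observer_params(
    sigma_rho = 1e-4, dim_d = 2, alpha = 0, sigma_adj = Inf,
    sigma_motor = 0.3), seed = 96)
  expect_warning(ftq <- fit_training(quiet, control = fast_ctrl(), seed = 97),
                 "boundary")
  expect_true(ftq$boundary)
})

test_that("fit results expose tidy and glance summaries", {
  ses <- generate_session(seed = 98)
  train <- dplyr::filter(ses, phase == "training")
  resp <- simulate_responses(train, observer_params(
    sigma_rho = 0.063, dim_d = 2, alpha = 0, sigma_adj = Inf,
    sigma_motor = 0.76), seed = 99)
  ft <- fit_training(resp, control = fast_ctrl(n_restarts = 2, maxit = 40),
                     seed = 100)
  td <- tidy(ft)
  expect_setequal(td$term, c("sigma_rho", "dim_d", "alpha", "sigma_adj",
                             "sigma_motor", "sigma_err"))
  expect_true(td$fixed[td$term == "alpha"])
  gl <- glance(ft)
  expect_equal(gl$n_trials, 120)
  expect_true(is.finite(gl$loglik))
})

test_that("predicted slopes respond to the effort weight as expected", {
  none <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                          sigma_adj = Inf, sigma_motor = 0.5)
  sl0 <- predict_slopes(none, n_sessions = 1, seed = 101)
  expect_lt(max(abs(sl0)), 0.06)

  all_effort <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 1e9,
                                sigma_adj = 2.8, sigma_motor = 0.5)
  sl1 <- predict_slopes(all_effort, n_sessions = 1, seed = 102)
  expect_equal(unname(sl1), c(1, 1), tolerance = 0.08)

  slg <- predict_slopes(group_fit_params(), n_sessions = 2, seed = 103)
  expect_gt(slg[["high"]], slg[["low"]])
})
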
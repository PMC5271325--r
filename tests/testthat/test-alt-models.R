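test_that("quadratic error loss depends on the posterior only through its
           mean", {
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 2,
                       sigma_adj = 2.8, sigma_motor = 0.5)
  narrow <- gaussian_mixture(1, 1.2, 0.1, space = "com")
  wide <- gaussian_mixture(1, 1.2, 2.0, space = "com")
  for (r0 in c(-2, 0.5, 3)) {
    expect_identical(
      as.numeric(quadratic_adjusted_endpoint(narrow, r0, p)),
      as.numeric(quadratic_adjusted_endpoint(wide, r0, p))
    )
  }
  # mixtures with equal means but different shapes agree too
  mix <- gaussian_mixture(c(0.5, 0.5), c(0, 2.4), c(0.3, 0.3),
                          space = "com")
  point <- gaussian_mixture(1, 1.2, 0.01, space = "com")
  expect_equal(as.numeric(quadratic_adjusted_endpoint(mix, 2, p)),
               as.numeric(quadratic_adjusted_endpoint(point, 2, p)),
               tolerance = 1e-6)
})

test_that("quadratic variant collapses to the posterior mean at alpha 0 and
           to an affine optimum in the quadratic-adjustment limit", {
  p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                        sigma_adj = 2.8, sigma_motor = 0.5)
  gm <- gaussian_mixture(c(0.3, 0.7), c(-1, 2), c(0.5, 1.5), space = "com")
  mu <- sum(gm$weight * gm$mean)
  expect_equal(as.numeric(quadratic_adjusted_endpoint(gm, 3, p0)), mu,
               tolerance = 1e-6)

  # wide inverted-Gaussian adjustment ~ quadratic with curvature
  # alpha / (2 sigma_adj^2): closed-form weighted mean
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 5,
                       sigma_adj = 40, sigma_motor = 0.5)
  lambda <- p$alpha / (2 * p$sigma_adj^2)
  r0 <- 3
  expect_equal(as.numeric(quadratic_adjusted_endpoint(gm, r0, p)),
               (mu + lambda * r0) / (1 + lambda), tolerance = 1e-3)
})

test_that("power-law adjustment keeps the uncertainty modulation", {
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0.15,
                       sigma_adj = Inf, sigma_motor = 0.5)
  # alpha = 0 reduces to the preliminary endpoint
  gm <- gaussian_mixture(1, 0, 0.6, space = "com")
  p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                        sigma_adj = Inf, sigma_motor = 0.5)
  expect_identical(as.numeric(power_adjusted_endpoint(gm, 1.5, p0, 2)),
                   as.numeric(preliminary_endpoint(gm)))
  # wider posteriors leave a larger fraction uncorrected
  unc <- vapply(c(0.2, 0.6, 1.2, 2), function(s) {
    g <- gaussian_mixture(1, 0, s, space = "com")
    as.numeric(power_adjusted_endpoint(g, 1.5, p, 2)) / 1.5
  }, numeric(1))
  expect_true(all(diff(unc) > 0))
})

test_that("miscalibrated observers correct the same fraction in both
           classes", {
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                       sigma_adj = Inf, sigma_motor = 0)
  # perfect calibration: full correction, endpoint at the planned target
  out <- miscalibrated_response(c(0, 0.4), 1.5, p,
                                calibration = list(gain = 1, offset = 0))
  expect_equal(out$s_star, out$s_pre, tolerance = 1e-12)
  # gain < 1: the uncorrected fraction is exactly 1 - gain regardless of
  # the stimulus class (direct algebra on the response rule)
  for (rm in c(0, -0.4, 0.45)) {
    out2 <- miscalibrated_response(rm, 1.5, p,
                                   calibration = list(gain = 0.84,
                                                      offset = 0))
    expect_equal(out2$s_star - out2$s_pre, (1 - 0.84) * 1.5,
                 tolerance = 1e-9)
  }
})

test_that("alternative-variant simulations produce the expected slope
           patterns on small cohorts", {
  ses <- generate_session(seed = 81)
  test_rows <- which(ses$phase == "test")
  p <- group_fit_params()

  # quadratic error loss: equal slopes in both classes
  resp_q <- simulate_responses_variant(ses[test_rows, ],
                                       observer_params(
                                         sigma_rho = 0.063, dim_d = 2,
                                         alpha = 0.25, sigma_adj = 2.8,
                                         sigma_motor = 0.3),
                                       variant = "quadratic_error",
                                       seed = 82)
  sl_q <- slope_regression(resp_q)
  expect_lt(abs(diff(sl_q$slope)), 0.06)

  # miscalibrated cursor: equal, nonzero slopes in both classes
  p_mis <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                           sigma_adj = Inf, sigma_motor = 0.25)
  resp_m <- simulate_responses_variant(ses[test_rows, ], p_mis,
                                       variant = "miscalibrated",
                                       calibration = list(gain = 0.84,
                                                          offset = 0),
                                       seed = 83)
  sl_m <- slope_regression(resp_m)
  expect_lt(max(abs(sl_m$slope - 0.16)), 0.05)
  expect_lt(abs(diff(sl_m$slope)), 0.06)
})

test_that("the calibrated power loss mimics the inverted-Gaussian one", {
  p <- group_fit_params()
  a_pow <- calibrate_power_loss(p, gamma = 2, posterior_sd = 1)
  p_pow <- p
  p_pow$alpha <- a_pow
  post <- gaussian_mixture(1, 0, 1, space = "com")
  for (r0 in c(-1.5, 0.8, 2)) {
    expect_equal(
      as.numeric(power_adjusted_endpoint(post, r0, p_pow, 2)),
      as.numeric(adjusted_endpoint(post, r0, p)),
      tolerance = 0.12
    )
  }
})
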
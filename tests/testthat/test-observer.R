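test_that("preliminary endpoint maximizes the expected score objective", {
  # single component: the optimum is its mean
  g1 <- gaussian_mixture(1, 2.3, 0.8, space = "com")
  expect_equal(as.numeric(preliminary_endpoint(g1)), 2.3, tolerance = 1e-6)

  # symmetric bimodal posterior: stationary at 0; whether the center or
  # the modes win depends on separation vs width - decided by the oracle
  se <- score_config()$sigma_score
  for (s in c(0.5, 3)) {
    g2 <- gaussian_mixture(c(1, 1) / 2, c(-4.6, 4.6), c(s, s),
                           space = "com")
    obj <- function(x) {
      vapply(x, function(xi) {
        sum(g2$weight * dnorm(xi, g2$mean, sqrt(g2$sd^2 + se^2)))
      }, numeric(1))
    }
    got <- as.numeric(preliminary_endpoint(g2))
    want <- brute_argmax(obj, -12, 12)
    expect_equal(abs(got), abs(want), tolerance = 2e-3)
  }

  # with a central measurement and the task prior, the delta dominates
  post <- posterior_com(posterior_rho(0, prior_log_ratio(), 0.063), 2)
  expect_equal(as.numeric(preliminary_endpoint(post)), 0, tolerance = 1e-3)
})

test_that("flat objectives are flagged and resolved to the midpoint", {
  wide <- gaussian_mixture(1, 0, 1e9, space = "com")
  out <- preliminary_endpoint(wide)
  expect_true(attr(out, "flat"))
  expect_equal(as.numeric(out), 0)
})

test_that("adjusted endpoint reduces to the preliminary one at alpha = 0", {
  set.seed(31)
  p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                        sigma_adj = 2.8, sigma_motor = 0.5)
  for (i in 1:20) {
    gm <- random_com_mixture()
    r0 <- runif(1, -8, 8)
    expect_identical(as.numeric(adjusted_endpoint(gm, r0, p0)),
                     as.numeric(preliminary_endpoint(gm)))
  }
})

test_that("a dominant adjustment cost pins the endpoint at r0", {
  p_inf <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 1e9,
                           sigma_adj = 2.8, sigma_motor = 0.5)
  gm <- gaussian_mixture(1, 0, 0.54, space = "com")
  expect_equal(as.numeric(adjusted_endpoint(gm, 1.5, p_inf)), 1.5,
               tolerance = 0.02)
})

test_that("partial correction falls strictly between target and arrival", {
  # the reference configuration: wide posterior, moderate effort weight
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 3.1,
                       sigma_adj = 2.8, sigma_motor = 0.5)
  gm <- gaussian_mixture(1, 0, 0.54, space = "com")
  got <- as.numeric(adjusted_endpoint(gm, 1.5, p))
  expect_gt(got, 0)
  expect_lt(got, 1.5)
  # dense-grid oracle at 0.001 cm
  se <- p$sigma_err
  obj <- function(x) {
    p$alpha * exp(-(x - 1.5)^2 / (2 * p$sigma_adj^2)) +
      se / sqrt(0.54^2 + se^2) * exp(-x^2 / (2 * (0.54^2 + se^2)))
  }
  expect_equal(got, brute_argmax(obj, -12, 12), tolerance = 2e-3)
})

test_that("corrections shrink monotonically as the effort weight grows", {
  set.seed(32)
  for (i in 1:15) {
    gm <- random_com_mixture()
    r0 <- runif(1, -6, 6)
    gaps <- vapply(c(0, 0.5, 1.5, 4, 10), function(a) {
      p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = a,
                           sigma_adj = 2.8, sigma_motor = 0.5)
      abs(as.numeric(adjusted_endpoint(gm, r0, p)) - r0)
    }, numeric(1))
    expect_true(all(diff(gaps) <= 1e-6))
  }
})

test_that("wider posteriors leave more of the perturbation uncorrected", {
  # the core mechanism: at fixed effort parameters the correction gain
  # decreases with posterior width
  p <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 3.1,
                       sigma_adj = 2.8, sigma_motor = 0.5)
  r0 <- 1.5
  uncorrected <- vapply(c(0.2, 0.4, 0.8, 1.2, 2), function(s) {
    gm <- gaussian_mixture(1, 0, s, space = "com")
    as.numeric(adjusted_endpoint(gm, r0, p)) / r0
  }, numeric(1))
  expect_true(all(diff(uncorrected) > 0))
})

test_that("compiled and reference decision paths agree", {
  set.seed(33)
  p <- group_fit_params()
  rho_m <- runif(12, -0.7, 0.7)
  b <- sample(c(-1.5, -0.5, 0, 0.5, 1.5), 12, replace = TRUE)
  cpp <- comreach:::decide_trials_cpp(rho_m, b, p)
  ref <- purrr::map2_dfr(rho_m, b, decide_endpoint, params = p)
  expect_equal(cpp$s_pre, ref$s_pre, tolerance = 2e-3)
  expect_equal(cpp$s_star, ref$s_star, tolerance = 2e-3)
})

test_that("the marginal response density normalizes and concentrates", {
  p <- observer_params(sigma_rho = 1e-8, dim_d = 2, alpha = 0,
                       sigma_adj = Inf, sigma_motor = 0.3)
  rd <- response_distribution(0.3, 0, p)
  # noiseless measurement: mass concentrates at com_map(rho) with the
  # motor sd
  mu <- com_map(0.3, 2)
  expect_equal(rd$density(mu), dnorm(0, 0, 0.3), tolerance = 1e-3)
  expect_equal(integrate(rd$density, mu - 4, mu + 4)$value, 1,
               tolerance = 1e-6)

  set.seed(34)
  for (i in 1:5) {
    p2 <- observer_params(sigma_rho = runif(1, 0.02, 0.15),
                          dim_d = runif(1, 1, 3),
                          alpha = runif(1, 0, 4),
                          sigma_adj = runif(1, 1, 5),
                          sigma_motor = runif(1, 0.3, 1.2))
    rd2 <- response_distribution(runif(1, -0.6, 0.6),
                                 sample(c(-1.5, 0, 1.5), 1), p2)
    expect_equal(integrate(rd2$density, -13, 13, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("zero motor noise blocks density evaluation, not sampling", {
  p <- ideal_observer_params()
  rd <- response_distribution(0.2, 0, p)
  expect_error(rd$density(0), class = "comreach_degenerate_density")
  set.seed(35)
  expect_length(rd$sample(50), 50)
})

test_that("expected score behaves in its analytic limits", {
  # perfect observer: no sensory or motor noise -> maximum score always
  perfect <- observer_params(sigma_rho = 1e-9, dim_d = 2, alpha = 0,
                             sigma_adj = Inf, sigma_motor = 0)
  es <- expected_score(perfect, "high", n_sim = 400, seed = 41)
  expect_equal(es$mean_score, 10, tolerance = 1e-6)

  # pure Gaussian response error: mean unrounded score matches the
  # closed form max * s / sqrt(s^2 + sd^2)
  noisy <- observer_params(sigma_rho = 1e-9, dim_d = 2, alpha = 0,
                           sigma_adj = Inf, sigma_motor = 0.6)
  es2 <- expected_score(noisy, "low", n_sim = 40000, seed = 42,
                        config = score_config(rounding = FALSE))
  expect_equal(es2$mean_score, gaussian_expected_score(0.6),
               tolerance = 0.03)
})
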
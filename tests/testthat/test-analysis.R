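test_that("baseline subtraction centers unperturbed trials exactly", {
  resp <- dplyr::filter(fixture_subject(), phase == "test")
  adj <- baseline_subtract(resp)
  base <- adj |>
    dplyr::filter(perturbation_level == 0) |>
    dplyr::group_by(subject_id, uncertainty) |>
    dplyr::summarise(m = mean(delta_adj), .groups = "drop")
  expect_true(all(abs(base$m) < 1e-12))
})

test_that("baseline subtraction leaves slopes untouched", {
  # the subtraction removes a per-subject, per-class constant, so the
  # regression slope is unchanged exactly
  resp <- dplyr::filter(fixture_subject(), phase == "test")
  adj <- baseline_subtract(resp)
  for (u in c("low", "high")) {
    d <- dplyr::filter(adj, uncertainty == u)
    with_base <- coef(lm(delta_adj ~ b_p, data = d))[["b_p"]]
    without <- coef(lm(delta_p ~ b_p, data = d))[["b_p"]]
    expect_equal(with_base, without, tolerance = 1e-10)
  }
})

test_that("records without unperturbed trials are rejected", {
  resp <- dplyr::filter(fixture_subject(), phase == "test",
                        perturbation_level != 0)
  expect_error(baseline_subtract(resp), class = "comreach_invalid_parameter")
})

test_that("slope regression recovers a constructed uncorrected fraction", {
  ses <- generate_session(seed = 61)
  test <- dplyr::filter(ses, phase == "test")
  set.seed(62)
  # responses leaving exactly 16% of the perturbation uncorrected
  resp <- dplyr::mutate(test, subject_id = "S01",
                        r_cm = s_true_cm + 0.16 * b_cm + rnorm(dplyr::n(), 0, 0.2),
                        delta_s_cm = r_cm - s_true_cm,
                        score = ifelse(feedback, score_points(delta_s_cm), NA))
  sl <- slope_regression(resp)
  expect_lt(max(abs(sl$slope - 0.16)), 0.04)

  # invariance under a global left/right relabeling
  flipped <- dplyr::mutate(resp,
                           rho = -rho, s_true_cm = -s_true_cm, b_cm = -b_cm,
                           perturbation_level = -perturbation_level,
                           r_cm = -r_cm, delta_s_cm = -delta_s_cm,
                           uncertainty_class = dplyr::case_match(
                             uncertainty_class,
                             "high-left" ~ "high-right",
                             "high-right" ~ "high-left",
                             .default = uncertainty_class))
  expect_equal(slope_regression(flipped)$slope, sl$slope, tolerance = 1e-9)
})

test_that("a full-correction observer shows near-zero slopes", {
  ses <- generate_session(seed = 63)
  p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                        sigma_adj = Inf, sigma_motor = 0.5)
  resp <- simulate_responses(ses, p0, seed = 64) |>
    dplyr::filter(phase == "test")
  sl <- slope_regression(resp)
  expect_lt(max(abs(sl$slope)), 0.05)
})

test_that("condition summaries report the defined statistics", {
  ses <- generate_session(seed = 65)
  test <- dplyr::filter(ses, phase == "test")
  perfect <- dplyr::mutate(test, subject_id = "S01", r_cm = s_true_cm,
                           delta_s_cm = 0,
                           score = ifelse(feedback, 10, NA))
  cs <- condition_summaries(perfect)
  expect_true(all(cs$group$group_mean[cs$group$metric == "sd_delta"] == 0))
  expect_true(all(cs$group$group_mean[grepl("score", cs$group$metric)] == 10))
  expect_true(all(cs$group$group_mean[cs$group$metric == "balance_rate"] == 1))

  # Gaussian errors: mean score matches the closed-form benchmark and
  # the balance rate equals the fraction of nonzero scores
  set.seed(66)
  noisy <- dplyr::mutate(test, subject_id = "S01",
                         r_cm = s_true_cm + rnorm(dplyr::n(), 0, 1.02),
                         delta_s_cm = r_cm - s_true_cm,
                         score = ifelse(feedback, score_points(delta_s_cm), NA))
  cs2 <- condition_summaries(noisy)
  g <- cs2$group
  for (u in c("low", "high")) {
    ms <- g$group_mean[g$metric == "mean_score_all" & g$uncertainty == u]
    expect_equal(ms, gaussian_expected_score(1.02), tolerance = 0.25)
  }
  ps <- cs2$per_subject
  pooled <- pool_sides(noisy)
  for (u in c("low", "high")) {
    expect_equal(ps$balance_rate[ps$uncertainty == u],
                 mean(abs(pooled$delta_s_cm[pooled$uncertainty == u]) <= 1))
  }
})

test_that("hypothetical rescoring reproduces its defining special cases", {
  resp <- dplyr::filter(fixture_subject(), phase == "test")
  # zero bias: exactly the baseline score
  zero_tab <- tibble::tibble(subject_id = "S01",
                             strategy = "null", level = 0.5, bias_cm = 0)
  rs <- hypothetical_rescoring(resp, zero_tab)
  expect_equal(rs$per_subject$delta_score, 0)

  # a fixed 0.24 cm bias on error-free baseline responses scores
  # Round(10 exp(-0.24^2 / 2 sigma^2)) on every trial
  clean <- dplyr::mutate(resp, delta_s_cm = 0, r_cm = s_true_cm)
  tab <- tibble::tibble(subject_id = "S01", strategy = "partial",
                        level = 1.5, bias_cm = 0.24)
  rs2 <- hypothetical_rescoring(clean, tab)
  expect_equal(rs2$per_subject$mean_score, score_points(0.24))

  # missing bias entries are refused
  bad <- tibble::tibble(subject_id = "S01", strategy = "x", level = 0.5,
                        bias_cm = NA_real_)
  expect_error(hypothetical_rescoring(resp, bad),
               class = "comreach_invalid_parameter")
})

test_that("an uncorrecting cohort loses score under rescoring, a full
           corrector does not", {
  # built from the strategy table of a simulated alpha = 0 cohort the
  # almost-full bias is ~0 and rescoring leaves scores unchanged
  ses <- generate_session(seed = 67)
  p0 <- observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
                        sigma_adj = Inf, sigma_motor = 0.5)
  resp <- simulate_responses(ses, p0, seed = 68) |>
    dplyr::filter(phase == "test")
  tab <- strategy_bias_table(resp)
  rs <- hypothetical_rescoring(resp, tab)
  expect_lt(max(abs(rs$group$group_delta)), 0.25)
})

test_that("bias curves separate by perturbation only when correction is
           partial", {
  # full correction: no systematic vertical separation between the
  # largest perturbation levels anywhere on the curve
  bc <- bias_curve(fixture_null_cohort()) |>
    dplyr::filter(perturbation_level %in% c(-1.5, 1.5), n_trials >= 20) |>
    dplyr::group_by(bin_mid) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(sep = mean_bias[perturbation_level == 1.5] -
                       mean_bias[perturbation_level == -1.5],
                     .groups = "drop")
  expect_lt(abs(mean(bc$sep)), 0.15)

  partial <- dplyr::filter(fixture_subject(), phase == "test")
  bc2 <- bias_curve(partial)
  wide <- bc2 |>
    dplyr::filter(abs(bin_mid) > 2,
                  perturbation_level %in% c(-1.5, 1.5)) |>
    dplyr::group_by(bin_mid) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(sep = mean_bias[perturbation_level == 1.5] -
                       mean_bias[perturbation_level == -1.5],
                     .groups = "drop")
  expect_gt(mean(wide$sep), 0.25)
})

test_that("slope agreement computes identity-line R squared", {
  sl <- tibble::tibble(subject_id = rep(sprintf("S%02d", 1:8), 2),
                       uncertainty_class = rep(c("low", "high"), each = 8),
                       slope = c(runif(8, 0, 0.1), runif(8, 0.1, 0.3)))
  perfect <- slope_agreement(sl, sl)
  expect_equal(perfect$r_squared, 1)
  constant <- dplyr::mutate(sl, slope = mean(slope))
  expect_lte(slope_agreement(sl, constant)$r_squared, 0)
  expect_error(slope_agreement(sl[1:2, ], sl[1:2, ]),
               class = "comreach_invalid_parameter")
})

test_that("ideal observer benchmark aggregates per-subject scores", {
  bm <- ideal_observer_benchmark(c(0.05, 0.063, 0.08), n_sim = 3000,
                                 seed = 71, n_boot = 200)
  expect_setequal(bm$trial_class, c("low", "high"))
  expect_gt(bm$mean_score[bm$trial_class == "low"],
            bm$mean_score[bm$trial_class == "high"])
  expect_true(all(bm$boot_sd > 0))
  # vanishing sensory noise: perfect score in both classes
  bm0 <- ideal_observer_benchmark(1e-9, n_sim = 500, seed = 72,
                                  n_boot = 50)
  expect_equal(bm0$mean_score, c(10, 10), tolerance = 1e-6)
})
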
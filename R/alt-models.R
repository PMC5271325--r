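# Alternative observers used as controls. Each changes one ingredient of
# the decision rule; the analyses check which alternatives can and cannot
# reproduce uncertainty-dependent partial correction.

#' Adjusted endpoint under a quadratic error loss
#'
#' Replaces the inverted-Gaussian error term by a quadratic loss
#' \eqn{E[(\hat s - s)^2]}, keeping the inverted-Gaussian adjustment
#' cost. Because the quadratic expected loss equals
#' \eqn{(\hat s - \mu_{post})^2} plus a constant (the posterior
#' variance), the optimum depends on the posterior only through its mean
#' — posterior width cannot modulate the correction, so this variant
#' predicts identical uncorrected fractions in both uncertainty classes.
#'
#' @param post_com A `gaussian_mixture` in `"com"` space.
#' @param r0 Pre-adjustment arrival position (cm).
#' @param params An [observer_params()].
#' @param geometry A [task_geometry()].
#' @param step Grid resolution in cm.
#' @return The adjusted endpoint in cm.
#' @export
quadratic_adjusted_endpoint <- function(post_com, r0, params,
                                        geometry = task_geometry(),
                                        step = 0.01) {
  stopifnot(inherits(post_com, "gaussian_mixture"),
            identical(attr(post_com, "space"), "com"), is.finite(r0))
  half <- geometry$bar_length / 2
  mu <- sum(post_com$weight * post_com$mean)
  alpha <- params$alpha
  inv_sa <- params$inv_sigma_adj
  f <- function(shat) {
    -(shat - mu)^2 +
      if (alpha > 0) alpha * exp(-(shat - r0)^2 * inv_sa^2 / 2) else 0
  }
  grid_argmax(f, -half, half, step = step)
}

#' Adjusted endpoint under a power-law adjustment loss
#'
#' Keeps the inverted-Gaussian error loss but replaces the adjustment
#' cost by \eqn{\alpha |\hat s - r_0|^\gamma}. Like the main model, the
#' correction gain still decreases with posterior width, so uncertainty
#' modulation is preserved; empirically this variant is hard to
#' distinguish from the inverted-Gaussian adjustment cost.
#'
#' @param post_com A `gaussian_mixture` in `"com"` space.
#' @param r0 Pre-adjustment arrival position (cm).
#' @param params An [observer_params()] (its `alpha` weights the power
#'   loss; `sigma_adj` is ignored).
#' @param gamma Power exponent (> 0).
#' @param geometry A [task_geometry()].
#' @param step Grid resolution in cm.
#' @return The adjusted endpoint in cm.
#' @export
power_adjusted_endpoint <- function(post_com, r0, params, gamma = 2,
                                    geometry = task_geometry(),
                                    step = 0.01) {
  stopifnot(inherits(post_com, "gaussian_mixture"),
            identical(attr(post_com, "space"), "com"),
            is.finite(r0))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a single positive number.",
          class = "comreach_invalid_parameter")
  }
  half <- geometry$bar_length / 2
  egain <- mixture_err_gain(post_com, params$sigma_err)
  alpha <- params$alpha
  f <- function(shat) egain(shat) - alpha * abs(shat - r0)^gamma
  grid_argmax(f, -half, half, step = step)
}

#' Response of a miscalibrated-cursor observer
#'
#' Control model in which the lack of correction is explained not by an
#' effort cost but by miscalibration of the perceived position of the
#' reappeared cursor: the observer corrects fully toward its target but
#' perceives the correction distance with gain `gain` (and offset
#' `offset`), leaving a residual error proportional to the perturbation.
#' The proportionality is the same in both uncertainty classes, so this
#' variant cannot produce class-dependent slopes.
#'
#' @param rho_m Internal measurement(s) of the log radius ratio.
#' @param b Perturbation(s) in cm.
#' @param params An [observer_params()].
#' @param calibration List with `gain` and `offset` (perceived correction
#'   = `gain * true correction + offset`).
#' @param geometry A [task_geometry()].
#' @param prior Observer prior over log ratios.
#' @return A tibble with `rho_m`, `b`, `s_pre`, `r0`, `s_star` (final
#'   position before motor noise).
#' @export
miscalibrated_response <- function(rho_m, b = 0, params,
                                   calibration = list(gain = 0.84,
                                                      offset = 0),
                                   geometry = task_geometry(),
                                   prior = prior_log_ratio()) {
  stopifnot(is.finite(calibration$gain), is.finite(calibration$offset))
  ideal <- observer_params(sigma_rho = params$sigma_rho,
                           dim_d = params$dim_d, alpha = 0,
                           sigma_adj = Inf, sigma_motor = 0,
                           sigma_err = params$sigma_err)
  dec <- decide_trials_cpp(rho_m, rep(b, length.out = length(rho_m)),
                           ideal, geometry, prior)
  # full correction toward s_pre, but the executed correction distance is
  # gain * intended + offset
  correction <- dec$s_pre - dec$r0
  tibble(rho_m = rho_m, b = dec$b, s_pre = dec$s_pre, r0 = dec$r0,
         s_star = dec$r0 + calibration$gain * correction +
           calibration$offset)
}

#' Simulate a session under an alternative observer
#'
#' Drop-in variant of [simulate_responses()] for the control models:
#' `"quadratic_error"` (quadratic error loss), `"power_adjustment"`
#' (power-law adjustment loss with exponent `gamma`), or
#' `"miscalibrated"` (cursor-gain miscalibration).
#'
#' @param session A trial table from [generate_session()].
#' @param params An [observer_params()].
#' @param variant Which alternative observer to simulate.
#' @param gamma Exponent for the power-adjustment variant.
#' @param calibration Calibration list for the miscalibrated variant.
#' @param seed Optional integer seed.
#' @param prior Observer prior over log ratios.
#' @param cfg A [session_config()].
#' @return A response tibble like that of [simulate_responses()].
#' @export
simulate_responses_variant <- function(session, params,
                                       variant = c("quadratic_error",
                                                   "power_adjustment",
                                                   "miscalibrated"),
                                       gamma = 2,
                                       calibration = list(gain = 0.84,
                                                          offset = 0),
                                       seed = NULL,
                                       prior = prior_log_ratio(),
                                       cfg = session_config()) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(session)
  rho_m <- rnorm(n, session$rho, params$sigma_rho)
  geometry <- cfg$geometry
  if (variant == "miscalibrated") {
    dec <- miscalibrated_response(rho_m, session$b_cm, params, calibration,
                                  geometry, prior)
  } else {
    endpoint_fun <- switch(variant,
      quadratic_error = function(post_s, r0) {
        quadratic_adjusted_endpoint(post_s, r0, params, geometry)
      },
      power_adjustment = function(post_s, r0) {
        power_adjusted_endpoint(post_s, r0, params, gamma, geometry)
      }
    )
    dec <- purrr::map2_dfr(rho_m, session$b_cm, function(rm, bb) {
      post_r <- posterior_rho(rm, prior, params$sigma_rho)
      post_s <- posterior_com(post_r, params$dim_d, geometry)
      s_pre <- as.numeric(preliminary_endpoint(post_s, params$sigma_err,
                                               geometry))
      r0 <- s_pre + bb
      tibble(rho_m = rm, b = bb, s_pre = s_pre, r0 = r0,
             s_star = as.numeric(endpoint_fun(post_s, r0)))
    })
  }
  r <- dec$s_star +
    if (params$sigma_motor > 0) rnorm(n, 0, params$sigma_motor) else 0
  delta_s <- r - session$s_true_cm
  sc <- score_points(delta_s, cfg$score)
  dplyr::mutate(session,
                rho_m = rho_m, s_pre_cm = dec$s_pre, r0_cm = dec$r0,
                s_star_cm = dec$s_star, r_cm = r, delta_s_cm = delta_s,
                score = ifelse(session$feedback, sc, NA_real_))
}

#' Calibrate the power-adjustment loss against the main model
#'
#' Chooses the weight of the power-law adjustment cost so that, for a
#' representative single-component posterior, the variant's correction
#' profile over a range of arrival offsets matches the main model's as
#' closely as possible (least squares on the adjusted endpoints). This
#' gives matched parameters for comparing the two loss shapes on the
#' same cohorts without fitting data.
#'
#' @param params The main-model [observer_params()].
#' @param gamma Power exponent.
#' @param posterior_sd SD of the representative posterior (cm).
#' @param r0_range Offsets of the arrival position probed (cm).
#' @param geometry A [task_geometry()].
#' @return The calibrated weight `alpha_power`.
#' @export
calibrate_power_loss <- function(params, gamma = 2, posterior_sd = 1,
                                 r0_range = seq(-2, 2, by = 0.25),
                                 geometry = task_geometry()) {
  post <- gaussian_mixture(1, 0, posterior_sd, space = "com")
  target <- vapply(r0_range, function(r0) {
    as.numeric(adjusted_endpoint(post, r0, params, geometry))
  }, numeric(1))
  loss <- function(log_a) {
    p2 <- params
    p2$alpha <- exp(log_a)
    got <- vapply(r0_range, function(r0) {
      as.numeric(power_adjusted_endpoint(post, r0, p2, gamma, geometry))
    }, numeric(1))
    sum((got - target)^2)
  }
  exp(optimize(loss, interval = c(-8, 4), tol = 1e-4)$minimum)
}
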
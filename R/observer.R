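# The two-stage decision rule: a preliminary endpoint minimizing the
# expected inverted-Gaussian error loss, then an adjusted endpoint that
# trades the error loss against an inverted-Gaussian adjustment (effort)
# cost anchored at the pre-adjustment arrival position r0.

# Expected error gain (negative expected loss) as a vectorized closure.
# For an inverted-Gaussian error loss with scale sigma_err, the expected
# gain under mixture component (w, m, v) is
#   w * sigma_err / sqrt(v + sigma_err^2) * exp(-(s - m)^2 / 2 (v + sigma_err^2))
mixture_err_gain <- function(post_com, sigma_err) {
  w <- post_com$weight
  m <- post_com$mean
  vtot <- post_com$sd^2 + sigma_err^2
  amp <- w * sigma_err / sqrt(vtot)
  function(shat) {
    out <- numeric(length(shat))
    for (i in seq_along(w)) {
      out <- out + amp[i] * exp(-(shat - m[i])^2 / (2 * vtot[i]))
    }
    out
  }
}

#' Preliminary endpoint: minimizing the expected error loss
#'
#' The motor-planning stage picks the endpoint \eqn{s^*_{pre}} that
#' minimizes the posterior-expected inverted-Gaussian error loss, i.e.
#' maximizes \eqn{\sum_i Z^{(i)} N(\hat s \mid m^{(i)}, s^{(i)2} +
#' \sigma_{err}^2)} over the bar. The objective can be multimodal (the
#' posterior is a mixture), so the optimum is found on a deterministic
#' dense grid with parabolic refinement; ties break toward the midpoint.
#'
#' @param post_com A `gaussian_mixture` in `"com"` space.
#' @param sigma_err Error-loss length scale (cm).
#' @param geometry A [task_geometry()].
#' @param step Grid resolution in cm.
#' @return The endpoint in cm, with attribute `flat = TRUE` if the
#'   objective was degenerate (flat), in which case the midpoint of the
#'   maximizing set is returned.
#' @export
preliminary_endpoint <- function(post_com, sigma_err = score_config()$sigma_score,
                                 geometry = task_geometry(), step = 0.01) {
  stopifnot(inherits(post_com, "gaussian_mixture"),
            identical(attr(post_com, "space"), "com"), sigma_err > 0)
  half <- geometry$bar_length / 2
  grid_argmax(mixture_err_gain(post_com, sigma_err), -half, half, step = step)
}

#' Adjusted endpoint: error loss plus adjustment (effort) cost
#'
#' After the reach arrives at `r0` (planned endpoint plus any covert
#' perturbation), the observer settles on the position minimizing
#' \deqn{\alpha L_{adj}(\hat s - r_0) + E_{post}[L_{err}(\hat s - s)],}
#' with both losses inverted Gaussians (scales `sigma_adj`, `sigma_err`).
#' With `alpha = 0` this reduces exactly to [preliminary_endpoint()]; as
#' `alpha` grows the optimum is pulled toward `r0` (no correction). A wide
#' posterior flattens the error term, so less of the perturbation is
#' corrected on high-uncertainty trials — the model's core mechanism.
#'
#' @param post_com A `gaussian_mixture` in `"com"` space.
#' @param r0 Pre-adjustment arrival position (cm).
#' @param params An [observer_params()].
#' @param geometry A [task_geometry()].
#' @param step Grid resolution in cm.
#' @return The adjusted endpoint in cm (attribute `flat` as in
#'   [preliminary_endpoint()]).
#' @export
adjusted_endpoint <- function(post_com, r0, params,
                              geometry = task_geometry(), step = 0.01) {
  stopifnot(inherits(post_com, "gaussian_mixture"),
            identical(attr(post_com, "space"), "com"),
            inherits(params, "observer_params"),
            is.finite(r0))
  half <- geometry$bar_length / 2
  egain <- mixture_err_gain(post_com, params$sigma_err)
  alpha <- params$alpha
  inv_sa <- params$inv_sigma_adj
  f <- if (alpha == 0) {
    egain
  } else {
    function(shat) egain(shat) + alpha * exp(-(shat - r0)^2 * inv_sa^2 / 2)
  }
  grid_argmax(f, -half, half, step = step)
}

#' Full two-stage decision for one internal measurement
#'
#' Runs the whole decision path for a single trial: posterior over the
#' log ratio given `rho_m`, posterior over the center of mass, preliminary
#' endpoint, arrival position `r0 = s_pre + b`, and adjusted endpoint.
#' This is the reference (pure R) implementation; the simulation and
#' fitting code use a compiled equivalent.
#'
#' @param rho_m Internal measurement of the log radius ratio.
#' @param b Perturbation in cm (0 on standard trials).
#' @param params An [observer_params()].
#' @param geometry A [task_geometry()].
#' @param prior Prior `gaussian_mixture` in `"rho"` space.
#' @param step Decision-grid resolution in cm.
#' @return A one-row tibble with `rho_m`, `b`, `s_pre`, `r0`, `s_star`.
#' @export
decide_endpoint <- function(rho_m, b = 0, params, geometry = task_geometry(),
                            prior = prior_log_ratio(), step = 0.01) {
  post_r <- posterior_rho(rho_m, prior, params$sigma_rho)
  post_s <- posterior_com(post_r, params$dim_d, geometry)
  s_pre <- as.numeric(preliminary_endpoint(post_s, params$sigma_err,
                                           geometry, step = step))
  r0 <- s_pre + b
  s_star <- as.numeric(adjusted_endpoint(post_s, r0, params, geometry,
                                         step = step))
  tibble(rho_m = rho_m, b = b, s_pre = s_pre, r0 = r0, s_star = s_star)
}

#' Marginal response distribution for a trial
#'
#' The probability of a final response `r` on a trial with log ratio
#' `rho` and perturbation `b` marginalizes the two-stage decision over
#' the unobserved internal measurement:
#' \deqn{\Pr(r \mid \rho, b; \theta) = \int N(\rho_m \mid \rho,
#'   \sigma_\rho^2)\, N(r \mid s^*(\rho_m, s^*_{pre}(\rho_m) + b),
#'   \sigma_{motor}^2)\, d\rho_m,}
#' evaluated by Gauss-Hermite quadrature in \eqn{\rho_m} (exact decision
#' path at each node). The returned object can evaluate the density and
#' draw samples (measurement draw, two-stage decision, motor noise).
#'
#' @param rho True log radius ratio of the trial.
#' @param b Perturbation in cm.
#' @param params An [observer_params()].
#' @param geometry A [task_geometry()].
#' @param prior Prior mixture in `"rho"` space.
#' @param n_nodes Gauss-Hermite node count (>= 61 recommended).
#' @return An object of class `response_distribution` with elements
#'   `density(r)` (requires `sigma_motor > 0`) and `sample(n)` (uses the
#'   R RNG stream).
#' @export
response_distribution <- function(rho, b = 0, params,
                                  geometry = task_geometry(),
                                  prior = prior_log_ratio(), n_nodes = 61) {
  stopifnot(inherits(params, "observer_params"))
  gh <- gh_rule(n_nodes)
  rho_m_nodes <- rho + sqrt(2) * params$sigma_rho * gh$x
  dec <- decide_trials_cpp(rho_m_nodes, rep(b, n_nodes), params, geometry,
                           prior)
  wbar <- gh$w / sqrt(pi)
  s_star_nodes <- dec$s_star
  sigma_motor <- params$sigma_motor

  density <- function(r) {
    if (sigma_motor <= 0) {
      abort(paste("Density evaluation requires sigma_motor > 0;",
                  "with zero motor noise the response distribution has",
                  "point masses - use the sampler instead."),
            class = "comreach_degenerate_density")
    }
    vapply(r, function(ri) sum(wbar * dnorm(ri, s_star_nodes, sigma_motor)),
           numeric(1))
  }

  sample <- function(n) {
    rm <- rnorm(n, rho, params$sigma_rho)
    # fine tabulation of the decision path for this fixed b, then linear
    # interpolation: accurate to well below the motor noise scale
    rng <- range(c(rm, rho_m_nodes))
    grid <- seq(rng[1] - 1e-6, rng[2] + 1e-6, length.out = 1201)
    tab <- decide_trials_cpp(grid, rep(b, length(grid)), params, geometry,
                             prior)
    s_star <- approx(grid, tab$s_star, xout = rm)$y
    s_star + rnorm(n, 0, sigma_motor)
  }

  structure(list(rho = rho, b = b, params = params, nodes = rho_m_nodes,
                 weights = wbar, s_star_nodes = s_star_nodes,
                 density = density, sample = sample),
            class = "response_distribution")
}

# Compiled exact decision path for vectors of (rho_m, b).
decide_trials_cpp <- function(rho_m, b, params, geometry = task_geometry(),
                              prior = prior_log_ratio(), step = 0.01) {
  gh <- gh_rule(31)
  out <- cpp_decide_trials(rho_m, b, prior$weight, prior$mean, prior$sd,
                           params$sigma_rho, params$dim_d, params$alpha,
                           params$inv_sigma_adj, params$sigma_err,
                           geometry$bar_length / 2, gh$x, gh$w, step)
  tibble(rho_m = rho_m, b = b, s_pre = out$s_pre,
         r0 = out$s_pre + b, s_star = out$s_star)
}

#' Monte-Carlo expected score of an observer
#'
#' Simulates trials of one uncertainty class from the stimulus model
#' (equal disks for `"low"`, unequal disks with counterbalanced sides for
#' `"high"`), runs the observer's two-stage decision on each, scores the
#' responses against the true center of mass (computed with the veridical
#' mapping), and returns the mean score with its Monte-Carlo SE.
#'
#' @param params An [observer_params()].
#' @param trial_class `"low"` or `"high"`.
#' @param n_sim Number of simulated trials.
#' @param seed Optional integer seed for reproducibility.
#' @param config A [score_config()].
#' @param geometry A [task_geometry()].
#' @param prior Observer prior in `"rho"` space.
#' @param ratio_log_mean,ratio_log_sd Stimulus distribution of unequal
#'   trials (log space).
#' @return A one-row tibble: `trial_class`, `mean_score`, `se`, `n_sim`.
#' @export
expected_score <- function(params, trial_class = c("low", "high"),
                           n_sim = 10000, seed = NULL,
                           config = score_config(),
                           geometry = task_geometry(),
                           prior = prior_log_ratio(),
                           ratio_log_mean = log(1.5), ratio_log_sd = 0.1) {
  trial_class <- match.arg(trial_class)
  stopifnot(n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  rho <- if (trial_class == "low") {
    rep(0, n_sim)
  } else {
    side <- rep(c(-1, 1), length.out = n_sim)
    side * rnorm(n_sim, ratio_log_mean, ratio_log_sd)
  }
  s_true <- com_map(rho, 2, geometry)
  rho_m <- rnorm(n_sim, rho, params$sigma_rho)
  dec <- decide_trials_cpp(rho_m, rep(0, n_sim), params, geometry, prior)
  r <- dec$s_star
  if (params$sigma_motor > 0) r <- r + rnorm(n_sim, 0, params$sigma_motor)
  sc <- score_points(r - s_true, config)
  tibble(trial_class = trial_class,
         mean_score = mean(sc),
         se = sd(sc) / sqrt(n_sim),
         n_sim = n_sim)
}
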
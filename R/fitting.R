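# Maximum-likelihood fitting of the observer model. The marginal
# likelihood (Gauss-Hermite quadrature over the internal measurement) is
# evaluated from exact windowed grid decisions at every trial x node:
# the expected-error-gain curve of each node is cached per candidate
# mapping exponent, so candidate adjustment-loss parameters only pay for
# the adjustment term. The (alpha, sigma_adj) pair forms a shallow
# banana-shaped likelihood ridge along which the near-arrival curvature
# alpha / sigma_adj^2 is well identified while sigma_adj is weak; the
# search therefore runs in the ridge-aligned coordinates
# (log alpha/sigma_adj^2, log sigma_adj), with the mapping exponent
# profiled on top and sigma_motor profiled by 1-D search throughout.

#' Fitting control settings
#'
#' Numerical settings of the ML machinery: the decision-grid resolution
#' used inside the likelihood, quadrature order, optimizer effort, and
#' the parameter boxes searched.
#'
#' @param s_step Decision-grid resolution (cm) inside the likelihood.
#' @param window_margin Endpoint search-window margin beyond the
#'   `[s_pre, r0]` hull (cm); wide enough to capture side-mode optima.
#' @param n_nodes Gauss-Hermite order for the measurement quadrature.
#' @param n_restarts Latin-hypercube starts for the adjustment-loss
#'   search (a dedicated `alpha = 0` branch always runs as well).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param dim_d_range,sigma_motor_range,sigma_rho_range Search boxes for
#'   the mapping exponent, motor scale and sensory noise.
#' @param log_curv_range Box for `log(alpha / sigma_adj^2)`, the
#'   adjustment-cost curvature at the arrival point (cm^-2, log scale).
#' @param log_sigma_adj_range Box for `log(sigma_adj)` (log cm); the
#'   upper end stands in for the flat-adjustment boundary
#'   `sigma_adj = Inf`, which is also probed exactly by the `alpha = 0`
#'   branch.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(s_step = 0.04, window_margin = 3, n_nodes = 61,
                        n_restarts = 3, maxit = 100,
                        dim_d_range = c(0.5, 4),
                        sigma_motor_range = c(0.1, 3),
                        sigma_rho_range = c(0.005, 0.5),
                        log_curv_range = c(-6, 2.5),
                        log_sigma_adj_range = log(c(0.5, 40))) {
  structure(as.list(environment()), class = "fit_control")
}

clamp <- function(x, rng) min(max(x, rng[1]), rng[2])

# quadrature-node layout for a set of trials (node-major flattening)
node_layout <- function(records, sigma_rho, n_nodes) {
  gh <- gh_rule(n_nodes)
  K <- length(gh$x)
  n <- nrow(records)
  list(
    rho_m = rep(records$rho, each = K) +
      sqrt(2) * sigma_rho * rep(gh$x, times = n),
    b = rep(records$b_cm, each = K),
    gh = gh, n = n, K = K
  )
}

node_setup <- function(lay, sigma_rho, dim_d, sigma_err,
                       geometry, prior, control) {
  gh31 <- gh_rule(31)
  cpp_node_setup(lay$rho_m, lay$b, prior$weight, prior$mean, prior$sd,
                 sigma_rho, dim_d, sigma_err, geometry$bar_length / 2,
                 gh31$x, gh31$w, control$s_step, control$window_margin)
}

# profile the residual motor scale for a fixed set of node endpoints
profile_sigma_motor <- function(records, s_star, lay, control) {
  opt <- optimize(function(sm) {
    -sum(cpp_density_from_star(records$r_cm, s_star, lay$gh$w, sm))
  }, interval = control$sigma_motor_range, tol = 2e-3)
  list(nll = opt$objective, sigma_motor = opt$minimum)
}

#' Per-trial marginal log-likelihood (exact decision path)
#'
#' Evaluates the log of the marginal response density for each trial by
#' Gauss-Hermite quadrature over the internal measurement, running the
#' exact two-stage decision at every node on the full-bar 0.01 cm grid.
#' This is the reference likelihood; the fitting loop uses the cached
#' windowed equivalent.
#'
#' @param records Trial tibble with columns `rho`, `b_cm`, `r_cm`.
#' @param params An [observer_params()] with `sigma_motor > 0`.
#' @param geometry A [task_geometry()].
#' @param prior Observer prior over log ratios.
#' @param n_nodes Quadrature order.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
trial_loglik <- function(records, params, geometry = task_geometry(),
                         prior = prior_log_ratio(), n_nodes = 61) {
  stopifnot(inherits(params, "observer_params"))
  if (params$sigma_motor <= 0) {
    abort("trial_loglik() requires sigma_motor > 0.",
          class = "comreach_invalid_parameter")
  }
  lay <- node_layout(records, params$sigma_rho, n_nodes)
  dec <- decide_trials_cpp(lay$rho_m, lay$b, params, geometry, prior)
  cpp_density_from_star(records$r_cm, dec$s_star, lay$gh$w,
                        params$sigma_motor)
}

new_observer_fit <- function(params, loglik, n_trials, converged,
                             n_restarts_used, fixed_fields, boundary = FALSE,
                             predicted_slopes = NULL) {
  structure(
    list(params = params, loglik = loglik, n_trials = n_trials,
         converged = converged, n_restarts_used = n_restarts_used,
         fixed_fields = fixed_fields, boundary = boundary,
         predicted_slopes = predicted_slopes),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("<observer_fit>", x$n_trials, "trials, log-likelihood",
      sprintf("%.2f", x$loglik),
      if (x$boundary) "(boundary-pinned)" else "", "\n")
  cat("  fixed:", paste(x$fixed_fields, collapse = ", "), "\n")
  print(x$params)
  if (!is.null(x$predicted_slopes)) {
    cat(sprintf("  predicted slopes: low %.3f, high %.3f\n",
                x$predicted_slopes[["low"]], x$predicted_slopes[["high"]]))
  }
  invisible(x)
}

#' @export
tidy.observer_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("sigma_rho", "dim_d", "alpha", "sigma_adj", "sigma_motor",
             "sigma_err"),
    estimate = c(p$sigma_rho, p$dim_d, p$alpha, p$sigma_adj, p$sigma_motor,
                 p$sigma_err),
    fixed = c("sigma_rho", "dim_d", "alpha", "sigma_adj", "sigma_motor",
              "sigma_err") %in% x$fixed_fields
  )
}

#' @export
glance.observer_fit <- function(x, ...) {
  tibble(
    loglik = x$loglik, n_trials = x$n_trials, converged = x$converged,
    n_restarts_used = x$n_restarts_used, boundary = x$boundary,
    slope_low = if (is.null(x$predicted_slopes)) NA_real_ else
      x$predicted_slopes[["low"]],
    slope_high = if (is.null(x$predicted_slopes)) NA_real_ else
      x$predicted_slopes[["high"]]
  )
}

#' Estimate sensory noise from a training session
#'
#' Fits the observer to feedback-only, unperturbed training trials by
#' maximum likelihood to estimate the sensory noise `sigma_rho`. Since
#' training trials carry no perturbation, the adjustment cost is inert
#' and `alpha` is fixed at 0; the mapping exponent and the residual motor
#' scale are profiled as nuisance parameters and only `sigma_rho` is
#' carried forward to the test-session fit. Estimates pinned at the
#' search boundary are flagged (and a warning raised), never silently
#' returned.
#'
#' @param records Training trial tibble with columns `rho`, `b_cm`,
#'   `r_cm` (at least 50 trials).
#' @param geometry A [task_geometry()].
#' @param prior Observer prior over log ratios.
#' @param control A [fit_control()].
#' @param seed Integer seed for the restart draw.
#' @return An `observer_fit`; the `sigma_rho` element of its `params` is
#'   the estimate.
#' @export
fit_training <- function(records, geometry = task_geometry(),
                         prior = prior_log_ratio(), control = fit_control(),
                         seed = 1) {
  if (nrow(records) < 50) {
    abort("fit_training() needs at least 50 training trials.",
          class = "comreach_invalid_parameter")
  }
  sigma_err <- score_config()$sigma_score
  lsr_rng <- log(control$sigma_rho_range)
  d_rng <- control$dim_d_range

  nll <- function(par) {
    lsr <- clamp(par[1], lsr_rng)
    d <- clamp(par[2], d_rng)
    pen <- 1e4 * ((par[1] - lsr)^2 + (par[2] - d)^2)
    sr <- exp(lsr)
    lay <- node_layout(records, sr, control$n_nodes)
    setup <- node_setup(lay, sr, d, sigma_err, geometry, prior, control)
    profile_sigma_motor(records, setup$s_pre, lay, control)$nll + pen
  }

  set.seed(seed)
  u <- lhs::randomLHS(control$n_restarts, 2)
  starts <- rbind(c(log(0.06), 2),
                  cbind(lsr_rng[1] + u[, 1] * diff(lsr_rng),
                        d_rng[1] + u[, 2] * diff(d_rng)))
  fits <- apply(starts, 1, function(p0) {
    optim(p0, nll, method = "Nelder-Mead",
          control = list(maxit = control$maxit, reltol = 1e-7))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  sr <- exp(clamp(best$par[1], lsr_rng))
  d <- clamp(best$par[2], d_rng)
  lay <- node_layout(records, sr, control$n_nodes)
  setup <- node_setup(lay, sr, d, sigma_err, geometry, prior, control)
  prof <- profile_sigma_motor(records, setup$s_pre, lay, control)

  rel_edge <- min(sr / control$sigma_rho_range[1],
                  control$sigma_rho_range[2] / sr)
  boundary <- rel_edge < 1.05
  if (boundary) {
    warn(sprintf("sigma_rho estimate (%.4g) is pinned at the search boundary.",
                 sr))
  }
  params <- observer_params(sigma_rho = sr, dim_d = d, alpha = 0,
                            sigma_adj = Inf, sigma_motor = prof$sigma_motor,
                            sigma_err = sigma_err)
  new_observer_fit(params, -prof$nll, nrow(records),
                   converged = best$convergence == 0,
                   n_restarts_used = nrow(starts),
                   fixed_fields = c("alpha", "sigma_adj", "sigma_err"),
                   boundary = boundary)
}

#' Fit the full observer model to a test session
#'
#' Maximum-likelihood fit of the two-stage observer to test-session
#' trials with `sigma_rho` held at the training-session estimate.
#' Effectively three free parameters — the mapping exponent `dim_d`, the
#' effort weight `alpha` and the adjustment length scale `sigma_adj` —
#' plus the residual motor scale `sigma_motor`, profiled for every
#' candidate. `dim_d` is profiled over a coarse-then-fine 1-D search; at
#' each candidate `dim_d` the adjustment-loss parameters are optimized
#' by Nelder-Mead in the ridge-aligned coordinates
#' `(log alpha/sigma_adj^2, log sigma_adj)` from Latin-hypercube starts
#' (warm-started along the `dim_d` search), and a dedicated `alpha = 0`
#' (full-correction) branch is always evaluated. Fits reaching the upper
#' `sigma_adj` bound are reported as flat-adjustment observers
#' (`sigma_adj = Inf`).
#'
#' @param records Test trial tibble with columns `rho`, `b_cm`, `r_cm`
#'   (at least 100 trials).
#' @param sigma_rho Sensory noise estimate from [fit_training()].
#' @param geometry A [task_geometry()].
#' @param prior Observer prior over log ratios.
#' @param control A [fit_control()].
#' @param seed Integer seed for the restart draw.
#' @param slopes If `TRUE`, simulate the fitted observer to attach
#'   predicted uncorrected-fraction slopes (see [predict_slopes()]).
#' @return An `observer_fit`.
#' @export
fit_test <- function(records, sigma_rho, geometry = task_geometry(),
                     prior = prior_log_ratio(), control = fit_control(),
                     seed = 1, slopes = FALSE) {
  if (nrow(records) < 100) {
    abort("fit_test() needs at least 100 test trials.",
          class = "comreach_invalid_parameter")
  }
  stopifnot(is.numeric(sigma_rho), sigma_rho > 0)
  sigma_err <- score_config()$sigma_score
  lay <- node_layout(records, sigma_rho, control$n_nodes)
  lc_rng <- control$log_curv_range
  ls_rng <- control$log_sigma_adj_range
  d_rng <- control$dim_d_range

  set.seed(seed)
  u <- lhs::randomLHS(control$n_restarts, 2)
  lhs_starts <- cbind(lc_rng[1] + u[, 1] * diff(lc_rng),
                      ls_rng[1] + u[, 2] * diff(ls_rng))

  warm <- NULL     # best inner solution so far, carried along the D search
  n_inner <- 0L

  eval_d <- function(d, thorough) {
    setup <- node_setup(lay, sigma_rho, d, sigma_err, geometry, prior,
                        control)
    inner_nll <- function(par) {
      lc <- clamp(par[1], lc_rng)
      ls <- clamp(par[2], ls_rng)
      pen <- 1e4 * ((par[1] - lc)^2 + (par[2] - ls)^2)
      sadj <- exp(ls)
      ss <- cpp_star_from_setup(setup, lay$b, exp(lc) * sadj^2, 1 / sadj,
                                control$window_margin)
      profile_sigma_motor(records, ss, lay, control)$nll + pen
    }
    starts <- if (thorough) {
      rbind(if (!is.null(warm) && is.finite(warm$par[1])) warm$par,
            c(log(0.4), log(2.8)), lhs_starts)
    } else if (!is.null(warm) && is.finite(warm$par[1])) {
      rbind(warm$par)
    } else {
      rbind(c(log(0.4), log(2.8)))
    }
    res <- lapply(seq_len(nrow(starts)), function(i) {
      optim(starts[i, ], inner_nll, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = 1e-7))
    })
    n_inner <<- n_inner + nrow(starts)
    vals <- purrr::map_dbl(res, "value")
    best <- res[[which.min(vals)]]
    # full-correction branch at this D
    nll0 <- profile_sigma_motor(records, setup$s_pre, lay, control)$nll
    if (nll0 < best$value) {
      best <- list(par = c(-Inf, Inf), value = nll0, convergence = 0L)
    }
    if (is.null(warm) || best$value < warm$value) {
      warm <<- best
      warm$d <<- d
    }
    best
  }

  # coarse profile over the mapping exponent (visited from the veridical
  # exponent outward so the warm start stays relevant; full multistart on
  # the first visit only), then local refinement
  d_coarse <- seq(d_rng[1] + 0.1, d_rng[2] - 0.1, length.out = 8)
  d_coarse <- d_coarse[order(abs(d_coarse - 2))]
  coarse_vals <- vapply(seq_along(d_coarse), function(i) {
    eval_d(d_coarse[i], thorough = i == 1)$value
  }, numeric(1))
  d_best <- d_coarse[which.min(coarse_vals)]
  half_step <- diff(d_coarse[1:2]) / 2
  opt_d <- optimize(function(d) eval_d(d, thorough = FALSE)$value,
                    interval = c(max(d_rng[1], d_best - 2 * half_step),
                                 min(d_rng[2], d_best + 2 * half_step)),
                    tol = 5e-3)

  d <- warm$d
  full_correction <- !is.finite(warm$par[1])
  lc <- clamp(warm$par[1], lc_rng)
  ls <- clamp(warm$par[2], ls_rng)
  at_flat_bound <- !full_correction && ls >= ls_rng[2] - 1e-6
  sadj <- if (full_correction || at_flat_bound) Inf else exp(ls)
  alpha <- if (full_correction) 0 else
    exp(lc) * (if (is.finite(sadj)) sadj^2 else exp(ls)^2)
  setup <- node_setup(lay, sigma_rho, d, sigma_err, geometry, prior,
                      control)
  ss <- if (full_correction) setup$s_pre else
    cpp_star_from_setup(setup, lay$b, if (is.finite(sadj)) alpha else 0,
                        if (is.finite(sadj)) 1 / sadj else 0,
                        control$window_margin)
  if (at_flat_bound) {
    # at the flat boundary the adjustment term is constant: endpoints
    # equal the preliminary ones, matching alpha = 0
    ss <- setup$s_pre
    alpha <- 0
  }
  prof <- profile_sigma_motor(records, ss, lay, control)

  params <- observer_params(sigma_rho = sigma_rho, dim_d = d,
                            alpha = alpha, sigma_adj = sadj,
                            sigma_motor = prof$sigma_motor,
                            sigma_err = sigma_err)
  fit <- new_observer_fit(
    params, -prof$nll, nrow(records),
    converged = TRUE, n_restarts_used = n_inner,
    fixed_fields = c("sigma_rho", "sigma_err")
  )
  if (slopes) {
    fit$predicted_slopes <- predict_slopes(params, geometry = geometry,
                                           prior = prior)
  }
  fit
}

#' Model-predicted uncorrected-fraction slopes
#'
#' Simulates test sessions from a parameter vector and applies the same
#' slope analysis as for real data (baseline subtraction, regression of
#' residual error on perturbation size per uncertainty class). A slope of
#' 0 is full correction; 1 is no correction.
#'
#' @param params An [observer_params()].
#' @param geometry A [task_geometry()].
#' @param n_sessions Number of simulated sessions to average over.
#' @param seed Integer seed.
#' @param cfg A [session_config()].
#' @param prior Observer prior over log ratios.
#' @return Named numeric `c(low = ..., high = ...)`.
#' @export
predict_slopes <- function(params, geometry = task_geometry(),
                           n_sessions = 2, seed = 1,
                           cfg = session_config(geometry = geometry),
                           prior = prior_log_ratio()) {
  cohort <- simulate_cohort(params, n_subjects = n_sessions, cfg = cfg,
                            seed = seed, prior = prior) |>
    dplyr::filter(.data$phase == "test")
  sl <- slope_regression(cohort)
  out <- sl |>
    dplyr::group_by(.data$uncertainty_class) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  setNames(out$slope, out$uncertainty_class)[c("low", "high")]
}
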
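#' One-dimensional Gaussian mixtures with delta components
#'
#' Priors and posteriors in this package are mixtures of Gaussians in which
#' a component standard deviation of exactly 0 encodes a delta function at
#' the component mean (the formal convention \eqn{N(x\mid\mu,0)\equiv
#' \delta(x-\mu)}). A mixture lives either in log-ratio space (`"rho"`)
#' or in center-of-mass space (`"com"`, cm).
#'
#' @param weight Nonnegative component weights; normalized to sum to 1.
#' @param mean Component means (log-ratio units or cm).
#' @param sd Component SDs, `>= 0`; 0 encodes a delta component.
#' @param space `"rho"` or `"com"`.
#' @return A tibble of class `gaussian_mixture` with columns `weight`,
#'   `mean`, `sd` and a `space` attribute.
#' @examples
#' prior_log_ratio()
#' @export
gaussian_mixture <- function(weight, mean, sd, space = c("rho", "com")) {
  space <- match.arg(space)
  n <- length(weight)
  if (length(mean) != n || length(sd) != n || n == 0) {
    abort("`weight`, `mean`, `sd` must have equal, positive length.",
          class = "comreach_invalid_parameter")
  }
  if (any(!is.finite(weight)) || any(weight < 0) || sum(weight) <= 0) {
    abort("Mixture weights must be finite, nonnegative, not all zero.",
          class = "comreach_invalid_parameter")
  }
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd < 0)) {
    abort("Mixture means must be finite and sds finite and >= 0.",
          class = "comreach_invalid_parameter")
  }
  out <- tibble(weight = weight / sum(weight), mean = mean, sd = sd)
  attr(out, "space") <- space
  class(out) <- c("gaussian_mixture", class(out))
  out
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("<gaussian_mixture> space:", attr(x, "space"), "\n")
  NextMethod()
}

#' The experimental prior over log radius ratios
#'
#' Trimodal mixture matching the stimulus statistics: a delta at 0 (equal
#' disks, probability 1/3) and two Gaussians at \eqn{\pm\log 1.5} with SD
#' 0.1 in log space (larger disk right / left).
#'
#' @param ratio_log_mean Mean log ratio of the unequal-disk components.
#' @param ratio_log_sd SD of the unequal-disk components in log space.
#' @return A `gaussian_mixture` in `"rho"` space.
#' @export
prior_log_ratio <- function(ratio_log_mean = log(1.5), ratio_log_sd = 0.1) {
  gaussian_mixture(
    weight = rep(1 / 3, 3),
    mean = c(-ratio_log_mean, 0, ratio_log_mean),
    sd = c(ratio_log_sd, 0, ratio_log_sd),
    space = "rho"
  )
}

#' Posterior over the log radius ratio given a noisy measurement
#'
#' Conjugate update of a Gaussian-mixture prior under the measurement model
#' \eqn{\rho_m \sim N(\rho, \sigma_\rho^2)}. Each component is updated by
#' the standard Gaussian product rule; a delta component keeps its mean
#' with sd 0. The posterior weight of component i is proportional to the
#' prior weight times the predictive density
#' \eqn{N(\rho_m \mid \mu_i, \sigma_\rho^2 + \sigma_i^2)}.
#'
#' @param rho_m Internal measurement (log-ratio units), a single value.
#' @param prior A `gaussian_mixture` in `"rho"` space.
#' @param sigma_rho Measurement noise SD in log space (> 0).
#' @return A `gaussian_mixture` in `"rho"` space.
#' @export
posterior_rho <- function(rho_m, prior = prior_log_ratio(), sigma_rho) {
  stopifnot(inherits(prior, "gaussian_mixture"),
            identical(attr(prior, "space"), "rho"))
  if (!is.numeric(rho_m) || length(rho_m) != 1 || !is.finite(rho_m)) {
    abort("`rho_m` must be a single finite number.",
          class = "comreach_invalid_parameter")
  }
  if (!is.numeric(sigma_rho) || length(sigma_rho) != 1 || sigma_rho <= 0) {
    abort("`sigma_rho` must be a single positive number.",
          class = "comreach_invalid_parameter")
  }
  v0 <- prior$sd^2
  vr <- sigma_rho^2
  logw <- log(prior$weight) + dnorm(rho_m, prior$mean, sqrt(v0 + vr), log = TRUE)
  logw <- logw - max(logw)
  w <- exp(logw)
  post_mean <- (vr * prior$mean + v0 * rho_m) / (v0 + vr)
  post_sd <- sqrt(v0 * vr / (v0 + vr))
  gaussian_mixture(w, post_mean, post_sd, space = "rho")
}

#' Posterior over the center of mass
#'
#' Pushes a log-ratio-space mixture through the center-of-mass mapping
#' [com_map()]. The image of a Gaussian component under the nonlinear map
#' is not Gaussian; each output component is the Gaussian with the exact
#' first two moments of the mapped component, computed by Gauss-Hermite
#' quadrature (not a linearization, so curvature of the mapping is
#' retained). Delta components map exactly. Weights are preserved.
#'
#' @param post_rho A `gaussian_mixture` in `"rho"` space.
#' @param dim_d Radius-to-mass exponent used by the observer.
#' @param geometry A [task_geometry()].
#' @param n_nodes Gauss-Hermite node count for the component moments.
#' @return A `gaussian_mixture` in `"com"` space.
#' @export
posterior_com <- function(post_rho, dim_d, geometry = task_geometry(),
                          n_nodes = 31) {
  stopifnot(inherits(post_rho, "gaussian_mixture"),
            identical(attr(post_rho, "space"), "rho"))
  gh <- gh_rule(n_nodes)
  wbar <- gh$w / sqrt(pi)
  mom <- purrr::map2(post_rho$mean, post_rho$sd, function(mu, s) {
    if (s == 0) {
      c(com_map(mu, dim_d, geometry), 0)
    } else {
      f <- com_map(mu + sqrt(2) * s * gh$x, dim_d, geometry)
      m1 <- sum(wbar * f)
      v <- sum(wbar * (f - m1)^2)
      c(m1, sqrt(max(v, 0)))
    }
  })
  gaussian_mixture(post_rho$weight,
                   purrr::map_dbl(mom, 1),
                   purrr::map_dbl(mom, 2),
                   space = "com")
}

#' Mean and SD of a Gaussian mixture
#'
#' @param gm A `gaussian_mixture`.
#' @return A tibble with columns `mean`, `sd`.
#' @export
mixture_moments <- function(gm) {
  stopifnot(inherits(gm, "gaussian_mixture"))
  m <- sum(gm$weight * gm$mean)
  v <- sum(gm$weight * (gm$sd^2 + gm$mean^2)) - m^2
  tibble(mean = m, sd = sqrt(max(v, 0)))
}
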
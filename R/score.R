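#' Scoring rule configuration
#'
#' The task scores each trial from the signed error
#' \eqn{\Delta s} (cm) between the final cursor position and the true
#' center of mass:
#' \deqn{\mathrm{Score}(\Delta s) = \mathrm{Round}\left(
#'   \mathrm{max}\cdot e^{-\Delta s^2 / 2\sigma_{score}^2}\right).}
#' The default length scale \eqn{\sigma_{score} = 1/\sqrt{2\ln 20}} is the
#' unique value for which the score has maximum 10 at zero error and first
#' reaches 0 strictly beyond 1 cm (the raw score at exactly 1 cm is 0.5,
#' which rounds half-away-from-zero to 1). See [solve_score_scale()].
#'
#' @param max_score Maximum score, at zero error.
#' @param sigma_score Score length scale in cm.
#' @param rounding If `TRUE` (task default), scores are rounded
#'   half-away-from-zero to integers; `FALSE` returns the raw value.
#' @return An object of class `score_config`.
#' @export
score_config <- function(max_score = 10,
                         sigma_score = 1 / sqrt(2 * log(20)),
                         rounding = TRUE) {
  stopifnot(max_score > 0, sigma_score > 0, is.logical(rounding))
  structure(list(max_score = max_score, sigma_score = sigma_score,
                 rounding = rounding),
            class = "score_config")
}

# half-away-from-zero, with a tiny guard so that a raw value that is
# exactly 1/2 in exact arithmetic (the 1 cm score boundary) is not lost
# to floating-point rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5 + 1e-9)

#' Score a response error
#'
#' @param delta_s Signed response error in cm; vectorized.
#' @param config A [score_config()].
#' @return Integer scores in `0:max_score` (or raw values if the config
#'   disables rounding).
#' @examples
#' score_points(0)      # 10
#' score_points(1)      # 1: last nonzero score
#' score_points(1.2)    # 0
#' @export
score_points <- function(delta_s, config = score_config()) {
  if (any(!is.finite(delta_s))) {
    abort("`delta_s` must be finite.", class = "comreach_invalid_parameter")
  }
  raw <- config$max_score * exp(-delta_s^2 / (2 * config$sigma_score^2))
  if (config$rounding) round_half_away(raw) else raw
}

#' Solve for the score length scale implied by the task constraints
#'
#' Finds the \eqn{\sigma_{score}} for which the rounded score is nonzero
#' exactly up to `zero_beyond` cm: the raw score at the boundary equals
#' 1/2 (the rounding threshold), i.e.
#' \eqn{\mathrm{max}\, e^{-z^2/2\sigma^2} = 1/2}, solved numerically.
#'
#' @param max_score Maximum score.
#' @param zero_beyond Distance (cm) at which the score last reaches 1.
#' @return The length scale in cm (`1/sqrt(2 log(2 max_score))` for the
#'   defaults, about 0.4086).
#' @export
solve_score_scale <- function(max_score = 10, zero_beyond = 1) {
  f <- function(sigma) {
    max_score * exp(-zero_beyond^2 / (2 * sigma^2)) - 0.5
  }
  uniroot(f, lower = 1e-3, upper = 10, tol = 1e-12)$root
}

#' Expected score under pure Gaussian response error
#'
#' Closed form for the mean unrounded score when the response error is
#' \eqn{N(0, \sigma^2)}:
#' \eqn{E[\mathrm{Score}] = \mathrm{max}\,\sigma_{score} /
#' \sqrt{\sigma_{score}^2 + \sigma^2}}. With rounding the true mean
#' differs by at most a fraction of a point; this is the benchmark used
#' in sanity checks of simulated scores.
#'
#' @param error_sd SD of the Gaussian response error (cm).
#' @param config A [score_config()].
#' @return Expected (unrounded) score.
#' @export
gaussian_expected_score <- function(error_sd, config = score_config()) {
  stopifnot(error_sd >= 0)
  s2 <- config$sigma_score^2
  config$max_score * sqrt(s2 / (s2 + error_sd^2))
}
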
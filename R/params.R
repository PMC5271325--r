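#' Observer model parameters
#'
#' The observer is parameterized by
#' \describe{
#'   \item{`sigma_rho`}{measurement noise SD on the log radius ratio
#'     (log units, > 0);}
#'   \item{`dim_d`}{exponent of the radius-to-mass mapping the observer
#'     uses to locate the center of mass (> 0; 2 is veridical for disks);}
#'   \item{`alpha`}{relative weight of the adjustment (effort) cost in the
#'     loss function (>= 0; 0 = pure error loss, full correction);}
#'   \item{`sigma_adj`}{length scale of the inverted-Gaussian adjustment
#'     cost in cm (> 0; `Inf` means a flat adjustment loss and is stored
#'     internally as `inv_sigma_adj = 0` so the flat boundary is an
#'     interior point of the fitted parameterization);}
#'   \item{`sigma_motor`}{SD of residual Gaussian response noise in cm
#'     (>= 0);}
#'   \item{`sigma_err`}{length scale of the inverted-Gaussian error loss,
#'     tied to the score length scale of the task.}
#' }
#'
#' @param sigma_rho Measurement noise SD in log space.
#' @param dim_d Radius-to-mass exponent.
#' @param alpha Adjustment-cost weight.
#' @param sigma_adj Adjustment-cost length scale (cm); `Inf` allowed.
#' @param sigma_motor Residual motor noise SD (cm).
#' @param sigma_err Error-loss length scale (cm); defaults to the score
#'   length scale.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_rho = 0.063, dim_d = 2, alpha = 0,
#'                 sigma_adj = Inf, sigma_motor = 0)
#' @export
observer_params <- function(sigma_rho, dim_d, alpha = 0, sigma_adj = Inf,
                            sigma_motor = 0,
                            sigma_err = score_config()$sigma_score) {
  chk <- function(x, name, lo, allow_inf = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
      (allow_inf || is.finite(x)) && x >= lo
    if (!ok) {
      abort(paste0("`", name, "` must be a single number >= ", lo,
                   if (allow_inf) " (Inf allowed)", "."),
            class = "comreach_invalid_parameter")
    }
  }
  chk(sigma_rho, "sigma_rho", 0); if (sigma_rho <= 0)
    abort("`sigma_rho` must be > 0.", class = "comreach_invalid_parameter")
  chk(dim_d, "dim_d", 0); if (dim_d <= 0)
    abort("`dim_d` must be > 0.", class = "comreach_invalid_parameter")
  chk(alpha, "alpha", 0)
  chk(sigma_adj, "sigma_adj", 0, allow_inf = TRUE); if (sigma_adj <= 0)
    abort("`sigma_adj` must be > 0 (Inf allowed).",
          class = "comreach_invalid_parameter")
  chk(sigma_motor, "sigma_motor", 0)
  chk(sigma_err, "sigma_err", 0); if (sigma_err <= 0)
    abort("`sigma_err` must be > 0.", class = "comreach_invalid_parameter")
  structure(
    list(sigma_rho = sigma_rho, dim_d = dim_d, alpha = alpha,
         sigma_adj = sigma_adj, inv_sigma_adj = 1 / sigma_adj,
         sigma_motor = sigma_motor, sigma_err = sigma_err),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  sigma_rho = %.4g  dim_d = %.4g  alpha = %.4g\n",
              x$sigma_rho, x$dim_d, x$alpha))
  cat(sprintf("  sigma_adj = %.4g cm  sigma_motor = %.4g cm  sigma_err = %.4g cm\n",
              x$sigma_adj, x$sigma_motor, x$sigma_err))
  invisible(x)
}

#' @export
as.list.observer_params <- function(x, ...) unclass(x)

#' Group-level fitted observer parameters
#'
#' Convenience constructor for the group-mean parameter values reported
#' for the task (sensory noise 0.063, mapping exponent 1.94, effort
#' weight 3.1, adjustment length scale 2.8 cm, motor noise 0.76 cm),
#' useful as a realistic default cohort configuration.
#'
#' @return An `observer_params` object.
#' @export
group_fit_params <- function() {
  observer_params(sigma_rho = 0.063, dim_d = 1.94, alpha = 3.1,
                  sigma_adj = 2.8, sigma_motor = 0.76)
}

#' Ideal-observer parameters
#'
#' The ideal observer shares the subject's sensory noise but uses the
#' veridical mapping (`dim_d = 2`), no adjustment cost (`alpha = 0`) and
#' no motor noise; it is the upper-bound benchmark for the score.
#'
#' @param sigma_rho Sensory noise SD in log space.
#' @return An `observer_params` object.
#' @export
ideal_observer_params <- function(sigma_rho = 0.063) {
  observer_params(sigma_rho = sigma_rho, dim_d = 2, alpha = 0,
                  sigma_adj = Inf, sigma_motor = 0)
}
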
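#' Task geometry
#'
#' Geometry of the two-disk dumbbell: the disks sit at the ends of a
#' horizontal target line of length `bar_length` (cm), and the center of
#' mass coordinate `s` is measured in cm from the bar midpoint, positive
#' toward the right-hand (second) disk. Any physically attainable center
#' of mass satisfies `|s| < bar_length / 2`.
#'
#' @param bar_length Distance between the two disk centers, in cm.
#' @return An object of class `task_geometry`.
#' @examples
#' task_geometry()
#' @export
task_geometry <- function(bar_length = 24) {
  if (!is.numeric(bar_length) || length(bar_length) != 1 ||
      !is.finite(bar_length) || bar_length <= 0) {
    abort("`bar_length` must be a single positive number (cm).",
          class = "comreach_invalid_parameter")
  }
  structure(list(bar_length = bar_length), class = "task_geometry")
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("<task_geometry> bar length", x$bar_length, "cm; s in (",
      -x$bar_length / 2, ",", x$bar_length / 2, ") cm\n")
  invisible(x)
}

#' Center-of-mass mapping from log radius ratio
#'
#' Location of the center of mass of two D-dimensional spheres placed at
#' the ends of the bar, as a function of the log radius ratio
#' \eqn{\rho = \log(r_2/r_1)}. With masses proportional to `radius^dim_d`,
#' the mass-weighted average of the two endpoint positions reduces to
#' \deqn{s = (\ell/2)\,\tanh(D\rho/2),}
#' which is odd and strictly increasing in \eqn{\rho} and bounded by
#' \eqn{\pm\ell/2}. `dim_d = 2` is veridical for flat disks; `dim_d = 3`
#' corresponds to treating the disks as spheres.
#'
#' @param rho Log radius ratio (natural log units); vectorized.
#' @param dim_d Exponent of the radius-to-mass mapping (> 0).
#' @param geometry A [task_geometry()].
#' @return Center of mass in cm relative to the bar midpoint.
#' @examples
#' com_map(log(1.5), 2)              # 4.615 cm
#' com_map(0, 3)                     # equal disks balance at the midpoint
#' @export
com_map <- function(rho, dim_d, geometry = task_geometry()) {
  if (!is.numeric(dim_d) || length(dim_d) != 1 || !is.finite(dim_d) ||
      dim_d <= 0) {
    abort("`dim_d` must be a single positive number.",
          class = "comreach_invalid_parameter")
  }
  stopifnot(inherits(geometry, "task_geometry"))
  (geometry$bar_length / 2) * tanh(dim_d * rho / 2)
}
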
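# Deterministic 1-D maximization on a dense grid with parabolic refinement.
# Used for the endpoint decisions, whose objectives (Gaussian mixtures plus
# an inverted-Gaussian adjustment term) can be multimodal: a dense scan is
# robust and reproducible where general-purpose optimizers are not.
# Ties are broken toward the smaller |s|.

grid_argmax <- function(f, lower, upper, step = 0.01, refine = TRUE,
                        flat_tol = 1e-12) {
  grid <- seq(lower, upper, by = step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  fx <- f(grid)
  fmax <- max(fx)
  if (fmax - min(fx) <= flat_tol * max(1, abs(fmax))) {
    # degenerate flat objective: midpoint of the maximizing set
    return(structure(mean(range(grid)), flat = TRUE, value = fmax))
  }
  cand <- which(fx >= fmax - flat_tol * max(1, abs(fmax)))
  i <- cand[which.min(abs(grid[cand]))]
  x <- grid[i]
  if (refine && i > 1 && i < length(fx)) {
    h <- grid[i + 1] - grid[i]
    den <- fx[i - 1] - 2 * fx[i] + fx[i + 1]
    if (is.finite(den) && den < 0) {
      dx <- 0.5 * h * (fx[i - 1] - fx[i + 1]) / den
      dx <- max(min(dx, h), -h)
      xr <- min(max(x + dx, lower), upper)
      if (f(xr) >= fx[i]) x <- xr
    }
  }
  structure(x, flat = FALSE, value = fmax)
}
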
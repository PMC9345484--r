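## Savitzky-Golay smoothing.
##
## The smoothed value at each interior sample is the value at the window
## center of the least-squares polynomial fitted to the surrounding window.
## Edge samples are handled as in scipy's mode = "interp": a polynomial is
## fitted to the first (last) full window and evaluated at the edge
## positions, so polynomials of degree <= polyorder pass through unchanged.

## Least-squares projector rows for a window: row i gives the coefficients
## that map the window samples to the fitted value at window position i.
savgol_projector <- function(window, polyorder) {
  half <- (window - 1L) %/% 2L
  A <- outer(seq(-half, half), 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing of a uniformly sampled signal
#'
#' @param x numeric vector without missing values.
#' @param window odd integer window length in samples.
#' @param polyorder polynomial order, less than `window`.
#' @return smoothed numeric vector, same length as `x`. If `x` is shorter
#'   than `window` it is returned unchanged (with a message), mirroring the
#'   contract that segments too short to smooth pass through.
#' @export
savgol_smooth <- function(x, window = 21L, polyorder = 2L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  n <- length(x)
  if (n < window) {
    message("segment of ", n, " samples shorter than Savitzky-Golay window (",
            window, "); passed through unsmoothed")
    return(x)
  }
  P <- savgol_projector(window, polyorder)
  half <- (window - 1L) %/% 2L
  ## interior: convolution with the center row (symmetric for the center
  ## evaluation point, so no reversal is needed)
  out <- as.numeric(stats::filter(x, P[half + 1L, ], sides = 2))
  ## edges: evaluate the first/last window fit at the edge positions
  out[1:half] <- (P %*% x[1:window])[1:half]
  out[(n - half + 1L):n] <- (P %*% x[(n - window + 1L):n])[(half + 2L):window]
  out
}
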
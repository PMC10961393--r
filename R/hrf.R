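#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF (SPM parameterization: response gamma with shape 6,
#' undershoot gamma with shape 16, both rate 1/s, undershoot scaled by 1/6,
#' 32 s support) on a grid of width \code{TR} starting at 0. The continuous
#' kernel peaks near 5 s and integrates to a positive value.
#'
#' @param TR sampling interval in seconds (> 0).
#' @param duration_s kernel support in seconds (default 32).
#' @return An object of class \code{"hrf_kernel"}: numeric vector of samples,
#'   peak-normalized to 1, with attributes \code{TR} and \code{times}.
#' @examples
#' h <- canonical_hrf(2.5)
#' length(h)          # 13 samples covering 0..32 s
#' which.max(h)       # sample at t = 5 s
#' @export
canonical_hrf <- function(TR, duration_s = 32) {
  stopifnot(is.numeric(TR), length(TR) == 1L, TR > 0)
  t <- seq(0, duration_s, by = TR)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  structure(h, TR = TR, times = t, kind = "canonical", class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("Canonical HRF kernel: %d samples at TR = %g s (peak at %g s)\n",
              length(x), attr(x, "TR"), attr(x, "times")[which.max(x)]))
  invisible(x)
}

# Convolve a stimulus vector sampled at TR with the HRF kernel, keeping the
# input length (causal convolution).
convolve_hrf <- function(x, hrf) {
  n <- length(x)
  out <- stats::convolve(x, rev(as.numeric(hrf)), type = "open")[seq_len(n)]
  out
}
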
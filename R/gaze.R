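#' Simulate a fixation trajectory over a stimulus
#'
#' Stand-in generator for eye-tracker fixation sequences during the 20 s
#' stimulation epochs: fixation centers are drawn from a Gaussian around the
#' centroid of the lit stimulus pixels (stimulus centered on the screen),
#' durations are log-normal, and the sequence is truncated so the total
#' duration never exceeds the stimulation epoch.
#'
#' @param stimulus a [render_navon()] object (must have lit pixels).
#' @param n_fixations number of fixations to attempt (>= 1).
#' @param dispersion SD of fixation placement around the lit-pixel centroid,
#'   in pixels; 0 puts every fixation exactly at the centroid.
#' @param seed integer seed.
#' @param screen_px c(width, height) of the screen in pixels; the stimulus
#'   raster is centered on it. Default 1280 x 1024.
#' @param epoch_ms stimulation epoch length in ms (default 20000).
#' @param mean_duration_ms median fixation duration (default 300 ms).
#' @return Object of class \code{"gaze_trajectory"}: data.frame
#'   \code{fixations} (x, y in screen px, duration_ms, onset_ms) plus
#'   \code{screen} and \code{dva_per_pixel}.
#' @examples
#' s <- render_navon("E", "Global", 0.05)
#' g <- simulate_gaze(s, 10, dispersion = 20, seed = 1)
#' sum(g$fixations$duration_ms) <= 20000
#' @export
simulate_gaze <- function(stimulus, n_fixations, dispersion, seed = NULL,
                          screen_px = c(1280, 1024), epoch_ms = 20000,
                          mean_duration_ms = 300) {
  stopifnot(n_fixations >= 1, dispersion >= 0)
  lit <- which(stimulus$raster == 1, arr.ind = TRUE)
  if (nrow(lit) == 0) stop("empty stimulus raster")
  # stimulus centered on screen; raster rows = y (top down), cols = x
  off_x <- (screen_px[1] - ncol(stimulus$raster)) / 2
  off_y <- (screen_px[2] - nrow(stimulus$raster)) / 2
  cx <- mean(lit[, "col"]) + off_x
  cy <- mean(lit[, "row"]) + off_y
  with_seed(seed, {
    x <- cx + dispersion * stats::rnorm(n_fixations)
    y <- cy + dispersion * stats::rnorm(n_fixations)
    x <- pmin(pmax(x, 1), screen_px[1])
    y <- pmin(pmax(y, 1), screen_px[2])
    dur <- stats::rlnorm(n_fixations, meanlog = log(mean_duration_ms), sdlog = 0.4)
    dur <- pmax(dur, 1)
    onset <- cumsum(c(0, dur[-n_fixations]))
    keep <- onset < epoch_ms
    x <- x[keep]; y <- y[keep]; dur <- dur[keep]; onset <- onset[keep]
    over <- (onset + dur) > epoch_ms
    dur[over] <- epoch_ms - onset[over]
    structure(
      list(fixations = data.frame(x = x, y = y, duration_ms = dur,
                                  onset_ms = onset),
           screen = screen_px, dva_per_pixel = stimulus$dva_per_pixel),
      class = "gaze_trajectory")
  })
}

#' @export
print.gaze_trajectory <- function(x, ...) {
  cat(sprintf("Gaze trajectory: %d fixations, %.0f ms total, screen %d x %d px\n",
              nrow(x$fixations), sum(x$fixations$duration_ms),
              x$screen[1], x$screen[2]))
  invisible(x)
}
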
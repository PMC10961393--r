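#' Build a Gabor filter pyramid modeling V1
#'
#' Quadrature-pair Gabor filters at five spatial-frequency levels (1, 2, 4,
#' 8, 16 cycles/FOV), eight orientations (0..157.5 deg) and two phases,
#' tiling the field of view at evenly spaced positions per level (2, 8, 16,
#' 64, 256). Collapsing orientation and phase leaves one node per (level,
#' position): 346 nodes for the full bank. Kernels are zero-mean (no DC
#' response) and L2-normalized.
#'
#' @param fov_px c(width, height) of the field of view in pixels (>= 64).
#' @param levels spatial frequencies in cycles/FOV.
#' @param positions_per_level position counts matching \code{levels}.
#' @param n_orient number of orientations.
#' @return Object of class \code{"gabor_bank"}: \code{filters} (n_filters x
#'   n_pixels matrix, rows ordered phase within orientation within position
#'   within level), \code{meta} (per-filter level/position/orientation/phase),
#'   \code{node_of} (node id per filter), \code{nodes} (per-node level and
#'   position), \code{fov}.
#' @examples
#' b <- build_gabor_bank(c(64, 64), levels = c(1, 2), positions_per_level = c(2, 8))
#' nrow(b$nodes)  # 10 nodes
#' @export
build_gabor_bank <- function(fov_px = c(128, 128),
                             levels = c(1, 2, 4, 8, 16),
                             positions_per_level = c(2, 8, 16, 64, 256),
                             n_orient = 8) {
  stopifnot(length(fov_px) == 2, all(fov_px >= 64),
            length(levels) == length(positions_per_level))
  W <- fov_px[1]; H <- fov_px[2]
  X <- matrix(rep(seq_len(W), each = H), H, W)   # column = x
  Y <- matrix(rep(seq_len(H), times = W), H, W)  # row = y
  orientations <- (seq_len(n_orient) - 1) * 180 / n_orient
  filt_rows <- list(); meta <- list()
  for (li in seq_along(levels)) {
    f <- levels[li]
    lambda <- W / f
    sigma <- lambda / 2
    g <- position_grid(positions_per_level[li])
    px <- (rep(seq_len(g[1]), each = g[2]) - 0.5) / g[1] * W
    py <- (rep(seq_len(g[2]), times = g[1]) - 0.5) / g[2] * H
    for (p in seq_along(px)) {
      dx <- X - px[p]; dy <- Y - py[p]
      env <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
      for (th in orientations) {
        u <- dx * cos(th * pi / 180) + dy * sin(th * pi / 180)
        for (phase in c(0, 90)) {
          k <- env * cos(2 * pi * u / lambda + phase * pi / 180)
          k <- k - mean(k)
          k <- k / sqrt(sum(k^2))
          filt_rows[[length(filt_rows) + 1L]] <- as.vector(k)
          meta[[length(meta) + 1L]] <- c(level = f, pos_x = px[p], pos_y = py[p],
                                         orientation = th, phase = phase)
        }
      }
    }
  }
  meta <- as.data.frame(do.call(rbind, meta))
  node_key <- paste(meta$level, meta$pos_x, meta$pos_y)
  node_of <- match(node_key, unique(node_key))
  nodes <- meta[!duplicated(node_key), c("level", "pos_x", "pos_y")]
  rownames(nodes) <- NULL
  structure(list(filters = do.call(rbind, filt_rows), meta = meta,
                 node_of = node_of, nodes = nodes, fov = fov_px,
                 n_orient = n_orient),
            class = "gabor_bank")
}

# Near-square grid (nx, ny) with nx >= ny for n evenly spaced positions.
position_grid <- function(n) {
  ny <- 2^floor(log2(sqrt(n)))
  nx <- n / ny
  if (nx != round(nx)) stop("position count must factor into a 2^k grid: ", n)
  c(nx, ny)
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("Gabor bank: %d filters, %d nodes, FOV %d x %d px (levels %s cycles/FOV)\n",
              nrow(x$filters), nrow(x$nodes), x$fov[1], x$fov[2],
              paste(unique(x$meta$level), collapse = ", ")))
  invisible(x)
}

#' Retina-centered stimulus under a fixation
#'
#' Translates the screen image so the fixation point moves to the screen
#' center (the retinal image), zero-padding uncovered regions. A fixation d
#' pixels right of center shifts the stimulus d pixels left.
#'
#' @param raster screen image matrix (rows = y, cols = x), or a
#'   \code{"navon_stimulus"}.
#' @param fixation c(x, y) in pixel coordinates of the raster.
#' @return Shifted raster of identical dimensions.
#' @export
gaze_shift_stimulus <- function(raster, fixation) {
  if (inherits(raster, "navon_stimulus")) raster <- raster$raster
  H <- nrow(raster); W <- ncol(raster)
  dx <- round(fixation[1] - (W + 1) / 2)
  dy <- round(fixation[2] - (H + 1) / 2)
  out <- matrix(0, H, W)
  src_r <- (1 + max(dy, 0)):(H + min(dy, 0))
  src_c <- (1 + max(dx, 0)):(W + min(dx, 0))
  if (length(src_r) > 0 && length(src_c) > 0 &&
      src_r[1] <= H && src_c[1] <= W) {
    out[src_r - dy, src_c - dx] <- raster[src_r, src_c]
  }
  out
}

# Embed a (smaller) stimulus raster centered in a canvas of given size.
embed_centered <- function(raster, canvas_px) {
  if (inherits(raster, "navon_stimulus")) raster <- raster$raster
  W <- canvas_px[1]; H <- canvas_px[2]
  h <- nrow(raster); w <- ncol(raster)
  if (h > H || w > W) stop("stimulus larger than canvas")
  out <- matrix(0, H, W)
  r0 <- floor((H - h) / 2); c0 <- floor((W - w) / 2)
  out[r0 + seq_len(h), c0 + seq_len(w)] <- raster
  out
}

#' Node responses of the Gabor bank per fixation
#'
#' For each fixation: shifts the stimulus to retinal coordinates, applies
#' every Gabor filter, and collapses orientation and phase at each position:
#' quadrature energy sqrt(even^2 + odd^2) over the two phases, summed over
#' orientations, giving one nonnegative value per (level, position) node.
#' Fixation coordinates given on a different screen size are rescaled to the
#' bank's FOV.
#'
#' @param bank a [build_gabor_bank()].
#' @param stimulus a \code{"navon_stimulus"} or raster matrix (embedded
#'   centered in the FOV if smaller).
#' @param trajectory a [simulate_gaze()] result (or data.frame with x, y,
#'   duration_ms).
#' @param collapse "energy" (default) or "sum" (plain summation over
#'   orientation/phase).
#' @return nodes x fixations matrix of responses.
#' @export
fixation_node_responses <- function(bank, stimulus, trajectory,
                                    collapse = c("energy", "sum")) {
  collapse <- match.arg(collapse)
  fx <- if (inherits(trajectory, "gaze_trajectory")) trajectory$fixations else trajectory
  if (nrow(fx) == 0) stop("empty trajectory")
  canvas <- embed_centered(stimulus, bank$fov)
  sx <- if (inherits(trajectory, "gaze_trajectory")) trajectory$screen else bank$fov
  xs <- fx$x * bank$fov[1] / sx[1]
  ys <- fx$y * bank$fov[2] / sx[2]
  imgs <- vapply(seq_len(nrow(fx)), function(i)
    as.vector(gaze_shift_stimulus(canvas, c(xs[i], ys[i]))),
    numeric(length(canvas)))
  R <- bank$filters %*% imgs                       # filters x fixations
  even <- R[bank$meta$phase == 0, , drop = FALSE]
  odd <- R[bank$meta$phase == 90, , drop = FALSE]
  pair_node <- bank$node_of[bank$meta$phase == 0]
  per_pair <- if (collapse == "energy") sqrt(even^2 + odd^2) else even + odd
  out <- rowsum(per_pair, pair_node)               # sum over orientations
  rownames(out) <- NULL
  out
}

#' Expand fixation responses into an artificial BOLD series
#'
#' Holds each fixation's node response for its duration on a 1 ms grid,
#' convolves with the canonical HRF and samples at the TR grid (equivalent to
#' dense convolution followed by decimation by sampling; computed exactly via
#' step-response superposition with the cumulative 1 ms HRF). No noise is
#' added.
#'
#' @param responses nodes x fixations matrix from [fixation_node_responses()].
#' @param trajectory the matching trajectory (onset_ms, duration_ms used).
#' @param TR sampling interval in seconds (default 2.5).
#' @param n_samples number of TR samples to produce (default: epoch length /
#'   TR, i.e. 8 for a 20 s block).
#' @param epoch_ms epoch length in ms.
#' @return time x node matrix at the TR grid.
#' @export
simulate_bold <- function(responses, trajectory, TR = 2.5, n_samples = NULL,
                          epoch_ms = 20000) {
  fx <- if (inherits(trajectory, "gaze_trajectory")) trajectory$fixations else trajectory
  if (nrow(fx) == 0) stop("empty trajectory")
  stopifnot(ncol(responses) == nrow(fx))
  if (is.null(n_samples)) n_samples <- round(epoch_ms / 1000 / TR)
  h <- as.numeric(canonical_hrf(0.001))
  CH <- cumsum(h)
  ch_at <- function(u) {            # u in ms (vector); CH(u < 1) = 0
    v <- numeric(length(u))
    inside <- u >= 1
    v[inside] <- CH[pmin(u[inside], length(CH))]
    v
  }
  t_ms <- seq_len(n_samples) * TR * 1000
  on <- round(fx$onset_ms); off <- round(fx$onset_ms + fx$duration_ms)
  # weight of fixation f at sample k: CH(t_k - on_f) - CH(t_k - off_f)
  Wt <- matrix(0, nrow(fx), n_samples)
  for (k in seq_len(n_samples))
    Wt[, k] <- ch_at(t_ms[k] - on) - ch_at(t_ms[k] - off)
  t(responses %*% Wt)                     # time x node
}
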
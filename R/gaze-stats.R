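#' Fixation-duration heatmap
#'
#' Projects fixations onto the screen as Dirac deltas with amplitude equal to
#' their durations, convolves with a 2D Gaussian kernel (normalized to unit
#' mass), and downsizes the result by block summation at the given scale, so
#' the total map mass equals the total fixation duration (up to truncation of
#' kernel tails at the screen borders).
#'
#' @param trajectory a [simulate_gaze()] result, or a data.frame with x, y,
#'   duration_ms plus a \code{screen} attribute/argument.
#' @param kernel_sd Gaussian SD in screen pixels (the experiment used 5, 10,
#'   20 and 40; other values are allowed with a warning; 0 skips smoothing).
#' @param downscale scale factor (default 0.25; 1/downscale must be integer).
#' @param screen_px screen size, taken from the trajectory when present.
#' @return Object of class \code{"gaze_heatmap"}: \code{grid} (rows = y) of
#'   dimension screen * downscale, \code{kernel_sd}, \code{downscale}.
#' @export
fixation_heatmap <- function(trajectory, kernel_sd, downscale = 0.25,
                             screen_px = NULL) {
  fx <- if (inherits(trajectory, "gaze_trajectory")) trajectory$fixations else trajectory
  if (is.null(screen_px))
    screen_px <- if (inherits(trajectory, "gaze_trajectory")) trajectory$screen
    else stop("screen_px required")
  if (!kernel_sd %in% c(0, 5, 10, 20, 40))
    warning("kernel_sd outside the standard set {5, 10, 20, 40}")
  W <- screen_px[1]; H <- screen_px[2]
  x <- round(fx$x); y <- round(fx$y)
  if (any(x < 1 | x > W | y < 1 | y > H)) {
    warning("fixation off screen; clipped")
    x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  }
  img <- matrix(0, H, W)
  for (i in seq_along(x)) img[y[i], x[i]] <- img[y[i], x[i]] + fx$duration_ms[i]
  if (kernel_sd > 0) img <- gauss_smooth2d(img, kernel_sd)
  f <- round(1 / downscale)
  if (abs(f - 1 / downscale) > 1e-8) stop("1/downscale must be an integer")
  grid <- block_sum(img, f)
  structure(list(grid = grid, kernel_sd = kernel_sd, downscale = downscale,
                 screen = screen_px),
            class = "gaze_heatmap")
}

# Separable 2D Gaussian smoothing with zero padding; kernel sums to 1.
gauss_smooth2d <- function(img, sd) {
  r <- ceiling(3.5 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  smooth1 <- function(m) {              # along rows (first dim)
    n <- nrow(m)
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

# Downscale by f x f block summation, zero-padding to a multiple of f.
block_sum <- function(img, f) {
  H <- ceiling(nrow(img) / f) * f
  W <- ceiling(ncol(img) / f) * f
  if (H != nrow(img) || W != ncol(img)) {
    pad <- matrix(0, H, W)
    pad[seq_len(nrow(img)), seq_len(ncol(img))] <- img
    img <- pad
  }
  gr <- rep(seq_len(H / f), each = f)
  gc <- rep(seq_len(W / f), each = f)
  t(rowsum(t(rowsum(img, gr)), gc))
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("Gaze heatmap: %d x %d grid (downscale %g, kernel sd %g px), mass %.0f\n",
              nrow(x$grid), ncol(x$grid), x$downscale, x$kernel_sd, sum(x$grid)))
  invisible(x)
}

# ---- vectorized mass-univariate random-intercept LMM ------------------------

# Profiled-ML fit of y ~ X + (1 | group) for many outcomes at once.
# For each candidate variance ratio lambda = var_u / var_e the model is
# whitened in closed form (group-mean shrinkage), reducing each pixel to OLS;
# lambda maximizing the profiled ML log-likelihood is selected per pixel from
# the grid. Wald t uses between-within denominator df (n - groups - p + 1),
# the standard choice for within-group effects under a random intercept.
pixel_lmm_fit <- function(Y, X, group,
                          lambdas = c(0, exp(seq(log(1e-3), log(1e3),
                                                 length.out = 25)))) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); p <- ncol(X)
  g <- as.integer(factor(group))
  ng <- tabulate(g)
  npix <- ncol(Y)
  nll <- matrix(Inf, length(lambdas), npix)
  store <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    cg <- 1 - 1 / sqrt(1 + ng * lam)
    Ys <- Y - (cg[g]) * (rowsum(Y, g) / ng)[g, , drop = FALSE]
    Xs <- X - (cg[g]) * (rowsum(X, g) / ng)[g, , drop = FALSE]
    qx <- qr(Xs)
    beta <- qr.coef(qx, Ys)
    rss <- colSums((Ys - Xs %*% beta)^2)
    rss <- pmax(rss, 1e-300)
    nll[li, ] <- n * (log(2 * pi * rss / n) + 1) + sum(log(1 + ng * lam))
    xtxinv_diag <- diag(chol2inv(qr.R(qx)))
    store[[li]] <- list(beta = beta, rss = rss, xtxinv = xtxinv_diag)
  }
  best <- max.col(-t(nll), ties.method = "first")
  beta <- matrix(0, p, npix); se <- matrix(0, p, npix)
  df_bw <- max(n - length(unique(g)) - p + 1, 1)
  for (li in unique(best)) {
    idx <- which(best == li)
    st <- store[[li]]
    beta[, idx] <- st$beta[, idx, drop = FALSE]
    sig2 <- st$rss[idx] / df_bw
    se[, idx] <- sqrt(outer(st$xtxinv, sig2))
  }
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df_bw)
  dimnames(beta) <- dimnames(se) <- dimnames(tval) <- dimnames(pval) <-
    list(colnames(X), NULL)
  list(beta = beta, se = se, t = tval, p = pval,
       lambda = lambdas[best], n = n, p_terms = p, df = df_bw)
}

#' Mass-univariate mixed models over heatmap pixels
#'
#' Fits, at every pixel with nonzero signal, the linear mixed model
#' heatmap ~ 1 + Level + Letter + TrialOrder + Level:Letter + (1 | participant)
#' by maximum likelihood, and returns coefficient, t and p maps for the fixed
#' effects. Level and Letter use +-0.5 sum-to-zero coding so their
#' coefficients are average condition differences; TrialOrder is centered.
#' The fitter is a vectorized profiled-ML solver specialized to the
#' random-intercept structure (the design is shared across pixels), selecting
#' the variance ratio per pixel on a grid.
#'
#' @param heatmaps list of [fixation_heatmap()] objects (one per trial), or an
#'   n_trials x n_pixels matrix with a \code{dims} attribute.
#' @param design data.frame with columns \code{participant}, \code{level}
#'   ("Global"/"Local"), \code{letter} ("E"/"U"), \code{trial_order}.
#' @return Object of class \code{"pixel_lmm"}: coefficient/se/t/p matrices
#'   over masked pixels, \code{mask} (pixel indices), \code{dims} (grid
#'   dimensions), plus the design pieces needed for bootstrapping.
#' @export
fit_pixel_models <- function(heatmaps, design,
                             lambdas = c(0, exp(seq(log(1e-3), log(1e3),
                                                    length.out = 25)))) {
  if (is.list(heatmaps)) {
    dims <- dim(heatmaps[[1]]$grid)
    Y <- t(vapply(heatmaps, function(h) as.vector(h$grid),
                  numeric(prod(dims))))
  } else {
    Y <- as.matrix(heatmaps)
    dims <- attr(heatmaps, "dims")
    if (is.null(dims)) stop("matrix input needs a 'dims' attribute")
  }
  stopifnot(nrow(Y) == nrow(design))
  if (length(unique(design$participant)) < 2)
    stop("need at least 2 participants")
  mask <- which(colSums(Y != 0) > 0)
  X <- lmm_design_matrix(design)
  fit <- pixel_lmm_fit(Y[, mask, drop = FALSE], X, design$participant, lambdas)
  structure(c(fit, list(mask = mask, dims = dims,
                        Y = Y[, mask, drop = FALSE], X = X,
                        participant = design$participant, lambdas = lambdas)),
            class = "pixel_lmm")
}

lmm_design_matrix <- function(design) {
  lv <- ifelse(design$level == "Local", 0.5, -0.5)
  lt <- ifelse(design$letter == "U", 0.5, -0.5)
  to <- scale(design$trial_order, scale = FALSE)[, 1]
  cbind("(Intercept)" = 1, level = lv, letter = lt, trial_order = to,
        "level:letter" = lv * lt)
}

#' @export
print.pixel_lmm <- function(x, ...) {
  cat(sprintf("Mass-univariate LMM: %d nonzero pixels on a %d x %d grid, %d trials\n",
              length(x$mask), x$dims[1], x$dims[2], x$n))
  invisible(x)
}

# 8-connected component labeling of a logical matrix; returns integer labels.
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      r <- ((v - 1L) %% H) + 1L
      c <- ((v - 1L) %/% H) + 1L
      nr <- r + offs[, 1]; nc <- c + offs[, 2]
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      nb <- (nc[ok] - 1L) * H + nr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Bootstrap cluster-mass inference on pixelwise LMM maps
#'
#' Thresholds the parametric p-map of one fixed effect at
#' \code{alpha_forming / n_nonzero_pixels}, forms 8-connected clusters of
#' supra-threshold pixels, and scores each by its mass (sum of the effect's
#' coefficient values). The null distribution is built by removing the fitted
#' contribution of the tested effect from the data (bootstrap under the
#' null), resampling participants with replacement, refitting, re-forming
#' clusters under the same threshold, and recording the maximum absolute
#' cluster mass per resample (max-statistic family-wise control). Cluster
#' p = (1 + #\{null max >= |mass|\}) / (1 + n_boot).
#'
#' @param fit a [fit_pixel_models()] result.
#' @param contrast fixed-effect name (default "level").
#' @param alpha_forming cluster-forming alpha before the Bonferroni division
#'   (default 0.05).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return Object of class \code{"cluster_result"}: \code{clusters}
#'   data.frame (id, size, mass, p), \code{threshold}, \code{labels} (label
#'   image), \code{null_max}.
#' @export
cluster_mass_bootstrap <- function(fit, contrast = "level",
                                   alpha_forming = 0.05, n_boot = 1000,
                                   seed = NULL) {
  stopifnot(inherits(fit, "pixel_lmm"), alpha_forming > 0, alpha_forming < 1)
  thr <- alpha_forming / length(fit$mask)
  clusters_of <- function(pvec, cvec) {
    supra_img <- matrix(FALSE, fit$dims[1], fit$dims[2])
    supra_img[fit$mask[pvec < thr]] <- TRUE
    lab <- label_components8(supra_img)
    if (max(lab) == 0)
      return(list(labels = lab, mass = numeric(0), size = integer(0)))
    coef_img <- matrix(0, fit$dims[1], fit$dims[2])
    coef_img[fit$mask] <- cvec
    mass <- vapply(seq_len(max(lab)), function(k) sum(coef_img[lab == k]), 0)
    size <- tabulate(lab[lab > 0], nbins = max(lab))
    list(labels = lab, mass = mass, size = size)
  }
  obs <- clusters_of(fit$p[contrast, ], fit$beta[contrast, ])
  if (length(obs$mass) == 0) {   # nothing to test; skip the bootstrap
    return(structure(list(
      clusters = data.frame(id = integer(0), size = integer(0),
                            mass = numeric(0), p = numeric(0)),
      threshold = thr, labels = obs$labels, null_max = numeric(0),
      contrast = contrast, n_boot = n_boot),
      class = "cluster_result"))
  }
  # null-centered data: remove the tested effect's fitted contribution
  Y0 <- fit$Y - fit$X[, contrast] %o% fit$beta[contrast, ]
  parts <- unique(fit$participant)
  rows_of <- lapply(parts, function(pp) which(fit$participant == pp))
  null_max <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    take <- sample(length(parts), replace = TRUE)
    idx <- unlist(rows_of[take], use.names = FALSE)
    grp <- rep(seq_along(take), times = lengths(rows_of[take]))
    rf <- pixel_lmm_fit(Y0[idx, , drop = FALSE],
                        fit$X[idx, , drop = FALSE], grp, fit$lambdas)
    cl <- clusters_of(rf$p[contrast, ], rf$beta[contrast, ])
    if (length(cl$mass)) max(abs(cl$mass)) else 0
  }, 0))
  pvals <- vapply(abs(obs$mass), function(m)
    (1 + sum(null_max >= m)) / (1 + n_boot), 0)
  structure(list(
    clusters = data.frame(id = seq_along(obs$mass), size = obs$size,
                          mass = obs$mass, p = pvals),
    threshold = thr, labels = obs$labels, null_max = null_max,
    contrast = contrast, n_boot = n_boot),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster-mass bootstrap (%s, forming threshold p < %.3g, %d resamples)\n",
              x$contrast, x$threshold, x$n_boot))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}
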
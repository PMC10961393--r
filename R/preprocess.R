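#' Discrete cosine drift basis
#'
#' DCT regressors spanning fluctuations slower than \code{cutoff_s}, the
#' standard GLM equivalent of a high-pass filter with that time constant.
#'
#' @param n_vol number of volumes.
#' @param TR repetition time (s).
#' @param cutoff_s high-pass time constant in seconds (default 128).
#' @return Matrix with \code{floor(2 * n_vol * TR / cutoff_s)} columns (may be
#'   zero columns for short runs).
#' @export
dct_basis <- function(n_vol, TR, cutoff_s = 128) {
  K <- floor(2 * n_vol * TR / cutoff_s)
  t <- seq_len(n_vol) - 0.5
  X <- sapply(seq_len(K), function(k) cos(pi * k * t / n_vol))
  if (K == 0) X <- matrix(0, n_vol, 0) else X <- matrix(X, n_vol, K)
  colnames(X) <- if (K > 0) paste0("dct", seq_len(K)) else character(0)
  X
}

#' Nuisance regression with high-pass filtering
#'
#' Removes the least-squares projection of the data onto the confound
#' regressors, an intercept, and a discrete-cosine drift basis up to the
#' high-pass cutoff. Residuals are orthogonal to all regressors.
#'
#' @param bold time x vertex matrix.
#' @param confounds time x k matrix (may have zero columns).
#' @param TR repetition time in seconds.
#' @param highpass_cutoff_s high-pass time constant (s), default 128; NULL
#'   disables the drift basis.
#' @return Residual bold matrix of the same dimension.
#' @export
nuisance_regress <- function(bold, confounds = NULL, TR, highpass_cutoff_s = 128) {
  bold <- as.matrix(bold)
  n <- nrow(bold)
  if (is.null(confounds)) confounds <- matrix(0, n, 0)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n) stop("confound time dimension does not match bold")
  X <- cbind(1, confounds,
             if (!is.null(highpass_cutoff_s)) dct_basis(n, TR, highpass_cutoff_s))
  ols_residuals(bold, X)
}

# OLS residuals of Y on X via rank-revealing QR; warns on rank deficiency and
# falls back to the pseudoinverse solution (residuals are identical).
ols_residuals <- function(Y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning(sprintf("rank-deficient design (%d of %d); using pseudoinverse",
                    qr_x$rank, ncol(X)))
  Y - qr.fitted(qr_x, Y)
}

#' Deconvolve the stimulus-evoked response with a GLM
#'
#' Removes the modeled evoked response from full-run time series, enhancing
#' subject-idiosyncratic/background activity. Two basis sets are supported:
#' \code{"canonical"} models each condition as a 20 s boxcar convolved with
#' the canonical HRF; \code{"FIR"} models each condition with 19 unit-impulse
#' regressors at TR lags 0..18 from each stimulation onset (flexible enough to
#' span any TR-locked response shape). All condition regressors are fit
#' jointly with an intercept by OLS per vertex; residuals are returned.
#'
#' @param bold time x vertex matrix for one run.
#' @param schedule a [make_block_schedule()]; only the given run's rows are used.
#' @param run run number within the schedule.
#' @param basis "canonical" or "FIR".
#' @param n_fir number of FIR delta regressors per condition (default 19).
#' @return Residual bold matrix.
#' @export
deconvolve_glm <- function(bold, schedule, run, basis = c("canonical", "FIR"),
                           n_fir = 19) {
  basis <- match.arg(basis)
  bold <- as.matrix(bold)
  TR <- attr(schedule, "TR")
  n_vol <- nrow(bold)
  X <- design_matrix(schedule, run, basis, n_vol, TR, n_fir)
  qr_x <- qr(cbind(1, X))
  if (basis == "FIR" && qr_x$rank < ncol(X) + 1)
    warning("collinear FIR design (overlapping windows); using pseudoinverse")
  bold - qr.fitted(qr_x, bold)
}

# Condition regressor block (no intercept) for one run.
design_matrix <- function(schedule, run, basis, n_vol, TR, n_fir = 19) {
  if (basis == "canonical") {
    X <- sapply(V1_CONDITIONS, function(cond)
      evoked_regressor(schedule, run, cond, n_vol, TR))
    colnames(X) <- V1_CONDITIONS
    return(X)
  }
  blocks <- schedule[schedule$run == run, ]
  X <- matrix(0, n_vol, 4 * n_fir)
  colnames(X) <- paste0(rep(V1_CONDITIONS, each = n_fir), "_lag",
                        rep(seq_len(n_fir) - 1, 4))
  for (i in seq_len(nrow(blocks))) {
    k <- match(blocks$condition[i], V1_CONDITIONS)
    on <- round(blocks$stim_onset_s[i] / TR)   # 0-based volume of onset
    for (l in seq_len(n_fir) - 1L) {
      t <- on + l + 1L
      if (t >= 1 && t <= n_vol) X[t, (k - 1) * n_fir + l + 1L] <- 1
    }
  }
  X
}

#' Segment, detrend and concatenate stimulation epochs of one condition
#'
#' Extracts the 20 s stimulation window of every block of the named condition
#' (shifted by the hemodynamic lag and rounded to the TR grid), linearly
#' detrends each segment independently (removing mean and slope), and
#' concatenates the segments in run/block order. With 5 runs this yields 120
#' time points per condition (3 blocks x 8 TRs x 5 runs); with 4 runs, 96.
#'
#' @param bold_runs list of time x vertex matrices, one per run.
#' @param schedule a [make_block_schedule()].
#' @param condition one of EG, EL, UG, UL.
#' @param lag_s hemodynamic lag in seconds (default 5; should be near the
#'   canonical HRF peak).
#' @return Object of class \code{"condition_series"}: list with \code{data}
#'   (concatenated time x vertex), \code{segment_boundaries} (start indices),
#'   \code{condition}, \code{TR}.
#' @export
segment_concatenate <- function(bold_runs, schedule, condition, lag_s = 5) {
  TR <- attr(schedule, "TR")
  stopifnot(condition %in% V1_CONDITIONS)
  segs <- list()
  for (r in seq_along(bold_runs)) {
    bold <- as.matrix(bold_runs[[r]])
    blocks <- schedule[schedule$run == r & schedule$condition == condition, ]
    n_stim <- round(blocks$stim_duration_s[1] / TR)
    for (i in seq_len(nrow(blocks))) {
      start <- round((blocks$stim_onset_s[i] + lag_s) / TR) + 1L  # 1-based
      idx <- start:(start + n_stim - 1L)
      if (max(idx) > nrow(bold))
        stop("stimulation window exceeds run length after lag shift")
      segs[[length(segs) + 1L]] <- detrend_linear(bold[idx, , drop = FALSE])
    }
  }
  data <- do.call(rbind, segs)
  starts <- cumsum(c(1, vapply(segs, nrow, 1L)))[seq_along(segs)]
  structure(list(data = data, segment_boundaries = starts,
                 condition = condition, TR = TR),
            class = "condition_series")
}

# Remove per-column mean and best-fit line from a segment.
detrend_linear <- function(x) {
  n <- nrow(x)
  t <- seq_len(n) - (n + 1) / 2
  x <- sweep(x, 2, colMeans(x))
  x - t %o% (crossprod(t, x)[1, ] / sum(t^2))
}

#' Full preprocessing to per-condition series for one subject
#'
#' Applies the pipeline in the fixed order: nuisance regression with 128 s
#' high-pass on full runs, optional deconvolution GLM on full runs, then
#' epoch segmentation/detrending/concatenation. Deconvolution is deliberately
#' applied on full runs before segmentation (the two orders are not
#' equivalent).
#'
#' @param dataset a subject element of a [simulate_cohort()] result (fields
#'   \code{runs} with \code{bold}, \code{confounds}).
#' @param schedule the cohort's block schedule.
#' @param condition condition to extract.
#' @param scheme "raw" (no deconvolution; also the input to common-response
#'   matrices), "HRFc" or "FIR".
#' @param lag_s hemodynamic lag (s).
#' @param highpass_cutoff_s high-pass time constant (s).
#' @return A [segment_concatenate()] result.
#' @export
condition_series <- function(dataset, schedule, condition,
                             scheme = c("raw", "HRFc", "FIR"), lag_s = 5,
                             highpass_cutoff_s = 128) {
  scheme <- match.arg(scheme)
  runs <- lapply(seq_along(dataset$runs), function(r) {
    run <- dataset$runs[[r]]
    x <- nuisance_regress(run$bold, run$confounds, run$TR, highpass_cutoff_s)
    if (scheme == "HRFc") x <- deconvolve_glm(x, schedule, r, "canonical")
    if (scheme == "FIR") x <- deconvolve_glm(x, schedule, r, "FIR")
    x
  })
  segment_concatenate(runs, schedule, condition, lag_s)
}
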
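#' Simulate a multi-subject V1 cohort
#'
#' Generates per-run vertex time series for each subject as the sum of three
#' sources: a cohort-common evoked response (a condition-specific spatial
#' pattern times the boxcar-convolved canonical HRF regressor), an
#' idiosyncratic evoked response (subject-specific gain and pattern jitter on
#' the same regressor), and temporally autocorrelated background activity
#' whose vertex covariance follows the planted per-condition structure during
#' stimulation epochs (shifted by the hemodynamic lag) and is isotropic
#' elsewhere. Confound signals (linear drift plus six pseudo-motion random
#' walks) are mixed into the data and returned alongside it.
#'
#' Fully reproducible: identical \code{(seed, effect, schedule, map)} give
#' bitwise-identical cohorts.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param map a [build_retinotopic_map()] result.
#' @param schedule a [make_block_schedule()] result.
#' @param effect an [effect_spec()].
#' @param seed integer seed.
#' @param lag_s hemodynamic lag (s) aligning planted epochs with the
#'   segmentation downstream; default 5.
#' @return An object of class \code{"v1_cohort"}: list with \code{subjects}
#'   (each with \code{subject_id}, \code{runs} = list of
#'   \code{list(bold, TR, confounds)}), \code{map}, \code{schedule},
#'   \code{effect}, \code{seed}.
#' @examples
#' map <- build_retinotopic_map(20, seed = 1)
#' sch <- make_block_schedule(4, seed = 1)
#' coh <- simulate_cohort(3, map, sch, effect_spec("null"), seed = 1)
#' dim(coh$subjects[[1]]$runs[[1]]$bold)
#' @export
simulate_cohort <- function(n_subjects, map, schedule, effect, seed = NULL,
                            lag_s = 5) {
  stopifnot(n_subjects >= 2, inherits(effect, "effect_spec"))
  TR <- attr(schedule, "TR")
  n_vol <- attr(schedule, "n_volumes")
  n_runs <- attr(schedule, "n_runs")
  V <- nrow(map)
  hrf <- canonical_hrf(TR)

  # Condition chol factors (shared across subjects); may stop() on non-PSD.
  chol_by_cond <- lapply(V1_CONDITIONS, function(cond)
    planted_correlation(map, effect, cond))
  names(chol_by_cond) <- V1_CONDITIONS

  regs <- lapply(seq_len(n_runs), function(r)
    sapply(V1_CONDITIONS, function(cond)
      evoked_regressor(schedule, r, cond, n_vol, TR, hrf)))
  states <- lapply(seq_len(n_runs), function(r)
    epoch_state(schedule, r, TR, n_vol, lag_s))

  with_seed(seed, {
    patterns <- matrix(stats::rnorm(V * 4), V, 4,
                       dimnames = list(NULL, V1_CONDITIONS))
    innov_sd <- effect$bg_sd * sqrt(1 - effect$ar1^2)
    subjects <- lapply(seq_len(n_subjects), function(s) {
      gain <- 1 + effect$idio_sd * stats::rnorm(4)
      pat_jit <- effect$idio_sd * matrix(stats::rnorm(V * 4), V, 4)
      runs <- lapply(seq_len(n_runs), function(r) {
        X <- regs[[r]]   # n_vol x 4 evoked regressors
        bold <- matrix(0, n_vol, V)
        for (k in seq_along(V1_CONDITIONS)) {
          pat_s <- effect$common_gain[k] * (gain[k] * patterns[, k] + pat_jit[, k])
          bold <- bold + X[, k] %o% pat_s
        }
        # background: state-dependent innovations + AR(1) recursion
        E <- matrix(stats::rnorm(n_vol * V), n_vol, V)
        st <- states[[r]]
        for (k in seq_along(V1_CONDITIONS)) {
          rows <- which(st == k)
          if (length(rows))
            E[rows, ] <- E[rows, , drop = FALSE] %*% chol_by_cond[[k]]
        }
        E <- E * innov_sd
        if (effect$ar1 != 0 && n_vol > 1)
          for (t in 2:n_vol) E[t, ] <- E[t, ] + effect$ar1 * E[t - 1, ]
        bold <- bold + E
        # confounds: drift + 6 pseudo-motion random walks, leaked into bold
        drift <- seq_len(n_vol) / n_vol - 0.5
        motion <- apply(matrix(stats::rnorm(n_vol * 6, sd = 0.1), n_vol, 6),
                        2, cumsum)
        confounds <- cbind(drift = drift, motion)
        colnames(confounds) <- c("drift", paste0("motion", 1:6))
        leak <- matrix(stats::rnorm(7 * V, sd = 0.15 * effect$bg_sd), 7, V)
        bold <- bold + confounds %*% leak
        list(bold = bold, TR = TR, confounds = confounds)
      })
      structure(list(subject_id = s, runs = runs, seed = seed),
                class = "subject_dataset")
    })
    structure(list(subjects = subjects, map = map, schedule = schedule,
                   effect = effect, seed = seed, lag_s = lag_s),
              class = "v1_cohort")
  })
}

#' @export
print.v1_cohort <- function(x, ...) {
  cat(sprintf("Synthetic V1 cohort: %d subjects, %d vertices, %d runs (%s effect)\n",
              length(x$subjects), nrow(x$map), attr(x$schedule, "n_runs"),
              x$effect$preset))
  invisible(x)
}

# Boxcar (stimulation epochs of one condition, onsets rounded to the TR grid)
# convolved with the canonical HRF sampled at TR.
evoked_regressor <- function(schedule, run, condition, n_vol, TR, hrf = canonical_hrf(TR)) {
  box <- numeric(n_vol)
  blocks <- schedule[schedule$run == run & schedule$condition == condition, ]
  n_stim <- round(blocks$stim_duration_s[1] / TR)
  for (i in seq_len(nrow(blocks))) {
    on <- round(blocks$stim_onset_s[i] / TR)
    idx <- on + seq_len(n_stim)           # 1-based samples after onset
    idx <- idx[idx >= 1 & idx <= n_vol]
    box[idx] <- 1
  }
  convolve_hrf(box, hrf)
}

# Integer state per volume: 0 baseline, k = condition index while inside the
# lag-shifted stimulation window of condition k.
epoch_state <- function(schedule, run, TR, n_vol, lag_s) {
  st <- integer(n_vol)
  blocks <- schedule[schedule$run == run, ]
  n_stim <- round(blocks$stim_duration_s[1] / TR)
  for (i in seq_len(nrow(blocks))) {
    on <- round((blocks$stim_onset_s[i] + lag_s) / TR)
    idx <- on + seq_len(n_stim)
    idx <- idx[idx >= 1 & idx <= n_vol]
    st[idx] <- match(blocks$condition[i], V1_CONDITIONS)
  }
  st
}
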
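#' Build a block schedule for the Navon experiment
#'
#' Each run has 12 blocks of 44 s (1 s cue + 19 s baseline + 20 s letter
#' repetitions + 4 s report), three blocks per condition (EG, EL, UG, UL),
#' with the condition order randomized independently per run.
#'
#' @param n_runs 4 or 5 runs.
#' @param seed integer seed controlling the condition order.
#' @param TR repetition time in seconds (default 2.5).
#' @return A data.frame of class \code{"block_schedule"} with columns
#'   \code{run}, \code{block}, \code{condition}, \code{block_onset_s},
#'   \code{cue_onset_s}, \code{stim_onset_s}, \code{stim_duration_s},
#'   \code{report_onset_s}; attributes \code{TR}, \code{n_runs},
#'   \code{run_duration_s} and \code{n_volumes} (volumes per run, sized so the
#'   last block plus hemodynamic tail fits on the TR grid).
#' @examples
#' sch <- make_block_schedule(5, seed = 1)
#' table(sch$condition)
#' @export
make_block_schedule <- function(n_runs, seed = NULL, TR = 2.5) {
  if (!n_runs %in% c(4L, 5L)) stop("n_runs must be 4 or 5")
  block_s <- 44
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      conds <- sample(rep(V1_CONDITIONS, each = 3L))
      onset <- (seq_along(conds) - 1L) * block_s
      data.frame(run = r, block = seq_along(conds), condition = conds,
                 block_onset_s = onset,
                 cue_onset_s = onset,
                 stim_onset_s = onset + 1 + 19,
                 stim_duration_s = 20,
                 report_onset_s = onset + 40,
                 stringsAsFactors = FALSE)
    })
    sch <- do.call(rbind, runs)
    class(sch) <- c("block_schedule", "data.frame")
    attr(sch, "TR") <- TR
    attr(sch, "n_runs") <- n_runs
    attr(sch, "run_duration_s") <- 12 * block_s
    # 25 s tail so the final block's hemodynamic and FIR windows fit
    attr(sch, "n_volumes") <- ceiling(12 * block_s / TR) + 10L
    sch
  })
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("Block schedule: %d runs x 12 blocks of 44 s (TR = %g s, %d volumes/run)\n",
              attr(x, "n_runs"), attr(x, "TR"), attr(x, "n_volumes")))
  print(table(run = x$run, condition = x$condition))
  invisible(x)
}
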
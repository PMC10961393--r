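#' Specify the generative effect structure of a synthetic cohort
#'
#' Controls the three signal sources of the generator: a cohort-common evoked
#' response (amplitude per condition), subject-idiosyncratic evoked activity
#' (gain and spatial-pattern jitter), and background activity whose vertex
#' covariance can carry condition-dependent network structure during
#' stimulation epochs.
#'
#' Planted network structure is realized as correlation increments on disjoint
#' vertex pairs, which keeps the covariance positive definite for any
#' increment below 1: \code{"interhemispheric"} pairs the i-th left-hemisphere
#' vertex with the i-th right-hemisphere vertex, \code{"intrahemispheric"}
#' pairs consecutive vertices within each hemisphere, and any of the ten
#' quadrant sub-network labels (see [partition_subnetworks()]) pairs vertices
#' within/between the named quadrants.
#'
#' @param preset \code{"null"} (no condition effect anywhere: the negative
#'   control), or \code{"level_topology"} (interhemispheric pair correlations
#'   for the Global conditions, intra-hemispheric for Local: the positive
#'   control emulating the reported Level topology).
#' @param common_gain named amplitude per condition of the shared evoked
#'   response (recycled if scalar).
#' @param idio_sd between-subject SD of evoked gain and pattern jitter.
#' @param bg_sd background activity scale.
#' @param ar1 lag-1 autocorrelation of background activity.
#' @param planted_network named list, one entry per condition: a named numeric
#'   vector of correlation increments keyed by \code{"interhemispheric"},
#'   \code{"intrahemispheric"} or a sub-network label.
#' @return An object of class \code{"effect_spec"}.
#' @examples
#' effect_spec("null")
#' effect_spec("level_topology", idio_sd = 0.2)
#' @export
effect_spec <- function(preset = c("null", "level_topology"),
                        common_gain = NULL, idio_sd = NULL, bg_sd = NULL,
                        ar1 = 0.3, planted_network = NULL) {
  preset <- match.arg(preset)
  if (preset == "null") {
    def <- list(common_gain = stats::setNames(rep(0, 4), V1_CONDITIONS),
                idio_sd = 0, bg_sd = 1,
                planted_network = stats::setNames(
                  rep(list(numeric(0)), 4), V1_CONDITIONS))
  } else {
    def <- list(common_gain = stats::setNames(rep(1, 4), V1_CONDITIONS),
                idio_sd = 0.3, bg_sd = 1,
                planted_network = list(
                  EG = c(interhemispheric = 0.35),
                  EL = c(intrahemispheric = 0.35),
                  UG = c(interhemispheric = 0.35),
                  UL = c(intrahemispheric = 0.35)))
  }
  if (!is.null(common_gain)) {
    if (is.null(names(common_gain)))
      common_gain <- stats::setNames(rep_len(common_gain, 4), V1_CONDITIONS)
    def$common_gain[names(common_gain)] <- common_gain
  }
  if (!is.null(idio_sd)) def$idio_sd <- idio_sd
  if (!is.null(bg_sd)) def$bg_sd <- bg_sd
  if (!is.null(planted_network)) def$planted_network[names(planted_network)] <- planted_network
  stopifnot(def$idio_sd >= 0, def$bg_sd >= 0, abs(ar1) < 1)
  structure(c(def, list(ar1 = ar1, preset = preset)), class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat(sprintf("Effect spec ('%s'): common gain [%s], idio_sd = %g, bg_sd = %g, AR(1) = %g\n",
              x$preset, paste(sprintf("%s=%g", names(x$common_gain), x$common_gain),
                              collapse = ", "),
              x$idio_sd, x$bg_sd, x$ar1))
  for (cond in names(x$planted_network)) {
    pn <- x$planted_network[[cond]]
    if (length(pn))
      cat(sprintf("  planted %s: %s\n", cond,
                  paste(sprintf("%s +%g", names(pn), pn), collapse = ", ")))
  }
  invisible(x)
}

# Disjoint vertex pairs realizing a planted increment group for a given map.
# Returns a 2-column matrix of vertex index pairs.
planted_pairs <- function(map, group) {
  il <- which(map$hemisphere == "L")
  ir <- which(map$hemisphere == "R")
  if (group == "interhemispheric") {
    k <- min(length(il), length(ir))
    return(cbind(il[seq_len(k)], ir[seq_len(k)]))
  }
  if (group == "intrahemispheric") {
    pair_within <- function(idx) {
      k <- floor(length(idx) / 2)
      cbind(idx[2 * seq_len(k) - 1], idx[2 * seq_len(k)])
    }
    return(rbind(pair_within(il), pair_within(ir)))
  }
  qp <- subnetwork_quadrants(group)
  if (qp[1] == qp[2]) {
    idx <- which(map$quadrant == qp[1])
    k <- floor(length(idx) / 2)
    return(cbind(idx[2 * seq_len(k) - 1], idx[2 * seq_len(k)]))
  }
  ia <- which(map$quadrant == qp[1])
  ib <- which(map$quadrant == qp[2])
  k <- min(length(ia), length(ib))
  cbind(ia[seq_len(k)], ib[seq_len(k)])
}

# Per-condition background correlation matrix (V x V) from the planted spec.
planted_correlation <- function(map, effect, condition) {
  V <- nrow(map)
  R <- diag(V)
  pn <- effect$planted_network[[condition]]
  for (group in names(pn)) {
    pr <- planted_pairs(map, group)
    if (nrow(pr) == 0) next
    R[pr] <- R[pr] + pn[[group]]
    R[pr[, 2:1, drop = FALSE]] <- R[pr[, 2:1, drop = FALSE]] + pn[[group]]
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("planted covariance for condition %s is not positive semi-definite",
                 condition))
  ch
}
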
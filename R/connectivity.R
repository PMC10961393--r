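#' Row-major upper-triangle edge index
#'
#' The fixed edge ordering used by every feature vector and edge table in the
#' package: pairs (i, j) with i < j, ordered by i then j.
#'
#' @param V vertex count.
#' @return Two-column integer matrix (i, j) with V(V-1)/2 rows.
#' @export
edge_index <- function(V) {
  i <- rep.int(seq_len(V - 1L), times = (V - 1L):1L)
  j <- unlist(lapply(seq_len(V - 1L), function(k) (k + 1L):V), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Within-subject connectivity matrix
#'
#' Pearson correlation between all vertex pairs of a concatenated
#' per-condition series; symmetric with the diagonal zeroed. Zero-variance
#' vertices get zero rows/columns with a warning.
#'
#' @param series a [segment_concatenate()] result, or a time x vertex matrix.
#' @return Object of class \code{"connectivity_matrix"}: the correlation
#'   matrix with attributes \code{scheme} (if known) and \code{condition}.
#' @export
within_subject_matrix <- function(series) {
  x <- if (inherits(series, "condition_series")) series$data else as.matrix(series)
  if (nrow(x) < 3) stop("need at least 3 time points")
  sds <- apply(x, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    warning(sprintf("%d zero-variance vertices; setting their edges to 0",
                    length(bad)))
    x[, bad] <- seq_len(nrow(x))  # placeholder; rows/cols zeroed below
  }
  M <- stats::cor(x)
  if (length(bad)) { M[bad, ] <- 0; M[, bad] <- 0 }
  diag(M) <- 0
  structure(M, class = c("connectivity_matrix", class(M)),
            condition = if (inherits(series, "condition_series")) series$condition)
}

#' Common-response connectivity matrix
#'
#' Correlates one subject's per-condition series with the grand-average series
#' of all other subjects, in both directions, and averages the two to obtain a
#' symmetric matrix. This suppresses subject-idiosyncratic activity and
#' residual noise, isolating the stimulus-evoked response shared across the
#' cohort.
#'
#' @param series_i the held-out subject's [segment_concatenate()] result.
#' @param others list of the remaining subjects' series (same condition, same
#'   length and vertex order).
#' @return A \code{"connectivity_matrix"} (entries may exceed the usual
#'   within-subject values in magnitude only through averaging; still in
#'   [-1, 1]).
#' @export
common_response_matrix <- function(series_i, others) {
  if (length(others) < 1) stop("need at least 2 subjects")
  xi <- if (inherits(series_i, "condition_series")) series_i$data else as.matrix(series_i)
  mats <- lapply(others, function(s)
    if (inherits(s, "condition_series")) s$data else as.matrix(s))
  if (any(vapply(mats, function(m) !all(dim(m) == dim(xi)), TRUE)))
    stop("series length/vertex mismatch between subjects")
  G <- Reduce(`+`, mats) / length(mats)
  M1 <- suppressWarnings(stats::cor(xi, G))
  M1[!is.finite(M1)] <- 0
  M <- (M1 + t(M1)) / 2
  diag(M) <- 0
  structure(M, class = c("connectivity_matrix", "matrix", "array"),
            condition = if (inherits(series_i, "condition_series")) series_i$condition)
}

#' Vectorize a connectivity matrix into classifier features
#'
#' Takes the row-major upper triangle, applies the Fisher r-to-z transform
#' (atanh), and rectifies by setting negative values to zero (rectification in
#' z-space; the transform is sign-preserving, so this is equivalent to
#' rectifying in r-space). Correlations at |r| = 1 are clipped to
#' 1 - 1e-7 with a warning before the transform.
#'
#' @param matrix a \code{"connectivity_matrix"} (or symmetric matrix).
#' @return Numeric feature vector of length V(V-1)/2, all values >= 0, with
#'   attribute \code{edge_index}.
#' @export
to_features <- function(matrix) {
  M <- unclass(matrix)
  ei <- edge_index(ncol(M))
  r <- M[ei]
  if (any(abs(r) >= 1)) {
    warning("correlations at |r| = 1 clipped before Fisher z")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  z <- atanh(r)
  z[z < 0] <- 0
  attr(z, "edge_index") <- ei
  z
}

# Map a sub-network label to its unordered quadrant pair.
subnetwork_quadrants <- function(label) {
  tab <- list(ULq = c("UL", "UL"), URq = c("UR", "UR"),
              LoLeq = c("LL", "LL"), LoRq = c("LR", "LR"),
              LRup = c("UL", "UR"), LRlo = c("LL", "LR"),
              UDle = c("UL", "LL"), UDr = c("UR", "LR"),
              DiagP = c("UL", "LR"), DiagS = c("UR", "LL"))
  if (is.null(tab[[label]])) stop("unknown sub-network label: ", label)
  tab[[label]]
}

#' The ten quadrant-pair sub-network labels
#'
#' Within-quadrant: ULq, URq (upper left/right), LoLeq, LoRq (lower
#' left/right). Between-quadrant: LRup, LRlo (left-right horizontal, upper and
#' lower), UDle, UDr (up-down vertical, left and right), DiagP, DiagS
#' (principal and secondary diagonals).
#' @export
SUBNETWORK_LABELS <- c("ULq", "URq", "LoLeq", "LoRq", "LRup", "LRlo",
                       "UDle", "UDr", "DiagP", "DiagS")

#' Partition V1 edges into quadrant-pair sub-networks
#'
#' Labels every edge by the unordered pair of visual-field quadrants its two
#' endpoint vertices map: 4 within-quadrant plus 6 between-quadrant classes.
#'
#' @param map a [build_retinotopic_map()] result.
#' @return Factor of sub-network labels in edge-index order, with attribute
#'   \code{edge_index}.
#' @export
partition_subnetworks <- function(map) {
  q <- map$quadrant
  if (any(is.na(q) | !q %in% c("UL", "UR", "LL", "LR")))
    stop("every vertex must have a quadrant label")
  ei <- edge_index(nrow(map))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- stats::setNames(SUBNETWORK_LABELS,
                         vapply(SUBNETWORK_LABELS, function(l) {
                           qp <- subnetwork_quadrants(l)
                           key(qp[1], qp[2])
                         }, ""))
  lab <- lut[key(q[ei[, 1]], q[ei[, 2]])]
  out <- factor(lab, levels = SUBNETWORK_LABELS)
  attr(out, "edge_index") <- ei
  out
}

#' Per-subject feature table for a contrast
#'
#' Runs the full preprocessing + connectivity + vectorization pipeline for
#' every subject of a cohort under one scheme, returning one feature row per
#' subject x condition. For the CR scheme, each subject's matrix correlates
#' their raw-scheme series with the grand average of all other subjects'
#' series of the same condition.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param scheme "raw", "HRFc", "FIR" or "CR".
#' @param conditions conditions to include (default all four).
#' @param lag_s hemodynamic lag (s).
#' @return List with \code{x} (features, rows = subject x condition),
#'   \code{condition}, \code{subject} vectors.
#' @export
cohort_features <- function(cohort, scheme = c("raw", "HRFc", "FIR", "CR"),
                            conditions = V1_CONDITIONS, lag_s = cohort$lag_s) {
  scheme <- match.arg(scheme)
  base_scheme <- if (scheme == "CR") "raw" else scheme
  n <- length(cohort$subjects)
  rows <- list(); cond_v <- character(0); subj_v <- integer(0)
  for (cond in conditions) {
    series <- lapply(cohort$subjects, condition_series,
                     schedule = cohort$schedule, condition = cond,
                     scheme = base_scheme, lag_s = lag_s)
    for (s in seq_len(n)) {
      M <- if (scheme == "CR")
        common_response_matrix(series[[s]], series[-s])
      else within_subject_matrix(series[[s]])
      rows[[length(rows) + 1L]] <- to_features(M)
      cond_v <- c(cond_v, cond)
      subj_v <- c(subj_v, s)
    }
  }
  list(x = do.call(rbind, rows), condition = cond_v, subject = subj_v,
       scheme = scheme)
}
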
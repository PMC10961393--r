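#' Haufe forward-model transformation of classifier weights
#'
#' Converts the backward-model SVM weights into a forward-model activation
#' pattern by multiplying with the sample covariance of the retained training
#' features, a = cov(X_retained) w (the single-discriminant case; the scalar
#' latent variance is irrelevant to rankings and percentile selection). The
#' activation is mapped back onto the full edge index, zero outside the
#' retained set, and its sign is fixed so that positive values support the
#' model's \code{positive_class}.
#'
#' @param model a [train_svm()] fit.
#' @param x_train the training sample x feature matrix the model was fit on
#'   (full feature space).
#' @return Numeric activation vector over all edges (class
#'   \code{"weight_map"}), with attribute \code{positive_class}.
#' @export
haufe_transform <- function(model, x_train) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2) stop("covariance undefined with fewer than 2 samples")
  xr <- x_train[, model$retained, drop = FALSE]
  xc <- sweep(xr, 2, colMeans(xr))
  # cov(X) %*% w without forming the k x k covariance: Xc'(Xc w) / (n - 1)
  a <- drop(crossprod(xc, xc %*% model$w)) / (nrow(xr) - 1)
  out <- numeric(ncol(x_train))
  out[model$retained] <- a
  structure(out, positive_class = model$positive_class, class = "weight_map")
}

# Flip a weight map so that positive activations support `want_positive`.
orient_map <- function(map, want_positive) {
  if (!identical(attr(map, "positive_class"), want_positive)) {
    map <- structure(-unclass(map), positive_class = want_positive,
                     class = "weight_map")
  }
  map
}

#' Bootstrap transformed weight maps for the two cross-classification directions
#'
#' Resamples participants with replacement; in each replicate the two
#' direction-specific Level classifiers (one trained on the E pair, one on the
#' U pair) are re-selected, re-trained and Haufe-transformed on the resampled
#' data. Replicates that draw a single unique subject are redrawn (logged as a
#' message). Maps are oriented so positive activation supports
#' \code{positive_level} (default "Local", matching the convention that
#' positive weights support Local and negative support Global).
#'
#' @param x_e,y_e E-pair samples (2 rows per subject) and Level labels.
#' @param x_u,y_u U-pair samples and Level labels.
#' @param subject subject id per row (same ordering in both pairs).
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param alpha feature-selection threshold.
#' @param positive_level label whose support is coded positive.
#' @return Object of class \code{"weight_map_boot"}: \code{maps_e},
#'   \code{maps_u} (n_boot x n_edges matrices), \code{full_e}, \code{full_u}
#'   (full-sample maps), \code{positive_level}.
#' @export
bootstrap_weight_maps <- function(x_e, y_e, x_u, y_u, subject, n_boot = 1000,
                                  seed = NULL, alpha = 0.01,
                                  positive_level = "Local") {
  stopifnot(n_boot >= 2)
  x_e <- as.matrix(x_e); x_u <- as.matrix(x_u)
  subjects <- unique(subject)
  rows_of <- lapply(subjects, function(s) which(subject == s))
  fit_maps <- function(idx_rows) {
    xe <- x_e[idx_rows, , drop = FALSE]; ye <- y_e[idx_rows]
    xu <- x_u[idx_rows, , drop = FALSE]; yu <- y_u[idx_rows]
    me <- train_svm(xe, ye, suppressWarnings(ttest_select(xe, ye, alpha)))
    mu <- train_svm(xu, yu, suppressWarnings(ttest_select(xu, yu, alpha)))
    list(e = orient_map(haufe_transform(me, xe), positive_level),
         u = orient_map(haufe_transform(mu, xu), positive_level))
  }
  full <- fit_maps(seq_len(nrow(x_e)))
  with_seed(seed, {
    maps_e <- matrix(0, n_boot, ncol(x_e))
    maps_u <- matrix(0, n_boot, ncol(x_u))
    for (b in seq_len(n_boot)) {
      repeat {
        take <- sample(length(subjects), replace = TRUE)
        if (length(unique(take)) > 1) break
        message("bootstrap replicate with a single unique subject; redrawn")
      }
      idx <- unlist(rows_of[take], use.names = FALSE)
      m <- fit_maps(idx)
      maps_e[b, ] <- m$e
      maps_u[b, ] <- m$u
    }
    structure(list(maps_e = maps_e, maps_u = maps_u,
                   full_e = full$e, full_u = full$u,
                   positive_level = positive_level, n_boot = n_boot),
              class = "weight_map_boot")
  })
}

#' Kendall's coefficient of concordance W
#'
#' W = 12 S / (m^2 (n^3 - n) - m T) where S is the sum of squared deviations
#' of the rank sums over n items ranked by m raters, with midranks for ties
#' and the usual tie correction T. Ranges from 0 (for m = 2, exactly reversed
#' rankings) to 1 (identical rankings); for two independent random rankings
#' the expected value is 0.5.
#'
#' @param rank_lists matrix with one row per rater (list of m >= 2 score or
#'   rank vectors also accepted); values are ranked internally.
#' @return W in [0, 1].
#' @examples
#' kendalls_w(rbind(1:5, 1:5))    # 1
#' kendalls_w(rbind(1:5, 5:1))    # 0
#' @export
kendalls_w <- function(rank_lists) {
  if (is.list(rank_lists)) rank_lists <- do.call(rbind, rank_lists)
  m <- nrow(rank_lists); n <- ncol(rank_lists)
  if (m < 2 || n < 2) stop("need m >= 2 raters and n >= 2 items")
  R <- t(apply(rank_lists, 1, rank))
  if (any(apply(R, 1, function(r) length(unique(r))) == 1))
    stop("all-tied ranking: W undefined")
  S <- sum((colSums(R) - m * (n + 1) / 2)^2)
  Tcorr <- sum(apply(R, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  W <- 12 * S / (m^2 * (n^3 - n) - m * Tcorr)
  min(max(W, 0), 1)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Standard BCa interval: the bias correction z0 comes from the fraction of
#' replicates below the original statistic, the acceleration a from the
#' jackknife skewness when jackknife values are supplied (a = 0 otherwise,
#' the bias-corrected percentile interval). With z0 = 0 and a = 0 the
#' interval reduces exactly to the plain percentile interval.
#'
#' @param bootstrap_stats numeric vector of replicate statistics (>= 100 for a
#'   stable interval; fewer allowed with a warning).
#' @param original_stat the statistic on the original data.
#' @param level confidence level (default 0.95).
#' @param jackknife optional vector of leave-one-out statistics for the
#'   acceleration term.
#' @return c(lo, hi). Degenerate replicate distributions give a point interval.
#' @export
bca_ci <- function(bootstrap_stats, original_stat, level = 0.95,
                   jackknife = NULL) {
  b <- bootstrap_stats[is.finite(bootstrap_stats)]
  if (length(b) < 100) warning("fewer than 100 bootstrap replicates")
  if (length(unique(b)) == 1) return(c(lo = b[1], hi = b[1]))
  prop <- (sum(b < original_stat) + 0.5 * sum(b == original_stat)) / length(b)
  prop <- min(max(prop, 1 / (2 * length(b))), 1 - 1 / (2 * length(b)))
  z0 <- stats::qnorm(prop)
  a <- 0
  if (!is.null(jackknife)) {
    d <- mean(jackknife) - jackknife
    denom <- 6 * sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / denom
  }
  zs <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zs) / (1 - a * (z0 + zs)))
  out <- stats::quantile(b, adj, names = FALSE, type = 7)
  c(lo = out[1], hi = out[2])
}

#' Summarize bootstrapped weight maps
#'
#' Averages the two direction maps within each replicate, takes the per-edge
#' median across replicates as the robust weight-map summary, and marks the
#' upper and lower 2.5% of the nonzero-median edges as significant (upper tail
#' supports the positive-coded level, lower tail the other). Also computes the
#' per-replicate Kendall's W concordance between the two direction maps,
#' ranked over the union of edges retained in either direction, with a 95%
#' BCa interval.
#'
#' @param boot a [bootstrap_weight_maps()] result.
#' @param tail_fraction fraction of nonzero edges in each significant tail
#'   (default 0.025); counts use the ceiling, ties broken by edge index.
#' @param level confidence level for the W interval.
#' @return Object of class \code{"weight_map_summary"}: \code{median_map},
#'   \code{significant_edges} (list \code{positive}, \code{negative}),
#'   \code{kendall_w_samples}, \code{w_median}, \code{w_ci},
#'   \code{positive_level}.
#' @export
summarize_maps <- function(boot, tail_fraction = 0.025, level = 0.95) {
  stopifnot(inherits(boot, "weight_map_boot"))
  avg <- (boot$maps_e + boot$maps_u) / 2
  med <- apply(avg, 2, stats::median)
  nz <- which(med != 0)
  k <- ceiling(tail_fraction * length(nz))
  ord <- nz[order(med[nz], nz)]         # ascending, ties by edge index
  negative <- sort(ord[seq_len(k)])     # most negative: supports the other level
  positive <- sort(ord[seq(length(ord), length.out = k, by = -1)])
  w_samples <- vapply(seq_len(boot$n_boot), function(b) {
    union_idx <- which(boot$maps_e[b, ] != 0 | boot$maps_u[b, ] != 0)
    if (length(union_idx) < 2) return(NA_real_)
    kendalls_w(rbind(boot$maps_e[b, union_idx], boot$maps_u[b, union_idx]))
  }, 0)
  w_obs <- stats::median(w_samples, na.rm = TRUE)
  ci <- bca_ci(w_samples[is.finite(w_samples)], w_obs, level)
  structure(list(median_map = med,
                 significant_edges = list(positive = positive, negative = negative),
                 kendall_w_samples = w_samples, w_median = w_obs, w_ci = ci,
                 positive_level = boot$positive_level,
                 n_nonzero = length(nz), tail_fraction = tail_fraction),
            class = "weight_map_summary")
}

#' @export
print.weight_map_summary <- function(x, ...) {
  cat(sprintf("Weight-map summary: %d nonzero-median edges, %d per 2.5%% tail\n",
              x$n_nonzero, length(x$significant_edges$positive)))
  cat(sprintf("  Kendall's W median %.3f (95%% BCa %.3f..%.3f); positive = %s\n",
              x$w_median, x$w_ci[1], x$w_ci[2], x$positive_level))
  invisible(x)
}

#' Count significant edges per sub-network
#'
#' Tabulates the positive-supporting (e.g. Local) and negative-supporting
#' (Global) significant edges of a weight-map summary over the ten
#' quadrant-pair sub-networks.
#'
#' @param summary a [summarize_maps()] result.
#' @param partition a [partition_subnetworks()] factor on the same edge index.
#' @return 2 x 10 integer matrix (rows: the level supported by positive /
#'   negative weights; columns: sub-network labels).
#' @export
subnetwork_counts <- function(summary, partition) {
  sig <- summary$significant_edges
  all_idx <- c(sig$positive, sig$negative)
  if (any(is.na(partition[all_idx])))
    stop("significant edge without a sub-network label")
  counts <- rbind(
    positive = table(partition[sig$positive]),
    negative = table(partition[sig$negative]))
  rownames(counts) <- c(summary$positive_level,
                        paste0("not_", summary$positive_level))
  counts
}

#' Heterogeneity of sub-network count distributions
#'
#' Chi-square test of homogeneity of the 10-category sub-network distribution
#' across several count tables (e.g. the 6 scheme x level margins of the
#' 3 x 2 x 10 contingency table), with a Monte-Carlo p-value when any
#' expected count is below 5. This is a documented substitute for loglinear
#' heterogeneity modeling; its p-values are not claimed to match any
#' particular printout.
#'
#' @param tables a list of count vectors (same length) or a matrix with one
#'   row per table.
#' @param B Monte-Carlo replicates when expected counts are small.
#' @param seed integer seed for the Monte-Carlo p.
#' @return list(statistic, p_value, method).
#' @export
heterogeneity_test <- function(tables, B = 2000, seed = NULL) {
  if (is.list(tables)) tables <- do.call(rbind, tables)
  if (is.null(dim(tables)) || nrow(tables) < 2)
    stop("need at least 2 tables of matching dimension")
  if (any(rowSums(tables) == 0)) stop("zero-total table")
  keep <- colSums(tables) > 0
  tab <- tables[, keep, drop = FALSE]
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  mc <- any(exp_counts < 5)
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(tab, simulate.p.value = mc, B = B)))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (mc) "chi-square homogeneity (Monte-Carlo p)"
       else "chi-square homogeneity")
}
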
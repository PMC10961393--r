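#' Two-sample t-test feature selection
#'
#' Per-feature two-tailed two-sample t-test between the two classes of the
#' training data; features with p below \code{alpha} are retained. Equal
#' variances are pooled by default (Student); \code{welch = TRUE} switches to
#' the Welch statistic. Features that are constant across all samples have an
#' undefined t and are excluded (p = 1). If no feature survives, the single
#' smallest-p feature is kept with a warning.
#'
#' @param x sample x feature training matrix.
#' @param y class labels (2 classes, each with >= 2 samples).
#' @param alpha retention threshold on p (default 0.01).
#' @param welch use the Welch unequal-variance statistic.
#' @return Integer vector of retained column indices (attribute \code{p}:
#'   all feature p-values).
#' @export
ttest_select <- function(x, y, alpha = 0.01, welch = FALSE) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("need exactly 2 classes")
  i1 <- which(y == levels(y)[1]); i2 <- which(y == levels(y)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples")
  x <- as.matrix(x)
  m1 <- colMeans(x[i1, , drop = FALSE]); m2 <- colMeans(x[i2, , drop = FALSE])
  v1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x[i2, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  d <- m1 - m2
  p <- rep(1, ncol(x))
  pos <- se2 > 0
  p[pos] <- 2 * stats::pt(-abs(d[pos]) / sqrt(se2[pos]), df = if (welch) df[pos] else df)
  p[!pos & d != 0] <- 0       # zero variance but separated means: t infinite
  keep <- which(p < alpha)
  if (length(keep) == 0) {
    warning("no feature below alpha; keeping the single smallest-p feature")
    keep <- which.min(p)
  }
  attr(keep, "p") <- p
  keep
}

#' Train a linear soft-margin SVM on retained features
#'
#' Linear-kernel support vector machine with box constraint C = 1 (libsvm via
#' e1071), no feature standardization. The problem is convex, so the fit is
#' deterministic given the data.
#'
#' @param x sample x feature matrix (full feature space).
#' @param y 2-class labels.
#' @param retained_edges column indices to train on.
#' @param C box constraint (default 1).
#' @return Object of class \code{"svm_edge_model"}: \code{w} (weights per
#'   retained column), \code{b} (bias), \code{retained}, \code{classes},
#'   \code{positive_class} (the class predicted when w.x + b > 0), and the
#'   underlying e1071 fit.
#' @export
train_svm <- function(x, y, retained_edges, C = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (min(table(y)) < 1) stop("degenerate single-class training set")
  if (any(table(y) < 1)) stop("each class needs at least one sample")
  xr <- as.matrix(x)[, retained_edges, drop = FALSE]
  fit <- e1071::svm(xr, y, kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # identify which class sits on the positive side of the decision function
  dv <- drop(xr %*% w) + b
  pred <- fit$fitted
  pos_tab <- table(pred[dv > 0])
  positive_class <- if (any(dv > 0)) names(which.max(pos_tab)) else fit$levels[1]
  structure(list(w = w, b = b, retained = retained_edges,
                 classes = levels(y), positive_class = positive_class,
                 C = C, fit = fit),
            class = "svm_edge_model")
}

#' @export
predict.svm_edge_model <- function(object, newdata, ...) {
  xr <- as.matrix(newdata)[, object$retained, drop = FALSE]
  stats::predict(object$fit, xr)
}

# Fit-and-test primitive shared by LOSO folds and cross-classification
# directions: select features and train on (xtr, ytr), test on (xte, yte).
select_train_test <- function(xtr, ytr, xte, yte, alpha, C = 1, welch = FALSE) {
  sel <- suppressWarnings(ttest_select(xtr, ytr, alpha, welch))
  model <- train_svm(xtr, ytr, sel, C)
  pred <- predict(model, xte)
  list(accuracy = mean(pred == yte), model = model, retained = sel)
}

#' Leave-one-subject-out classification
#'
#' Inter-subject "specific" classification: for every held-out subject, t-test
#' feature selection and SVM training use only the remaining subjects'
#' samples; the two held-out samples are then predicted. With 26 subjects and
#' one sample per subject per condition this is 50 training and 2 testing
#' samples per fold. Feature selection is refit inside every training fold and
#' never sees test rows.
#'
#' @param x sample x feature matrix (one row per subject per condition).
#' @param y 2-class condition labels.
#' @param subject subject identifier per row.
#' @param alpha feature-selection threshold.
#' @param C SVM box constraint.
#' @return Object of class \code{"loso_result"}: \code{accuracy} (mean over
#'   folds), \code{fold_accuracies}, \code{folds} (per-fold train/test row
#'   indices and retained features), and the inputs (for permutation testing).
#' @export
loso_classify <- function(x, y, subject, alpha = 0.01, C = 1) {
  y <- droplevels(as.factor(y))
  subjects <- unique(subject)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  x <- as.matrix(x)
  folds <- lapply(subjects, function(s) {
    te <- which(subject == s); tr <- which(subject != s)
    if (length(unique(y[te])) < nlevels(y))
      stop("missing condition for subject ", s)
    r <- select_train_test(x[tr, , drop = FALSE], y[tr],
                           x[te, , drop = FALSE], y[te], alpha, C)
    list(train_idx = tr, test_idx = te, accuracy = r$accuracy,
         retained = r$retained)
  })
  fold_acc <- vapply(folds, `[[`, 0, "accuracy")
  structure(list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
                 folds = folds, x = x, y = y, subject = subject,
                 alpha = alpha, C = C),
            class = "loso_result")
}

#' Two-direction cross-classification
#'
#' Trains on one condition pair and tests on the other (no cross-validation
#' needed since training and test sets are independent), in both directions,
#' and averages the two accuracies. For abstract Level the pairs are (EG, EL)
#' and (UG, UL); labels must encode the attribute being decoded (e.g. Global /
#' Local) so they carry across pairs.
#'
#' @param x_a,y_a training-pair samples and labels (e.g. the E pair).
#' @param x_b,y_b the other pair (e.g. the U pair).
#' @param subject optional subject id per row (same subjects in both pairs).
#' @param alpha feature-selection threshold.
#' @param C SVM box constraint.
#' @return Object of class \code{"cross_result"}: \code{accuracy} (average),
#'   \code{direction_accuracies} (A->B, B->A), \code{models}, \code{retained},
#'   and the inputs.
#' @export
cross_classify <- function(x_a, y_a, x_b, y_b, subject = NULL, alpha = 0.01,
                           C = 1) {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  if (!is.null(subject) && nrow(x_a) != nrow(x_b))
    stop("subject mismatch between pairs")
  lv <- sort(unique(c(as.character(y_a), as.character(y_b))))
  y_a <- factor(as.character(y_a), levels = lv)
  y_b <- factor(as.character(y_b), levels = lv)
  d1 <- select_train_test(x_a, y_a, x_b, y_b, alpha, C)
  d2 <- select_train_test(x_b, y_b, x_a, y_a, alpha, C)
  structure(list(
    accuracy = (d1$accuracy + d2$accuracy) / 2,
    direction_accuracies = c(AtoB = d1$accuracy, BtoA = d2$accuracy),
    models = list(AtoB = d1$model, BtoA = d2$model),
    retained = list(AtoB = d1$retained, BtoA = d2$retained),
    x_a = x_a, y_a = y_a, x_b = x_b, y_b = y_b,
    subject = subject, alpha = alpha, C = C),
    class = "cross_result")
}

#' Permutation test of classification accuracy
#'
#' Builds the null distribution of accuracy by shuffling training labels and
#' re-running the full selection + training + testing procedure. For LOSO
#' results, labels are shuffled within each fold's training set; for
#' cross-classification, only the training labels are shuffled, independently
#' in both directions, and the two accuracies are averaged as in the observed
#' statistic. The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param result a \code{"loso_result"} or \code{"cross_result"}.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return The result object augmented with \code{null_accuracies},
#'   \code{p_value} and \code{n_permutations}.
#' @export
permutation_test <- function(result, n_perm = 1000, seed = NULL) {
  UseMethod("permutation_test")
}

#' @export
permutation_test.cross_result <- function(result, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  with_seed(seed, {
    null_acc <- vapply(seq_len(n_perm), function(i) {
      ya_p <- sample(result$y_a)
      yb_p <- sample(result$y_b)
      a1 <- select_train_test(result$x_a, ya_p, result$x_b, result$y_b,
                              result$alpha, result$C)$accuracy
      a2 <- select_train_test(result$x_b, yb_p, result$x_a, result$y_a,
                              result$alpha, result$C)$accuracy
      (a1 + a2) / 2
    }, 0)
    result$null_accuracies <- null_acc
    result$p_value <- (1 + sum(null_acc >= result$accuracy)) / (1 + n_perm)
    result$n_permutations <- n_perm
    result
  })
}

#' @export
permutation_test.loso_result <- function(result, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  with_seed(seed, {
    null_acc <- vapply(seq_len(n_perm), function(i) {
      fold_acc <- vapply(result$folds, function(f) {
        ytr <- sample(result$y[f$train_idx])
        select_train_test(result$x[f$train_idx, , drop = FALSE], ytr,
                          result$x[f$test_idx, , drop = FALSE],
                          result$y[f$test_idx],
                          result$alpha, result$C)$accuracy
      }, 0)
      mean(fold_acc)
    }, 0)
    result$null_accuracies <- null_acc
    result$p_value <- (1 + sum(null_acc >= result$accuracy)) / (1 + n_perm)
    result$n_permutations <- n_perm
    result
  })
}

#' Fisher combination of p-values
#'
#' Combines k independent p-values with Fisher's method: X = -2 sum(log p) is
#' referred to the upper tail of a chi-square with 2k degrees of freedom.
#' Exact zeros are clipped to 1/(n_perm + 1) with a warning (the smallest
#' p a permutation test of that size can produce).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param n_perm permutation count used for the zero clip (default 1000).
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # about 0.0175
#' @export
fisher_combine <- function(p_values, n_perm = 1000) {
  stopifnot(length(p_values) >= 1, all(p_values >= 0), all(p_values <= 1))
  if (any(p_values == 0)) {
    warning("p = 0 clipped to 1/(n_perm + 1)")
    p_values[p_values == 0] <- 1 / (n_perm + 1)
  }
  X <- -2 * sum(log(p_values))
  stats::pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("LOSO classification: accuracy %.3f over %d folds\n",
              x$accuracy, length(x$fold_accuracies)))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations, null mean %.3f)\n",
                x$p_value, x$n_permutations, mean(x$null_accuracies)))
  invisible(x)
}

#' @export
print.cross_result <- function(x, ...) {
  cat(sprintf("Cross-classification: accuracy %.3f (A->B %.3f, B->A %.3f)\n",
              x$accuracy, x$direction_accuracies[1], x$direction_accuracies[2]))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations, null mean %.3f)\n",
                x$p_value, x$n_permutations, mean(x$null_accuracies)))
  invisible(x)
}
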
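#' Level and Letter attributes of a condition code
#'
#' Condition codes combine letter identity (E/U) and level (G/L):
#' EG, EL, UG, UL.
#'
#' @param condition character vector of condition codes.
#' @return Character vector of attribute values.
#' @export
cond_level <- function(condition) {
  c(G = "Global", L = "Local")[substr(condition, 2, 2)]
}

#' @rdname cond_level
#' @export
cond_letter <- function(condition) substr(condition, 1, 1)

#' Abstract cross-classification from a cohort feature table
#'
#' Builds the two condition pairs for the requested attribute (Level: train
#' on the E pair EG/EL, test on the U pair UG/UL, and vice versa; Letter:
#' the G pair EG/UG against the L pair EL/UL), labels samples by the
#' attribute, and runs the two-direction cross-classification, optionally
#' with a permutation test.
#'
#' @param feats a [cohort_features()] result over all four conditions.
#' @param attribute "Level" or "Letter".
#' @param alpha feature-selection threshold.
#' @param n_perm permutations (0 to skip).
#' @param seed seed for the permutation test.
#' @return A [cross_classify()] result (pair A = E pair for Level, G pair for
#'   Letter).
#' @export
abstract_cross <- function(feats, attribute = c("Level", "Letter"),
                           alpha = 0.01, n_perm = 0, seed = NULL) {
  attribute <- match.arg(attribute)
  if (attribute == "Level") {
    ia <- feats$condition %in% c("EG", "EL")
    ib <- feats$condition %in% c("UG", "UL")
    lab <- cond_level(feats$condition)
  } else {
    ia <- feats$condition %in% c("EG", "UG")
    ib <- feats$condition %in% c("EL", "UL")
    lab <- cond_letter(feats$condition)
  }
  res <- cross_classify(feats$x[ia, , drop = FALSE], lab[ia],
                        feats$x[ib, , drop = FALSE], lab[ib],
                        subject = feats$subject[ia], alpha = alpha)
  if (n_perm > 0) res <- permutation_test(res, n_perm, seed)
  res
}

#' Specific LOSO classification from a cohort feature table
#'
#' Inter-subject classification of one condition pair (e.g. EG vs EL, the
#' "Level for letter E" discrimination) under leave-one-subject-out
#' cross-validation.
#'
#' @param feats a [cohort_features()] result.
#' @param pair two condition codes.
#' @param alpha feature-selection threshold.
#' @param n_perm permutations (0 to skip).
#' @param seed permutation seed.
#' @return A [loso_classify()] result.
#' @export
specific_loso <- function(feats, pair, alpha = 0.01, n_perm = 0, seed = NULL) {
  sel <- feats$condition %in% pair
  res <- loso_classify(feats$x[sel, , drop = FALSE], feats$condition[sel],
                       feats$subject[sel], alpha = alpha)
  if (n_perm > 0) res <- permutation_test(res, n_perm, seed)
  res
}

#' Abstract-Level weight-map analysis from a cohort feature table
#'
#' Bootstraps the two direction-specific Level classifiers (E pair and U
#' pair), Haufe-transforms each replicate, and summarizes: median map,
#' significant 2.5% tails, Kendall's W concordance with BCa interval.
#'
#' @param feats a [cohort_features()] result over all four conditions.
#' @param n_boot bootstrap replicates.
#' @param seed seed.
#' @param alpha feature-selection threshold.
#' @return A [summarize_maps()] result.
#' @export
level_weight_analysis <- function(feats, n_boot = 1000, seed = NULL,
                                  alpha = 0.01) {
  ie <- feats$condition %in% c("EG", "EL")
  iu <- feats$condition %in% c("UG", "UL")
  ord_e <- order(feats$subject[ie], feats$condition[ie])
  ord_u <- order(feats$subject[iu], feats$condition[iu])
  xe <- feats$x[ie, , drop = FALSE][ord_e, , drop = FALSE]
  xu <- feats$x[iu, , drop = FALSE][ord_u, , drop = FALSE]
  ye <- cond_level(feats$condition[ie][ord_e])
  yu <- cond_level(feats$condition[iu][ord_u])
  subj <- feats$subject[ie][ord_e]
  boot <- bootstrap_weight_maps(xe, ye, xu, yu, subj, n_boot = n_boot,
                                seed = seed, alpha = alpha)
  summarize_maps(boot)
}

#' Inter-subject (LOSO) variant of the abstract cross-classification
#'
#' Checks the stability of the abstract transfer across subjects: for each
#' held-out subject, features are selected and the SVM trained on one
#' condition pair of the remaining subjects, then tested on the *other* pair
#' of the held-out subject; both directions are run and averaged. The exact
#' fold structure of this hybrid is an interpretation (train on pair A of
#' n-1 subjects, test on pair B of the left-out subject).
#'
#' @inheritParams abstract_cross
#' @return list with \code{accuracy}, \code{direction_accuracies} and
#'   per-fold accuracies for both directions.
#' @export
abstract_cross_loso <- function(feats, attribute = c("Level", "Letter"),
                                alpha = 0.01) {
  attribute <- match.arg(attribute)
  if (attribute == "Level") {
    ia <- feats$condition %in% c("EG", "EL")
    ib <- feats$condition %in% c("UG", "UL")
    lab <- cond_level(feats$condition)
  } else {
    ia <- feats$condition %in% c("EG", "UG")
    ib <- feats$condition %in% c("EL", "UL")
    lab <- cond_letter(feats$condition)
  }
  subjects <- unique(feats$subject)
  one_dir <- function(itr, ite) {
    vapply(subjects, function(s) {
      tr <- which(itr & feats$subject != s)
      te <- which(ite & feats$subject == s)
      sel <- suppressWarnings(ttest_select(feats$x[tr, , drop = FALSE],
                                           lab[tr], alpha))
      m <- train_svm(feats$x[tr, , drop = FALSE], lab[tr], sel)
      mean(predict(m, feats$x[te, , drop = FALSE]) == lab[te])
    }, 0)
  }
  f1 <- one_dir(ia, ib)
  f2 <- one_dir(ib, ia)
  list(accuracy = mean(c(f1, f2)),
       direction_accuracies = c(AtoB = mean(f1), BtoA = mean(f2)),
       fold_accuracies = list(AtoB = f1, BtoA = f2))
}
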
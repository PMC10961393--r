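test_that("t-test selection retains separated features and drops constants", {
  set.seed(71)
  n <- 25
  x <- matrix(rnorm(2 * n * 5), 2 * n)
  y <- rep(c("a", "b"), each = n)
  x[, 4] <- 0                                   # constant everywhere
  x[y == "b", 2] <- x[y == "b", 2] + 10         # 10 sigma class gap
  sel <- ttest_select(x, y, alpha = 0.01)
  expect_true(2 %in% sel)
  expect_false(4 %in% sel)
  p <- attr(sel, "p")
  expect_identical(p[4], 1)                     # undefined t -> excluded
  # independent check of the planted feature's p through the t CDF
  a <- x[y == "a", 2]; b <- x[y == "b", 2]
  sp <- sqrt(((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2))
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(2 / n))
  expect_equal(p[2], 2 * pt(-abs(tstat), 2 * n - 2), tolerance = 1e-12)
  expect_lt(p[2], 1e-10)
  # alpha = 1 keeps every feature with a finite t
  expect_setequal(ttest_select(x, y, alpha = 1), c(1, 2, 3, 5))
  expect_warning(ttest_select(x[, 4, drop = FALSE], y), "smallest-p")
  expect_error(ttest_select(x[c(1, n + 1), ], y[c(1, n + 1)]), "2 samples")
})

test_that("linear SVM training is deterministic, symmetric and separates toy data", {
  x <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
  y <- c("neg", "neg", "pos", "pos")
  m <- train_svm(x, y, retained_edges = 1:2)
  expect_equal(as.character(predict(m, x)), y)
  # duplicating every sample leaves the decision function unchanged
  m2 <- train_svm(x[rep(1:4, 2), ], y[rep(1:4, 2)], 1:2)
  probe <- cbind(runif(20, -1, 4), runif(20, -1, 2))
  expect_equal(as.character(predict(m, probe)), as.character(predict(m2, probe)))
  # label swap is prediction-equivalent
  y_swap <- ifelse(y == "neg", "pos", "neg")
  m3 <- train_svm(x, y_swap, 1:2)
  expect_equal(as.character(predict(m3, probe)),
               ifelse(predict(m, probe) == "neg", "pos", "neg"))
  # the weight vector points along the separating direction
  expect_gt(abs(m$w[1]), 10 * abs(m$w[2]))
})

test_that("LOSO classification uses 2(n-1) training and 2 test samples per fold", {
  sf <- separable_features(n_subj = 26)
  res <- loso_classify(sf$x, sf$y, sf$subject)
  expect_length(res$fold_accuracies, 26)
  for (f in res$folds) {
    expect_length(f$train_idx, 50)
    expect_length(f$test_idx, 2)
    # feature selection and training never see test rows
    expect_length(intersect(f$train_idx, f$test_idx), 0)
  }
  expect_equal(res$accuracy, mean(res$fold_accuracies))
  expect_equal(res$accuracy, 1)                # planted separable edge
  expect_error(loso_classify(sf$x[1:4, ], sf$y[1:4], sf$subject[1:4]),
               "3 subjects")
})

test_that("LOSO accuracy on label-free features stays in the binomial chance band", {
  accs <- vapply(1:12, function(s) {
    set.seed(800 + s)
    n_subj <- 12
    x <- matrix(abs(rnorm(2 * n_subj * 40, sd = 0.3)), 2 * n_subj)
    y <- rep(c("a", "b"), n_subj)
    loso_classify(x, y, rep(1:n_subj, each = 2))$accuracy
  }, 0)
  n_trials <- 12 * 24
  band <- qbinom(c(0.025, 0.975), n_trials, 0.5) / n_trials
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("cross-classification trains on one pair, tests on the other, both ways", {
  set.seed(73)
  n_subj <- 26
  mk <- function(gap) {
    x <- matrix(abs(rnorm(2 * n_subj * 20, sd = 0.3)), 2 * n_subj)
    y <- rep(c("Global", "Local"), n_subj)
    x[y == "Local", 5] <- x[y == "Local", 5] + gap
    list(x = x, y = y)
  }
  A <- mk(3); B <- mk(3)
  res <- cross_classify(A$x, A$y, B$x, B$y, subject = rep(1:n_subj, each = 2))
  expect_equal(nrow(res$x_a), 52)              # 52 observations per pair
  expect_equal(res$accuracy, 1)
  expect_equal(unname(res$direction_accuracies), c(1, 1))
  # an exact copy of the training pair as test pair is perfectly classified
  res2 <- cross_classify(A$x, A$y, A$x, A$y)
  expect_equal(res2$accuracy, 1)
  # deterministic given fixed inputs
  res3 <- cross_classify(A$x, A$y, B$x, B$y, subject = rep(1:n_subj, each = 2))
  expect_identical(res$accuracy, res3$accuracy)
  expect_identical(res$models$AtoB$w, res3$models$AtoB$w)
})

test_that("permutation tests use the add-one estimator and center on 0.5", {
  sf <- separable_features(n_subj = 8, gap = 6)
  A <- list(x = sf$x, y = sf$y)
  res <- cross_classify(A$x, A$y, A$x, A$y)
  pt_res <- permutation_test(res, n_perm = 99, seed = 5)
  expect_equal(pt_res$p_value, 1 / 100)        # observed beats every null
  expect_lt(abs(mean(pt_res$null_accuracies) - 0.5), 0.06)
  expect_length(pt_res$null_accuracies, 99)
  # same seed reproduces the null distribution exactly
  pt_res2 <- permutation_test(res, n_perm = 99, seed = 5)
  expect_identical(pt_res$null_accuracies, pt_res2$null_accuracies)
  # LOSO variant: shuffles within training folds only
  lres <- loso_classify(sf$x, sf$y, sf$subject)
  lpt <- permutation_test(lres, n_perm = 49, seed = 6)
  expect_equal(lpt$p_value, 1 / 50)
  expect_lt(abs(mean(lpt$null_accuracies) - 0.5), 0.12)
})

test_that("Fisher combination matches the closed-form chi-square(4) tail", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # for df = 4 the survival function is exp(-x/2) * (1 + x/2)
  x2 <- -2 * (log(0.05) + log(0.05))
  expect_equal(fisher_combine(c(0.05, 0.05)),
               exp(-x2 / 2) * (1 + x2 / 2), tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747, tolerance = 1e-3)
  expect_warning(p0 <- fisher_combine(c(0, 0.5), n_perm = 999), "clipped")
  expect_true(p0 > 0 && p0 < 1)
  # combining uniforms yields uniforms (KS on Monte-Carlo draws)
  set.seed(74)
  draws <- replicate(2000, fisher_combine(runif(3)))
  expect_gt(suppressWarnings(ks.test(draws, "punif"))$p.value, 0.01)
})

test_that("accuracy is invariant to edge-order permutation", {
  sf <- separable_features(n_subj = 8, gap = 3)
  perm <- sample(ncol(sf$x))
  r1 <- loso_classify(sf$x, sf$y, sf$subject)
  r2 <- loso_classify(sf$x[, perm], sf$y, sf$subject)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  # retained sets map through the permutation
  expect_setequal(perm[r2$folds[[1]]$retained], r1$folds[[1]]$retained)
})

test_that("the inter-subject cross-classification variant transfers planted effects", {
  set.seed(75)
  n_subj <- 8
  x <- matrix(abs(rnorm(4 * n_subj * 20, sd = 0.3)), 4 * n_subj)
  condition <- rep(c("EG", "EL", "UG", "UL"), n_subj)
  # Level effect on edge 7, identical for both letters
  x[cond_level(condition) == "Local", 7] <-
    x[cond_level(condition) == "Local", 7] + 3
  feats <- list(x = x, condition = condition,
                subject = rep(seq_len(n_subj), each = 4))
  res <- abstract_cross_loso(feats, "Level")
  expect_equal(res$accuracy, 1)
  expect_length(res$fold_accuracies$AtoB, n_subj)
  # no letter effect: transfer for Letter hovers at chance
  res_l <- abstract_cross_loso(feats, "Letter")
  expect_lt(res_l$accuracy, 0.85)
})
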
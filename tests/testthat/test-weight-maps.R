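test_that("Haufe transform equals the covariance-times-weights forward model", {
  # 3-feature fixture with hand-computable covariance
  X <- rbind(c(1, 2, 0), c(2, 4, 1), c(3, 5, 0), c(4, 9, 1))
  w <- c(0.5, -1, 2)
  model <- structure(list(w = w, retained = 1:3, positive_class = "Local"),
                     class = "svm_edge_model")
  a <- haufe_transform(model, X)
  # covariance by explicit sums
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    S[i, j] <- sum((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) / 3
  expect_equal(as.numeric(a), as.numeric(S %*% w), tolerance = 1e-12)

  # whitened features: activation proportional to the weights
  set.seed(81)
  Z <- matrix(rnorm(4000), 1000, 4)
  Z <- Z %*% solve(chol(cov(Z)))             # empirical identity covariance
  mw <- structure(list(w = c(1, -2, 0.5, 3), retained = 1:4,
                       positive_class = "Local"), class = "svm_edge_model")
  aw <- haufe_transform(mw, Z)
  expect_equal(as.numeric(aw), mw$w, tolerance = 1e-8)

  # anti-correlated noise-canceling pair: activations shrink toward zero
  n <- 500
  set.seed(82)
  u <- rnorm(n); e <- rnorm(n, sd = 0.05)
  Xa <- cbind(u, -u + e)
  ma <- structure(list(w = c(5, 5), retained = 1:2, positive_class = "Local"),
                  class = "svm_edge_model")
  aa <- haufe_transform(ma, Xa)
  # closed form: a1 = 5 * (var(u) + cov(u, -u+e)) which is ~ 5 * var(e)/ something small
  expect_lt(max(abs(aa)), 0.2 * max(abs(ma$w)))
  # non-retained edges are zero on the full index
  mr <- structure(list(w = c(1, 1), retained = c(2, 5), positive_class = "x"),
                  class = "svm_edge_model")
  ar <- haufe_transform(mr, matrix(rnorm(60), 10, 6))
  expect_true(all(ar[c(1, 3, 4, 6)] == 0))
  expect_error(haufe_transform(ma, Xa[1, , drop = FALSE]), "2 samples")
})

test_that("Kendall's W hits its analytic extremes and chance level", {
  expect_equal(kendalls_w(rbind(1:8, 1:8)), 1)
  expect_equal(kendalls_w(rbind(1:8, 8:1)), 0)   # rho = -1 => W = (1+rho)/2 = 0
  # two independent random rankings average W = 0.5
  set.seed(83)
  ws <- replicate(2000, kendalls_w(rbind(sample(50), sample(50))))
  expect_lt(abs(mean(ws) - 0.5), 0.01)
  # ties handled by midranks with tie correction; still bounded
  wt <- kendalls_w(rbind(c(1, 1, 2, 3), c(1, 2, 2, 3)))
  expect_true(wt >= 0 && wt <= 1)
  expect_error(kendalls_w(rbind(c(1, 1), c(1, 2))), "all-tied")
  expect_error(kendalls_w(rbind(1:3)), "m >= 2")
})

test_that("BCa intervals reduce to percentiles and achieve nominal coverage", {
  set.seed(84)
  b <- rnorm(4000)
  # z0 = 0 (original at the median), a = 0: exactly the percentile interval
  ci <- bca_ci(b, original_stat = median(b))
  expect_equal(unname(ci), unname(quantile(b, c(0.025, 0.975))),
               tolerance = 1e-6)
  # symmetric replicate distribution centered on the original: BCa close to
  # the percentile interval
  ci2 <- bca_ci(b, original_stat = mean(b))
  expect_lt(max(abs(ci2 - quantile(b, c(0.025, 0.975)))), sd(b) / 5)
  # coverage for the mean of a normal sample, jackknife acceleration
  cover <- vapply(1:500, function(s) {
    set.seed(s)
    x <- rnorm(30, mean = 1)
    boots <- vapply(1:999, function(b) mean(sample(x, replace = TRUE)), 0)
    jack <- vapply(seq_along(x), function(i) mean(x[-i]), 0)
    ci <- suppressWarnings(bca_ci(boots, mean(x), jackknife = jack))
    ci[1] <= 1 && 1 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
  expect_equal(unname(bca_ci(rep(2, 200), 2)), c(2, 2))
})

test_that("weight-map summaries pick the 2.5% tails deterministically", {
  # synthetic bootstrap object with identical replicates
  n_edges <- 1200
  set.seed(85)
  base <- numeric(n_edges)
  nz <- sample(n_edges, 1000)
  base[nz] <- rnorm(1000)
  boot <- structure(list(maps_e = matrix(base, 50, n_edges, byrow = TRUE),
                         maps_u = matrix(base, 50, n_edges, byrow = TRUE),
                         positive_level = "Local", n_boot = 50),
                    class = "weight_map_boot")
  sm <- suppressWarnings(summarize_maps(boot))
  expect_equal(sm$median_map, base)
  expect_equal(sm$n_nonzero, 1000)
  expect_length(sm$significant_edges$positive, 25)   # ceiling(0.025 * 1000)
  expect_length(sm$significant_edges$negative, 25)
  expect_length(intersect(sm$significant_edges$positive,
                          sm$significant_edges$negative), 0)
  expect_setequal(sm$significant_edges$positive,
                  order(base, decreasing = TRUE)[1:25])
  # identical replicates: Kendall's W = 1 with a point interval
  expect_equal(sm$w_median, 1)
  # scale invariance of the significant sets
  boot2 <- boot
  boot2$maps_e <- boot2$maps_e * 7; boot2$maps_u <- boot2$maps_u * 7
  sm2 <- suppressWarnings(summarize_maps(boot2))
  expect_identical(sm2$significant_edges, sm$significant_edges)
  # flipping the class coding negates the map and swaps the sets
  boot3 <- boot
  boot3$maps_e <- -boot3$maps_e; boot3$maps_u <- -boot3$maps_u
  sm3 <- suppressWarnings(summarize_maps(boot3))
  expect_equal(sm3$median_map, -sm$median_map)
  expect_identical(sm3$significant_edges$positive, sm$significant_edges$negative)
})

test_that("bootstrap weight maps are reproducible and consistent with the full sample", {
  sf <- separable_features(n_subj = 10, n_edges = 25, gap = 2, seed = 86)
  yl <- ifelse(sf$y == "A", "Global", "Local")
  b1 <- bootstrap_weight_maps(sf$x, yl, sf$x, yl, sf$subject, n_boot = 30,
                              seed = 9)
  b2 <- bootstrap_weight_maps(sf$x, yl, sf$x, yl, sf$subject, n_boot = 30,
                              seed = 9)
  expect_identical(b1$maps_e, b2$maps_e)
  # planted edge 3 supports Local (higher under Local): mean bootstrap
  # activation close to the full-sample activation
  full <- b1$full_e[3]
  expect_gt(full, 0)
  boot_mean <- mean(b1$maps_e[, 3])
  boot_se <- sd(b1$maps_e[, 3]) / 1   # scale of the replicate distribution
  expect_lt(abs(boot_mean - full), 2.5 * boot_se + 1e-12)
})

test_that("sub-network counts concentrate where edges are planted and conserve totals", {
  map <- small_map(40)
  part <- partition_subnetworks(map)
  lrlo_edges <- which(as.character(part) == "LRlo")
  n_edges <- length(part)
  med <- numeric(n_edges)
  med[lrlo_edges[1:10]] <- 5      # positive tail inside LRlo
  med[lrlo_edges[11:20]] <- -5    # negative tail inside LRlo
  med[setdiff(seq_len(n_edges), lrlo_edges)[1:360]] <-
    runif(360, -0.1, 0.1)
  boot <- structure(list(maps_e = matrix(med, 10, n_edges, byrow = TRUE),
                         maps_u = matrix(med, 10, n_edges, byrow = TRUE),
                         positive_level = "Local", n_boot = 10),
                    class = "weight_map_boot")
  sm <- suppressWarnings(summarize_maps(boot))
  counts <- subnetwork_counts(sm, part)
  expect_equal(sum(counts["Local", ]), length(sm$significant_edges$positive))
  expect_equal(sum(counts["not_Local", ]), length(sm$significant_edges$negative))
  expect_gte(counts["Local", "LRlo"], 10)
  expect_gte(counts["not_Local", "LRlo"], 10)
})

test_that("the heterogeneity test is calibrated and detects disjoint distributions", {
  # identical generating distributions: uniform p, nominal rejection rate
  set.seed(87)
  rej <- vapply(1:400, function(i) {
    t1 <- as.vector(rmultinom(1, 60, rep(0.1, 10)))
    t2 <- as.vector(rmultinom(1, 60, rep(0.1, 10)))
    heterogeneity_test(list(t1, t2), B = 499, seed = i)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # maximally disjoint one-hot distributions
  h <- heterogeneity_test(list(c(50, 0), c(0, 50)))
  expect_lt(h$p_value, 1e-6)
  expect_error(heterogeneity_test(list(c(1, 2))), "at least 2")
  expect_error(heterogeneity_test(list(c(0, 0), c(1, 1))), "zero-total")
})

test_that("direction concordance exceeds chance with shared topology, not without", {
  set.seed(88)
  n_subj <- 10; n_edges <- 60
  mk_pair <- function(informative) {
    x <- matrix(abs(rnorm(2 * n_subj * n_edges, sd = 0.3)), 2 * n_subj)
    y <- rep(c("Global", "Local"), n_subj)
    for (e in informative) x[y == "Local", e] <- x[y == "Local", e] + 1
    list(x = x, y = y)
  }
  subj <- rep(seq_len(n_subj), each = 2)
  # same informative edges in both directions: concordant rankings
  A <- mk_pair(1:5); B <- mk_pair(1:5)
  bs <- bootstrap_weight_maps(A$x, A$y, B$x, B$y, subj, n_boot = 60, seed = 1)
  sm <- suppressWarnings(summarize_maps(bs))
  expect_gt(sm$w_median, 0.5)
  # independent informative edges: W centers on its 0.5 chance level
  C <- mk_pair(1:5); D <- mk_pair(26:30)
  bs0 <- bootstrap_weight_maps(C$x, C$y, D$x, D$y, subj, n_boot = 60, seed = 2)
  sm0 <- suppressWarnings(summarize_maps(bs0))
  expect_lt(abs(sm0$w_median - 0.5), 0.2)
  expect_lt(sm0$w_median, sm$w_median)
})
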
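test_that("plug-in mutual information matches a hand-evaluated joint table", {
  # 2x2 joint distribution p = [[0.4, 0.1], [0.1, 0.4]]:
  # I = 0.8*log(1.6) + 0.2*log(0.4) = 0.192744...
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  expect_equal(eegfusion:::.mi_from_table(tab), 0.192744757, tolerance = 1e-8)
  # independence: I = 0
  expect_equal(eegfusion:::.mi_from_table(matrix(25, 2, 2)), 0)
})

test_that("MI scores: perfect dependence, independence, monotone invariance", {
  y <- rep(c(0L, 1L), 500)
  X <- cbind(ident = as.numeric(y), noise = 0)
  set.seed(10)
  X[, "noise"] <- rnorm(1000)
  sc <- mutual_information_scores(X, y)
  expect_equal(unname(sc["ident"]), log(2), tolerance = 1e-9)
  expect_lt(sc["noise"], 0.02)
  # quantile binning is invariant to strictly monotone transforms
  set.seed(11)
  x <- rnorm(300)
  yy <- rbinom(300, 1, 0.5)
  s1 <- mutual_information_scores(cbind(x), yy)
  s2 <- mutual_information_scores(cbind(exp(x)), yy)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
  expect_error(mutual_information_scores(cbind(x), rep(1, 300)),
               "single class")
})

test_that("MI filter retains floor(fraction * p) top features", {
  set.seed(12)
  X <- matrix(rnorm(60 * 249), 60, 249)
  y <- rep(0:1, 30)
  res <- mi_filter(X, y, 0.5)
  expect_length(res$retained, 124)
  expect_length(mi_filter(X[, 1:10], y, 0.5)$retained, 5)
  all_res <- mi_filter(X[, 1:10], y, 1.0)
  expect_identical(all_res$retained, 1:10)
  expect_error(mi_filter(X, y, 0), "in \\(0, 1\\]")
  # retained are exactly the top-scored, ties to the lower index
  d <- toy_features(n = 100, p = 6, k_inf = 2, shift = 2)
  r2 <- mi_filter(d$X, d$y, 0.5)
  expect_length(r2$retained, 3)
  expect_true(all(1:2 %in% r2$retained))
})

test_that("SFFS equals exhaustive subset search on constructed problems", {
  d <- toy_features(n = 60, p = 6, k_inf = 2, shift = 2, seed = 21)
  res <- sffs(d$X, d$y, 2, seed = 1)
  ev <- eegfusion:::.make_knn_evaluator(d$X, d$y, 5, 5, 1)
  pairs <- utils::combn(6, 2)
  pair_scores <- apply(pairs, 2, function(s) ev$score_subset(as.list(s)))
  best_pair <- sort(pairs[, which.max(pair_scores)])
  expect_identical(res$retained, as.integer(best_pair))
  expect_equal(res$best[[2]]$score, max(pair_scores))
  # a single perfectly predictive feature is picked at step 1
  d2 <- toy_features(n = 60, p = 5, k_inf = 0, seed = 22)
  d2$X[, 3] <- d2$y + 0.01 * d2$X[, 3]
  res2 <- sffs(d2$X, d2$y, 1, seed = 1)
  expect_equal(res2$trajectory$feature[1], 3)
  expect_identical(res2$retained, 3L)
  # degenerate targets
  expect_identical(sffs(d$X, d$y, 6)$retained, 1:6)
  expect_error(sffs(d$X, d$y, 7), "exceeds")
})

test_that("SFFS trajectory is reproducible and best scores never decrease", {
  d <- toy_features(n = 80, p = 8, k_inf = 3, shift = 1.2, seed = 23)
  r1 <- sffs(d$X, d$y, 4, seed = 5)
  r2 <- sffs(d$X, d$y, 4, seed = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$retained, r2$retained)
  # per size, the recorded best never decreases as the search proceeds
  tr <- r1$trajectory
  for (s in unique(tr$size)) {
    seq_s <- tr$score[tr$size == s]
    expect_true(all(diff(cummax(seq_s)) >= 0))
    expect_equal(max(seq_s), r1$best[[s]]$score)
  }
})

test_that("SFS, SBS and SFFS relate as expected on a monotone problem", {
  # independent informative features of graded strength: forward-only search
  # is optimal, so all three methods agree
  set.seed(24)
  n <- 80
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1] <- X[, 1] + 2.0 * y
  X[, 2] <- X[, 2] + 1.4 * y
  X[, 3] <- X[, 3] + 0.9 * y
  r_sffs <- sffs(X, y, 2, seed = 2)
  r_sfs <- sfs(X, y, 2, seed = 2)
  expect_identical(r_sffs$retained, r_sfs)
  expect_identical(sbs(X, y, 6, seed = 2), 1:6)
  # SFFS's best subset never scores below SFS's or SBS's at the target size
  ev <- eegfusion:::.make_knn_evaluator(X, y, 5, 5, 2)
  r_sbs <- sbs(X, y, 2, seed = 2)
  expect_gte(ev$score_subset(as.list(r_sffs$retained)),
             ev$score_subset(as.list(r_sfs)))
  expect_gte(ev$score_subset(as.list(r_sffs$retained)),
             ev$score_subset(as.list(r_sbs)))
})

test_that("correlation filter and PCA behave on constructed data", {
  set.seed(25)
  y <- rep(0:1, 50)
  X <- cbind(as.numeric(y), rnorm(100), y + rnorm(100) * 0.01)
  kept <- correlation_filter(X, y, threshold = 0.93)
  expect_true(1 %in% kept && 3 %in% kept)
  expect_false(2 %in% kept)
  # pairwise mode drops near-duplicates of already kept features
  kept2 <- correlation_filter(X, y, threshold = 0.93, mode = "pairwise")
  expect_true(1 %in% kept2 && 2 %in% kept2)
  expect_false(3 %in% kept2)
  # PCA to k = 2 reconstructs rank-2 data exactly
  base <- matrix(rnorm(40), 20, 2)
  Xr2 <- base %*% matrix(c(1, 2, 3, 0.5, -1, 2), 2, 3)
  pr <- pca_reduce(Xr2, 2)
  rec <- pr$scores %*% t(pr$rotation)
  rec <- sweep(rec, 2, pr$center, "+")
  expect_equal(rec, Xr2, tolerance = 1e-9)
  expect_equal(pr$project(Xr2), pr$scores, tolerance = 1e-9)
  # dispatcher: "mi" takes the top target_dim by score
  d <- toy_features(n = 100, p = 5, k_inf = 1, shift = 2.5, seed = 26)
  expect_true(1 %in% select_features(d$X, d$y, "mi", target_dim = 1))
})
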
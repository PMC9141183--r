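# Base classifiers, weight features and the fusion model.

sep_data <- function(n = 60, seed = 31, spread = 0.4) {
  set.seed(seed)
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * 2, sd = spread), n, 2) + outer(2 * y - 1, c(3, 3))
  list(X = X, y = y)
}

test_that("every base family emits normalized probabilities", {
  d <- sep_data()
  for (fam in c("knn", "svm", "rf")) {
    spec <- classifier_spec(fam, k = 5)
    m <- fit_classifier(spec, d$X, d$y, seed = 1)
    pr <- predict_classifier(m, d$X)
    expect_equal(rowSums(pr$prob), rep(1, nrow(d$X)), tolerance = 1e-9)
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    expect_true(all(pr$label %in% c(0L, 1L)))
  }
  expect_error(fit_classifier(classifier_spec("rf"), d$X, rep(1, 60)),
               "single class")
})

test_that("seeded classifier fits are deterministic", {
  d <- sep_data(seed = 32)
  for (fam in c("svm", "rf")) {
    m1 <- fit_classifier(classifier_spec(fam), d$X, d$y, seed = 9)
    m2 <- fit_classifier(classifier_spec(fam), d$X, d$y, seed = 9)
    p1 <- predict_classifier(m1, d$X)$prob
    p2 <- predict_classifier(m2, d$X)$prob
    expect_identical(p1, p2)
  }
})

test_that("cross-fitted training probabilities are confident on separable data", {
  d <- sep_data(n = 80, seed = 33)
  tb <- train_bases(d$X, d$y,
                    list(knn = classifier_spec("knn", k = 5),
                         rf = classifier_spec("rf"),
                         svm = classifier_spec("svm", cost = 1, gamma = 0.5)),
                    seed = 1)
  for (nm in names(tb$train_probs)) {
    pr <- tb$train_probs[[nm]]
    expect_equal(rowSums(pr), rep(1, 80), tolerance = 1e-9)
    p_true <- pr[cbind(seq_len(80), d$y + 1)]
    expect_gte(mean(p_true >= 0.9), 0.9)
  }
})

test_that("weight features are the per-class sums across fused bases", {
  expect_equal(unname(weight_features(list(cbind(1, 0), cbind(1, 0)))),
               cbind(2, 0))
  expect_equal(unname(weight_features(list(cbind(0.6, 0.4), cbind(0.2, 0.8)))),
               cbind(0.8, 1.2))
  k <- 3
  probs <- replicate(k, {
    p1 <- runif(10)
    cbind(1 - p1, p1)
  }, simplify = FALSE)
  W <- weight_features(probs)
  expect_equal(rowSums(W), rep(k, 10), tolerance = 1e-12)
  expect_error(weight_features(list(cbind(1, 0), cbind(1, 0, 0))), "shape")
})

test_that("fusion achieves perfect accuracy on separable data", {
  d <- sep_data(n = 80, seed = 34)
  te <- sep_data(n = 40, seed = 35)
  for (variant in list(c("knn", "rf"), c("knn", "svm"), c("rf", "svm"),
                       c("knn", "rf", "svm"))) {
    specs <- lapply(variant, function(f) classifier_spec(f, k = 5, cost = 1,
                                                         gamma = 0.5))
    names(specs) <- variant
    model <- fit_fusion(d$X, d$X, d$y, specs, classifier_spec("rf"), seed = 1)
    pred <- predict_fusion(model, te$X, te$X)
    acc <- mean(pred$label == te$y)
    expect_equal(acc, 1.0)
  }
})

test_that("constant weight features reduce fusion to the original features", {
  # a KNN final classifier cannot be influenced by columns that z-score to a
  # constant: predictions match the no-weight model exactly
  d <- toy_features(n = 60, p = 4, k_inf = 2, shift = 1.2, seed = 36)
  te <- toy_features(n = 30, p = 4, k_inf = 2, shift = 1.2, seed = 37)
  W_const <- cbind(rep(1, 60), rep(1, 60))
  Z <- cbind(d$X, W_const)
  zs <- zscore_fit(Z)
  m_w <- fit_classifier(classifier_spec("knn", k = 5), zscore_apply(Z, zs),
                        d$y)
  zs0 <- zscore_fit(d$X)
  m_0 <- fit_classifier(classifier_spec("knn", k = 5),
                        zscore_apply(d$X, zs0), d$y)
  Zte <- cbind(te$X, cbind(rep(1, 30), rep(1, 30)))
  p_w <- predict_classifier(m_w, zscore_apply(Zte, zs))$label
  p_0 <- predict_classifier(m_0, zscore_apply(te$X, zs0))$label
  expect_identical(p_w, p_0)
})

test_that("fusion predictions depend only on the fitted training data", {
  d <- sep_data(n = 60, seed = 38)
  te <- sep_data(n = 20, seed = 39)
  specs <- list(knn = classifier_spec("knn", k = 5), rf = classifier_spec("rf"))
  model <- fit_fusion(d$X, d$X, d$y, specs, classifier_spec("svm", cost = 1,
                                                            gamma = 0.5),
                      seed = 4)
  p_all <- predict_fusion(model, te$X, te$X)
  p_head <- predict_fusion(model, te$X[1:5, , drop = FALSE],
                           te$X[1:5, , drop = FALSE])
  expect_equal(p_all$prob[1:5, ], p_head$prob, tolerance = 1e-9)
  # dimension mismatch is caught
  expect_error(predict_fusion(model, te$X[, 1, drop = FALSE], te$X),
               "mismatch")
})

test_that("no-fusion model is the plain classifier on the selected subset", {
  d <- toy_features(n = 60, p = 4, k_inf = 2, shift = 1.5, seed = 40)
  m <- fit_fusion(d$X, d$X[, 1:2], d$y, list(), classifier_spec("knn", k = 5),
                  seed = 1)
  expect_false(m$fused)
  pred <- predict_fusion(m, d$X, d$X[, 1:2])
  expect_gte(mean(pred$label == d$y), max(mean(d$y == 1), mean(d$y == 0)))
})
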
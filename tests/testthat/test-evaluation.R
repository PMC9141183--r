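test_that("metrics match the defining confusion arithmetic", {
  # TP=3, FP=1, FN=2, TN=4
  y_true <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1)
  y_pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m[c("tp", "fp", "fn", "tn")], list(tp = 3, fp = 1, fn = 2,
                                                  tn = 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(m$f1, 4), 0.6667)
  # F1 identity against its own precision/recall
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # perfect prediction
  mp <- classification_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_equal(unlist(mp[1:4]), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  # all-positive prediction on balanced labels
  ma <- classification_metrics(rep(c(0, 1), 5), rep(1, 10))
  expect_equal(ma$recall, 1)
  expect_equal(ma$precision, 0.5)
  # guards return 0 with warnings (precision and F1 both degenerate here)
  expect_warning(expect_warning(
    mz <- classification_metrics(c(1, 1), c(0, 0)), "undefined"), "undefined")
  expect_equal(mz$precision, 0)
  expect_equal(mz$f1, 0)
  expect_error(classification_metrics(c(1, 0), c(1)), "length")
})

test_that("hold-out split is subject-disjoint with the expected row counts", {
  ids <- rep(sprintf("s%02d", 1:32), each = 160)
  sp <- holdout_split(ids, 27, 5, seed = 3)
  expect_length(sp$train_idx, 4320)
  expect_length(sp$test_idx, 800)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # two subjects, 1/1: every window lands on exactly one side
  ids2 <- rep(c("a", "b"), each = 7)
  sp2 <- holdout_split(ids2, 1, 1, seed = 1)
  expect_setequal(c(sp2$train_idx, sp2$test_idx), seq_along(ids2))
  expect_error(holdout_split(ids2, 2, 1), "only 2")
})

test_that("LOSO folds partition subjects and macro equals the fold mean", {
  ft <- fake_feature_table(n_subjects = 4, per_subject = 30, p = 8)
  cfg <- fold_config(mi_fraction = 0.5, target_dim = 3, selector = "mi",
                     variants = list(none = character(0),
                                     knn_rf = c("knn", "rf")),
                     finals = "knn",
                     base_specs = list(knn = classifier_spec("knn", k = 5),
                                       rf = classifier_spec("rf", ntree = 50)),
                     seed = 1)
  rep_ <- loso_cv(ft, cfg)
  res <- rep_$results
  expect_equal(sort(unique(res$fold)), sprintf("s%02d", 1:4))
  expect_true(all(res$n_test == 30))
  expect_true(all(res$tp + res$tn + res$fp + res$fn == res$n_test))
  # every subject tested exactly once per model
  expect_equal(nrow(res), 4 * 2 * 1)
  # macro average equals the mean of the per-fold values
  for (vn in c("none", "knn_rf")) {
    expect_equal(rep_$macro$accuracy[rep_$macro$variant == vn],
                 mean(res$accuracy[res$variant == vn]), tolerance = 1e-12)
  }
  # informative features drive accuracy well above chance
  expect_gt(rep_$macro$accuracy[rep_$macro$variant == "none"], 0.75)
  # exclusion list removes both the fold and the subject's rows
  rep2 <- loso_cv(ft, cfg, exclude = "s01")
  expect_equal(sort(unique(rep2$results$fold)), sprintf("s%02d", 2:4))
})

test_that("shuffled labels score at the majority-class rate (no leakage)", {
  ft <- fake_feature_table(n_subjects = 6, per_subject = 40, p = 8, k_inf = 0,
                           seed = 13)
  cfg <- fold_config(mi_fraction = 0.5, target_dim = 3, selector = "mi",
                     variants = list(none = character(0)), finals = "knn",
                     base_specs = list(knn = classifier_spec("knn", k = 5)),
                     seed = 1)
  rep_ <- loso_cv(ft, cfg)
  maj <- max(mean(ft$labels), 1 - mean(ft$labels))
  expect_lt(abs(rep_$macro$accuracy - maj), 0.07)
})

test_that("hold-out evaluation runs the full per-fold pipeline once", {
  ft <- fake_feature_table(n_subjects = 5, per_subject = 24, p = 8)
  cfg <- fold_config(mi_fraction = 1, target_dim = 4, selector = "sffs",
                     variants = list(none = character(0),
                                     rf_svm = c("rf", "svm")),
                     finals = c("knn", "rf"),
                     base_specs = list(knn = classifier_spec("knn", k = 5),
                                       svm = classifier_spec("svm", cost = 1,
                                                             gamma = 0.1),
                                       rf = classifier_spec("rf", ntree = 50)),
                     seed = 2)
  rep_ <- evaluate_holdout(ft, cfg, n_train = 4, n_test = 1, split_seed = 1)
  expect_equal(nrow(rep_$results), 2 * 2)
  expect_true(all(rep_$results$accuracy >= 0 & rep_$results$accuracy <= 1))
  expect_length(rep_$selected$holdout, 4)
  # report writers produce valid artifacts
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_report(rep_, jp, cp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$protocol, "holdout")
  expect_equal(nrow(read.csv(cp)), 4)
})
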
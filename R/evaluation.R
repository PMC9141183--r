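# Hold-out and leave-one-subject-out protocols. Every fold re-fits the whole
# pipeline (feature z-scoring, MI filter, wrapper selection, fusion) on the
# training subjects only, so no test-subject information leaks into any stage.

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with class 1 as the positive class.
#' Zero-denominator cases return 0 with a warning.
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, and the
#'   confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      return(0)
    }
    num / den
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "accuracy")
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * prec * rec, prec + rec, "F1")
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Subject-disjoint hold-out split
#'
#' @param subject_ids Character vector, one entry per window.
#' @param n_train,n_test Numbers of training/test subjects (defaults 27 / 5).
#' @param seed Seed controlling which subjects land in which side.
#' @return List with `train_subjects`, `test_subjects`, and the row index
#'   vectors `train_idx`, `test_idx`.
#' @export
holdout_split <- function(subject_ids, n_train = 27, n_test = 5, seed = 1) {
  subjects <- unique(subject_ids)
  if (n_train + n_test > length(subjects)) {
    stop(sprintf("need %d subjects but only %d are present",
                 n_train + n_test, length(subjects)))
  }
  picked <- with_seed(seed, sample(subjects, n_train + n_test))
  train_subjects <- picked[seq_len(n_train)]
  test_subjects <- picked[n_train + seq_len(n_test)]
  list(train_subjects = train_subjects, test_subjects = test_subjects,
       train_idx = which(subject_ids %in% train_subjects),
       test_idx = which(subject_ids %in% test_subjects))
}

#' Pipeline configuration for one evaluation fold
#'
#' @param mi_fraction Fraction of features kept by the mutual-information
#'   filter (default 0.5).
#' @param target_dim Subset size after wrapper selection (default 65).
#' @param selector `"sffs"`, `"sfs"`, `"sbs"` or `"mi"` (top `target_dim` by
#'   MI score, the fast mode).
#' @param variants Named list of base-family character vectors to fuse;
#'   `character(0)` entries denote the no-fusion baseline. Default: baseline
#'   plus the four fusion variants.
#' @param finals Final classifier families to evaluate (default all three).
#' @param base_specs Named list of [classifier_spec()]s for `"knn"`, `"svm"`,
#'   `"rf"`.
#' @param sffs_knn_k,sffs_folds Evaluator parameters of the wrapper search.
#' @param cross_folds Cross-fitting folds for the base probabilities.
#' @param seed Master seed.
#' @return List of class `fold_config`.
#' @export
fold_config <- function(mi_fraction = 0.5, target_dim = 65,
                        selector = c("sffs", "sfs", "sbs", "mi"),
                        variants = list(
                          none = character(0),
                          knn_rf = c("knn", "rf"),
                          knn_svm = c("knn", "svm"),
                          rf_svm = c("rf", "svm"),
                          knn_rf_svm = c("knn", "rf", "svm")),
                        finals = c("knn", "svm", "rf"),
                        base_specs = list(knn = classifier_spec("knn"),
                                          svm = classifier_spec("svm"),
                                          rf = classifier_spec("rf")),
                        sffs_knn_k = 5, sffs_folds = 5, cross_folds = 5,
                        seed = 1) {
  selector <- match.arg(selector)
  structure(list(mi_fraction = mi_fraction, target_dim = target_dim,
                 selector = selector, variants = variants, finals = finals,
                 base_specs = base_specs, sffs_knn_k = sffs_knn_k,
                 sffs_folds = sffs_folds, cross_folds = cross_folds,
                 seed = seed),
            class = "fold_config")
}

# Run selection + all requested variant/final combinations on one
# train/test split. Cross-fitted base probabilities are computed once per
# fold and shared across fusion variants.
.run_fold <- function(ft, train_idx, test_idx, cfg, fold_id) {
  ytr <- ft$labels[train_idx]
  yte <- ft$labels[test_idx]
  zs <- zscore_fit(ft$values[train_idx, , drop = FALSE])
  Xtr <- zscore_apply(ft$values[train_idx, , drop = FALSE], zs)
  Xte <- zscore_apply(ft$values[test_idx, , drop = FALSE], zs)
  # stage 1: MI filter on training data only
  flt <- mi_filter(Xtr, ytr, cfg$mi_fraction)
  keep <- flt$retained
  target <- min(cfg$target_dim, length(keep))
  # stage 2: wrapper (or fast MI) selection within the filtered set
  sel_local <- switch(cfg$selector,
    sffs = sffs(Xtr[, keep, drop = FALSE], ytr, target,
                knn_k = cfg$sffs_knn_k, n_folds = cfg$sffs_folds,
                seed = cfg$seed)$retained,
    sfs = sfs(Xtr[, keep, drop = FALSE], ytr, target,
              knn_k = cfg$sffs_knn_k, n_folds = cfg$sffs_folds,
              seed = cfg$seed),
    sbs = sbs(Xtr[, keep, drop = FALSE], ytr, target,
              knn_k = cfg$sffs_knn_k, n_folds = cfg$sffs_folds,
              seed = cfg$seed),
    mi = {
      sc <- flt$scores[keep]
      sort(order(-sc, seq_along(sc))[seq_len(target)])
    })
  selected <- keep[sel_local]
  Str <- Xtr[, selected, drop = FALSE]
  Ste <- Xte[, selected, drop = FALSE]
  # cross-fitted probabilities for every base family any variant needs
  need <- unique(unlist(cfg$variants))
  tb <- NULL
  if (length(need)) {
    tb <- train_bases(Str, ytr, cfg$base_specs[need],
                      n_folds = cfg$cross_folds, seed = cfg$seed)
  }
  rows <- list()
  for (vn in names(cfg$variants)) {
    fams <- cfg$variants[[vn]]
    for (fin in cfg$finals) {
      fin_spec <- cfg$base_specs[[fin]]
      if (length(fams) == 0) {
        model <- fit_fusion(Xtr, Str, ytr, list(), fin_spec, seed = cfg$seed)
        pred <- predict_fusion(model, Xte, Ste)
      } else {
        W <- weight_features(tb$train_probs[fams])
        Z <- cbind(Xtr, W)
        zsf <- zscore_fit(Z)
        final <- fit_classifier(fin_spec, zscore_apply(Z, zsf), ytr,
                                seed = derive_seed(cfg$seed, 999))
        Wte <- weight_features(lapply(tb$models[fams], function(m)
          predict_classifier(m, Ste)$prob))
        pred <- predict_classifier(final, zscore_apply(cbind(Xte, Wte), zsf))
      }
      m <- classification_metrics(yte, pred$label)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold_id, variant = vn, final = fin,
        accuracy = m$accuracy, precision = m$precision, recall = m$recall,
        f1 = m$f1, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
        n_test = length(yte), stringsAsFactors = FALSE)
    }
  }
  list(rows = do.call(rbind, rows), selected = selected)
}

# Macro averages per variant/final combination.
.macro_summary <- function(results) {
  agg <- aggregate(results[, c("accuracy", "precision", "recall", "f1")],
                   by = list(variant = results$variant, final = results$final),
                   FUN = mean)
  agg[order(agg$variant, agg$final), , drop = FALSE]
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' One fold per retained subject; within each fold every pipeline stage is
#' re-fit on the training subjects only. Subjects whose labels are
#' single-class are flagged and their precision/recall guards apply.
#'
#' @param ft A `feature_table` covering >= 2 subjects.
#' @param cfg A [fold_config()].
#' @param exclude Character vector of subject ids to leave out entirely.
#' @return An `evaluation_report`: list with `protocol`, `results` (one row per
#'   fold x variant x final), `macro` (means over folds), `selected` (per-fold
#'   selected feature indices) and `config`.
#' @export
loso_cv <- function(ft, cfg = fold_config(), exclude = character()) {
  stopifnot(inherits(ft, "feature_table"))
  subjects <- setdiff(unique(ft$subject_ids), exclude)
  if (length(subjects) < 2) stop("LOSO needs at least 2 retained subjects")
  all_rows <- list()
  selected <- list()
  for (s in subjects) {
    test_idx <- which(ft$subject_ids == s)
    train_idx <- which(ft$subject_ids %in% setdiff(subjects, s))
    if (length(unique(ft$labels[test_idx])) < 2) {
      message(sprintf("subject %s has single-class labels; metrics guarded", s))
    }
    res <- .run_fold(ft, train_idx, test_idx, cfg, fold_id = s)
    all_rows[[s]] <- res$rows
    selected[[s]] <- res$selected
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  structure(list(protocol = "loso", results = results,
                 macro = .macro_summary(results), selected = selected,
                 config = cfg, subjects = subjects),
            class = "evaluation_report")
}

#' Hold-out evaluation of the full pipeline
#'
#' @param ft A `feature_table`.
#' @param cfg A [fold_config()].
#' @param n_train,n_test Numbers of training/test subjects (defaults 27 / 5).
#' @param split_seed Seed of the subject split.
#' @return An `evaluation_report` with a single fold.
#' @export
evaluate_holdout <- function(ft, cfg = fold_config(), n_train = 27,
                             n_test = 5, split_seed = 1) {
  stopifnot(inherits(ft, "feature_table"))
  sp <- holdout_split(ft$subject_ids, n_train, n_test, split_seed)
  res <- .run_fold(ft, sp$train_idx, sp$test_idx, cfg, fold_id = "holdout")
  structure(list(protocol = "holdout", results = res$rows,
                 macro = .macro_summary(res$rows),
                 selected = list(holdout = res$selected),
                 config = cfg, split = sp),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> protocol=%s, %d fold(s)\n",
              x$protocol, length(unique(x$results$fold))))
  print(x$macro, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report An `evaluation_report`.
#' @param json_path Optional JSON path (macro averages + per-fold rows).
#' @param csv_path Optional CSV path (one row per fold x variant x final).
#' @return The report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(protocol = report$protocol, macro = report$macro,
           results = report$results),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(csv_path)) write.csv(report$results, csv_path, row.names = FALSE)
  invisible(report)
}
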
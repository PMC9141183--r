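# Multi-classifier fusion: base classifiers trained on the selected feature
# subset emit class probabilities; the probabilities of the fused bases are
# summed into "weight features", concatenated with the original feature block,
# re-standardized, and handed to a final classifier.

#' Train base classifiers and their cross-fitted training probabilities
#'
#' Each base is fitted on the full training data (for test-time prediction).
#' Training-set probabilities are cross-fitted (out-of-fold) by default so the
#' weight features fed to the final classifier are leakage-free; a random
#' forest's in-sample probabilities would otherwise be nearly 0/1. Set
#' `naive_insample = TRUE` to use in-sample probabilities instead.
#'
#' @param X_select Numeric matrix of the selected feature subset.
#' @param y Binary 0/1 labels.
#' @param specs Named list of [classifier_spec()]s (names identify the bases).
#' @param n_folds Cross-fitting folds (default 5).
#' @param seed Master seed for folds and stochastic fits.
#' @param naive_insample Use in-sample probabilities for the training set.
#' @return List with `models` (fitted bases) and `train_probs` (per base, an
#'   `n x 2` probability matrix whose rows sum to 1).
#' @export
train_bases <- function(X_select, y, specs, n_folds = 5, seed = 1,
                        naive_insample = FALSE) {
  X_select <- as.matrix(X_select)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  stopifnot(length(specs) >= 1)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "family")
  }
  models <- lapply(seq_along(specs), function(i)
    fit_classifier(specs[[i]], X_select, y, seed = derive_seed(seed, i)))
  names(models) <- names(specs)
  if (naive_insample) {
    train_probs <- lapply(models, function(m)
      predict_classifier(m, X_select)$prob)
  } else {
    fold <- stratified_folds(y, min(n_folds, length(y)), seed)
    train_probs <- lapply(seq_along(specs), function(i) {
      probs <- matrix(NA_real_, length(y), 2, dimnames = list(NULL, c("0", "1")))
      for (fd in unique(fold)) {
        te <- which(fold == fd)
        tr <- which(fold != fd)
        m <- fit_classifier(specs[[i]], X_select[tr, , drop = FALSE], y[tr],
                            seed = derive_seed(seed, i * 100 + fd))
        probs[te, ] <- predict_classifier(m, X_select[te, , drop = FALSE])$prob
      }
      probs
    })
  }
  names(train_probs) <- names(specs)
  list(models = models, train_probs = train_probs)
}

#' Sum per-class probabilities of the fused bases into weight features
#'
#' @param prob_list List of `n x 2` probability matrices, one per fused base.
#' @return `n x 2` matrix; every row sums to the number of fused bases.
#' @export
weight_features <- function(prob_list) {
  stopifnot(length(prob_list) >= 1)
  dims <- lapply(prob_list, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("probability matrices must share the same shape (same class set)")
  }
  W <- Reduce(`+`, lapply(prob_list, unname))
  colnames(W) <- c("w0", "w1")
  W
}

#' Fit the fusion model
#'
#' The final classifier consumes the original feature block concatenated with
#' the weight features; the concatenated matrix is re-standardized on the
#' training data.
#'
#' @param X_ori Numeric matrix of the full original feature block (training).
#' @param X_select Numeric matrix of the selected subset (training).
#' @param y Binary 0/1 labels.
#' @param base_specs Named list of [classifier_spec()]s to fuse; an empty list
#'   yields a no-fusion model (final classifier on `X_select` alone).
#' @param final_spec [classifier_spec()] of the final classifier.
#' @param n_folds Cross-fitting folds for the training probabilities.
#' @param seed Master seed.
#' @param naive_insample See [train_bases()].
#' @return An object of class `fusion_model`.
#' @export
fit_fusion <- function(X_ori, X_select, y, base_specs, final_spec,
                       n_folds = 5, seed = 1, naive_insample = FALSE) {
  X_ori <- as.matrix(X_ori)
  X_select <- as.matrix(X_select)
  stopifnot(nrow(X_ori) == nrow(X_select), nrow(X_ori) == length(y))
  if (length(base_specs) == 0) {
    zs <- zscore_fit(X_select)
    final <- fit_classifier(final_spec, zscore_apply(X_select, zs), y,
                            seed = derive_seed(seed, 999))
    return(structure(list(bases = NULL, base_specs = list(),
                          final = final, final_spec = final_spec,
                          zscore = zs, fused = FALSE),
                     class = "fusion_model"))
  }
  tb <- train_bases(X_select, y, base_specs, n_folds = n_folds, seed = seed,
                    naive_insample = naive_insample)
  W <- weight_features(tb$train_probs)
  Z <- cbind(X_ori, W)
  zs <- zscore_fit(Z)
  final <- fit_classifier(final_spec, zscore_apply(Z, zs), y,
                          seed = derive_seed(seed, 999))
  structure(list(bases = tb$models, base_specs = base_specs,
                 final = final, final_spec = final_spec,
                 zscore = zs, fused = TRUE),
            class = "fusion_model")
}

#' Predict from a fusion model
#'
#' Test-time weight features come from the bases fitted on all training data.
#'
#' @param model A [fit_fusion()] result.
#' @param X_ori_new Original feature block for the new observations.
#' @param X_select_new Selected subset for the new observations.
#' @return List with `label` (0/1) and `prob` (`n x 2`).
#' @export
predict_fusion <- function(model, X_ori_new, X_select_new) {
  stopifnot(inherits(model, "fusion_model"))
  X_select_new <- as.matrix(X_select_new)
  if (!model$fused) {
    return(predict_classifier(model$final,
                              zscore_apply(X_select_new, model$zscore)))
  }
  X_ori_new <- as.matrix(X_ori_new)
  probs <- lapply(model$bases, function(m)
    predict_classifier(m, X_select_new)$prob)
  W <- weight_features(probs)
  Z <- cbind(X_ori_new, W)
  if (ncol(Z) != length(model$zscore$mu)) {
    stop("dimension mismatch between the fitted model and the new data")
  }
  predict_classifier(model$final, zscore_apply(Z, model$zscore))
}
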
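# A uniform surface over the three base classifier families. All of them emit
# per-sample class probabilities over classes {0, 1}; every stochastic fit is
# seed-controlled so identical inputs give identical models.

#' Classifier specification
#'
#' Defaults follow the reference configuration: KNN with k = 41, RBF-kernel
#' SVM with C = 0.7 and gamma = 0.015, random forest with 100 trees.
#'
#' @param family One of `"knn"`, `"svm"` (RBF kernel), `"svm_poly"`
#'   (polynomial kernel) or `"rf"`.
#' @param k Neighbour count for KNN.
#' @param cost,gamma,degree SVM hyperparameters.
#' @param ntree Number of random-forest trees.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "svm", "svm_poly", "rf"),
                            k = 41, cost = 0.7, gamma = 0.015, degree = 3,
                            ntree = 100) {
  family <- match.arg(family)
  structure(list(family = family, k = k, cost = cost, gamma = gamma,
                 degree = degree, ntree = ntree),
            class = "classifier_spec")
}

# KNN with vote-proportion probabilities. Deterministic: stable ordering of
# squared Euclidean distances, ties at p = 0.5 resolved to class 0.
.knn_prob <- function(Xtr, ytr, Xte, k) {
  Xtr <- as.matrix(Xtr)
  Xte <- as.matrix(Xte)
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
  p1 <- apply(d2, 1, function(r) {
    nn <- sort.int(r, index.return = TRUE)$ix[seq_len(k)]
    mean(ytr[nn] == 1)
  })
  cbind(`0` = 1 - p1, `1` = p1)
}

#' Fit a base classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric training matrix.
#' @param y Binary 0/1 labels (both classes must be present).
#' @param seed Seed applied to the stochastic fits (SVM probability
#'   calibration, random forest).
#' @return Fitted model of class `eeg_classifier`.
#' @export
fit_classifier <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))  # canonical, so prediction
  y <- as.integer(y)                            # never depends on caller names
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(spec$family,
    knn = list(X = X, y = y, k = spec$k),
    svm = with_seed(seed, e1071::svm(
      x = X, y = yf, type = "C-classification", kernel = "radial",
      cost = spec$cost, gamma = spec$gamma, probability = TRUE)),
    svm_poly = with_seed(seed, e1071::svm(
      x = X, y = yf, type = "C-classification", kernel = "polynomial",
      cost = spec$cost, degree = spec$degree, probability = TRUE)),
    rf = with_seed(seed, randomForest::randomForest(x = X, y = yf,
                                                    ntree = spec$ntree))
  )
  structure(list(spec = spec, fit = fit), class = "eeg_classifier")
}

#' Class probabilities and labels from a fitted classifier
#'
#' @param model A [fit_classifier()] result.
#' @param X Numeric matrix of new observations.
#' @return List with `prob` (`n x 2` matrix, columns `"0"` and `"1"`, rows
#'   summing to 1) and `label` (0/1 predictions, argmax with ties to 0).
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "eeg_classifier"))
  X <- as.matrix(X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  prob <- switch(model$spec$family,
    knn = .knn_prob(model$fit$X, model$fit$y, X, model$fit$k),
    svm = ,
    svm_poly = {
      pr <- attr(predict(model$fit, X, probability = TRUE), "probabilities")
      pr[, c("0", "1"), drop = FALSE]
    },
    rf = {
      pr <- predict(model$fit, X, type = "prob")
      pr[, c("0", "1"), drop = FALSE]
    }
  )
  prob <- unname(prob)
  colnames(prob) <- c("0", "1")
  list(prob = prob, label = as.integer(prob[, "1"] > 0.5))
}
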
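# Two-stage feature selection: a mutual-information filter over
# quantile-binned features, then sequential forward floating selection with a
# cross-validated KNN evaluator. Forward-only (SFS), backward-only (SBS),
# correlation and PCA alternatives share the same machinery.

# Plug-in mutual information (nats) from a joint contingency table.
.mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  max(sum(terms[p > 0]), 0)
}

# Quantile-bin a continuous feature; constant features get a single bin.
.quantile_bin <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Mutual information between each feature and the class label
#'
#' Each continuous feature is quantile-binned, then the plug-in mutual
#' information `I(X; Y) = sum p(x,y) log(p(x,y) / (p(x) p(y)))` is evaluated in
#' nats. Quantile binning makes the score invariant to strictly monotone
#' transforms of a feature.
#'
#' @param features Numeric matrix with >= 10 rows.
#' @param labels Binary 0/1 vector with both classes present.
#' @param n_bins Number of quantile bins (default 10).
#' @return Numeric vector of non-negative scores, one per column.
#' @export
mutual_information_scores <- function(features, labels, n_bins = 10) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 rows")
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  apply(features, 2, function(x) {
    b <- .quantile_bin(x, n_bins)
    .mi_from_table(table(b, labels))
  })
}

#' Mutual-information filter
#'
#' Retains the `floor(retain_fraction * n_features)` top-scoring features;
#' score ties are broken in favour of the lower column index.
#'
#' @inheritParams mutual_information_scores
#' @param retain_fraction Fraction of features to keep, in (0, 1].
#' @return An object of class `mi_result` with fields `scores`, `ranking`
#'   (columns ordered by decreasing score), `retained` (sorted index set) and
#'   `retain_fraction`.
#' @export
mi_filter <- function(features, labels, retain_fraction = 0.5, n_bins = 10) {
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must be in (0, 1]")
  }
  scores <- mutual_information_scores(features, labels, n_bins)
  ranking <- order(-scores, seq_along(scores))
  n_keep <- floor(retain_fraction * length(scores))
  structure(
    list(scores = scores, ranking = ranking,
         retained = sort(ranking[seq_len(n_keep)]),
         retain_fraction = retain_fraction),
    class = "mi_result"
  )
}

# --- KNN cross-validation evaluator ------------------------------------------

# Closure-based evaluator caching one squared-difference matrix per feature,
# so adding/removing a candidate scores in O(n^2) without materializing the
# updated subset distance matrix (the fold scoring lives in C++).
.make_knn_evaluator <- function(X, y, k = 5, n_folds = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.integer(y)
  n_folds <- min(n_folds, n)
  fold <- as.integer(stratified_folds(y, n_folds, seed))
  cache <- vector("list", ncol(X))
  zero <- matrix(0, n, n)
  feat_dist <- function(f) {
    if (is.null(cache[[f]])) cache[[f]] <<- outer(X[, f], X[, f], "-")^2
    cache[[f]]
  }
  score_with <- function(D, f = NULL, sgn = 0) {
    .knn_cv_score_cpp(D, if (is.null(f)) D else feat_dist(f), sgn, fold, y, k)
  }
  list(feat_dist = feat_dist, zero = zero, score_with = score_with,
       score_subset = function(subset) {
         D <- Reduce(`+`, lapply(subset, feat_dist), accumulate = FALSE)
         score_with(D)
       })
}

#' Sequential forward floating selection (SFFS)
#'
#' Classic floating search: repeatedly add the single feature that maximizes
#' the evaluator score, then conditionally remove any feature whose removal
#' strictly improves on the best known score at the smaller subset size. The
#' evaluator is stratified cross-validated accuracy of a KNN classifier. The
#' search stops once the best subset of size `target_dim` is stable for a full
#' forward-backward cycle (or the candidate pool is exhausted). Ties are broken
#' in favour of the lowest feature index.
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 vector.
#' @param target_dim Desired subset size.
#' @param knn_k Neighbour count of the evaluator (default 5).
#' @param n_folds Cross-validation folds of the evaluator (default 5).
#' @param seed Fold seed; fixed data + seed give an identical trajectory.
#' @param max_cycles Safety cap on forward-backward cycles (default
#'   `5 * target_dim + 50`). On plateau-heavy evaluator landscapes the
#'   floating search can ratchet through very many add/remove oscillations
#'   that no longer change the subset at the target size; once the cap is hit
#'   the best recorded subset of size `target_dim` is returned.
#' @return An object of class `sffs_result` with fields `retained` (sorted
#'   index set of size `target_dim`), `trajectory` (data frame of step, action,
#'   feature, size, score) and `best` (best score and subset per visited size).
#' @export
sffs <- function(features, labels, target_dim, knn_k = 5, n_folds = 5,
                 seed = 1, max_cycles = 5 * target_dim + 50) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (target_dim > p) stop("target_dim exceeds the number of features")
  if (target_dim == p) {
    return(structure(list(retained = seq_len(p),
                          trajectory = data.frame(),
                          best = list()), class = "sffs_result"))
  }
  ev <- .make_knn_evaluator(features, labels, knn_k, n_folds, seed)
  best <- vector("list", p)  # best[[k]] = list(score, subset)
  cur <- integer(0)
  cur_D <- ev$zero
  traj <- list()
  step <- 0L
  record <- function(action, f, score, size) {
    step <<- step + 1L
    traj[[step]] <<- data.frame(step = step, action = action, feature = f,
                                size = size, score = score)
  }
  update_best <- function(size, score, subset) {
    if (is.null(best[[size]]) || score > best[[size]]$score) {
      best[[size]] <<- list(score = score, subset = sort(subset))
    }
  }
  prev_target_best <- NULL
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    if (cycles > max_cycles && !is.null(best[[target_dim]])) break
    # forward: add the best-scoring candidate (lowest index on ties)
    cand <- setdiff(seq_len(p), cur)
    if (!length(cand)) break
    scores <- vapply(cand, function(f) ev$score_with(cur_D, f, 1), numeric(1))
    fbest <- cand[which.max(scores)]
    cur <- c(cur, fbest)
    cur_D <- cur_D + ev$feat_dist(fbest)
    sc <- max(scores)
    record("add", fbest, sc, length(cur))
    update_best(length(cur), sc, cur)
    # conditional backward: remove while it strictly improves best at size-1
    while (length(cur) > 2) {
      rm_scores <- vapply(cur, function(f) ev$score_with(cur_D, f, -1),
                          numeric(1))
      jbest <- which.max(rm_scores)
      smaller <- length(cur) - 1L
      if (!is.null(best[[smaller]]) &&
          rm_scores[jbest] <= best[[smaller]]$score) break
      f_out <- cur[jbest]
      cur_D <- cur_D - ev$feat_dist(f_out)
      cur <- cur[-jbest]
      record("remove", f_out, rm_scores[jbest], length(cur))
      update_best(length(cur), rm_scores[jbest], cur)
    }
    if (length(cur) >= target_dim && !is.null(best[[target_dim]])) {
      if (identical(best[[target_dim]]$subset, prev_target_best)) break
      prev_target_best <- best[[target_dim]]$subset
    }
    if (length(cur) >= p) break
  }
  structure(
    list(retained = best[[target_dim]]$subset,
         trajectory = do.call(rbind, traj),
         best = best),
    class = "sffs_result"
  )
}

#' Forward-only sequential selection (SFS)
#'
#' @inheritParams sffs
#' @return Sorted index set of size `target_dim`.
#' @export
sfs <- function(features, labels, target_dim, knn_k = 5, n_folds = 5,
                seed = 1) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (target_dim > p) stop("target_dim exceeds the number of features")
  ev <- .make_knn_evaluator(features, labels, knn_k, n_folds, seed)
  cur <- integer(0)
  cur_D <- ev$zero
  while (length(cur) < target_dim) {
    cand <- setdiff(seq_len(p), cur)
    scores <- vapply(cand, function(f) ev$score_with(cur_D, f, 1), numeric(1))
    fbest <- cand[which.max(scores)]
    cur <- c(cur, fbest)
    cur_D <- cur_D + ev$feat_dist(fbest)
  }
  sort(cur)
}

#' Backward-only sequential selection (SBS)
#'
#' @inheritParams sffs
#' @return Sorted index set of size `target_dim`.
#' @export
sbs <- function(features, labels, target_dim, knn_k = 5, n_folds = 5,
                seed = 1) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (target_dim > p) stop("target_dim exceeds the number of features")
  ev <- .make_knn_evaluator(features, labels, knn_k, n_folds, seed)
  cur <- seq_len(p)
  cur_D <- Reduce(`+`, lapply(cur, ev$feat_dist))
  while (length(cur) > target_dim) {
    scores <- vapply(cur, function(f) ev$score_with(cur_D, f, -1), numeric(1))
    jbest <- which.max(scores)
    cur_D <- cur_D - ev$feat_dist(cur[jbest])
    cur <- cur[-jbest]
  }
  sort(cur)
}

#' Correlation filter
#'
#' With `mode = "target"` (default) features whose absolute Pearson
#' correlation with the label is at or above the threshold are retained. With
#' `mode = "pairwise"` features are scanned in order and dropped when they
#' correlate above the threshold with an already retained feature (a
#' redundancy filter).
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 vector.
#' @param threshold Correlation threshold (default 0.93).
#' @param mode `"target"` or `"pairwise"`.
#' @return Sorted integer vector of retained column indices.
#' @export
correlation_filter <- function(features, labels, threshold = 0.93,
                               mode = c("target", "pairwise")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (mode == "target") {
    r <- suppressWarnings(abs(cor(features, labels)))
    r[is.na(r)] <- 0
    which(as.vector(r) >= threshold)
  } else {
    kept <- integer(0)
    for (j in seq_len(ncol(features))) {
      if (!length(kept)) { kept <- j; next }
      r <- suppressWarnings(abs(cor(features[, kept, drop = FALSE],
                                    features[, j])))
      r[is.na(r)] <- 0
      if (all(r < threshold)) kept <- c(kept, j)
    }
    kept
  }
}

#' PCA reduction to k components
#'
#' @param features Numeric matrix.
#' @param k Number of principal components.
#' @return List with `scores` (`n x k`), `rotation`, `center`, and a
#'   `project(newdata)` function for held-out rows.
#' @export
pca_reduce <- function(features, k) {
  features <- as.matrix(features)
  if (k > ncol(features)) stop("k exceeds the number of features")
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  ctr <- pc$center
  list(scores = pc$x[, seq_len(k), drop = FALSE], rotation = rot,
       center = ctr,
       project = function(newdata) {
         sweep(as.matrix(newdata), 2, ctr) %*% rot
       })
}

#' Dispatch over the available selection methods
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 vector.
#' @param method One of `"sffs"`, `"sfs"`, `"sbs"`, `"mi"`, `"corr"`, `"pca"`.
#'   `"mi"` retains the `target_dim` top features by mutual information.
#' @param target_dim Subset size for the subset-valued methods.
#' @param ... Passed to the underlying method.
#' @return Sorted integer index set (or the [pca_reduce()] list for `"pca"`).
#' @export
select_features <- function(features, labels,
                            method = c("sffs", "sfs", "sbs", "mi", "corr",
                                       "pca"),
                            target_dim = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    sffs = sffs(features, labels, target_dim, ...)$retained,
    sfs = sfs(features, labels, target_dim, ...),
    sbs = sbs(features, labels, target_dim, ...),
    mi = {
      scores <- mutual_information_scores(features, labels, ...)
      sort(order(-scores, seq_along(scores))[seq_len(target_dim)])
    },
    corr = correlation_filter(features, labels, ...),
    pca = pca_reduce(features, target_dim)
  )
}
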
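# Recording and windowed-dataset containers plus the deterministic
# preprocessing steps: trimming, windowing, channel selection, label
# binarization and feature-level z-scoring.

#' The 32 electrodes of the DEAP preprocessed release (Geneva order)
#'
#' @return Character vector of 32 electrode labels in the order used by the
#'   DEAP preprocessed files.
#' @export
deap_channel_names <- function() {
  c("FP1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "OZ", "PZ", "FP2", "AF4", "FZ", "F4",
    "F8", "FC6", "FC2", "CZ", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

#' The 15-electrode emotion montage
#'
#' Frontal (AF3, AF4, F3, F4, F7, F8, FP1, FP2), parietal (P7, P8), temporal
#' (T7, T8), occipital (O1, O2) and central (CZ) electrodes used throughout
#' the pipeline.
#'
#' @return Character vector of 15 electrode labels.
#' @export
emotion_channels <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FP1", "FP2",
    "P7", "P8", "T7", "T8", "O1", "O2", "CZ")
}

#' Construct a single-subject EEG recording
#'
#' @param subject_id Character scalar identifying the subject.
#' @param signal Numeric array `[n_trials x n_channels x n_samples]` in
#'   microvolts.
#' @param sampling_rate Samples per second (default 128).
#' @param channel_names Character vector of electrode labels, one per channel.
#' @param ratings Numeric matrix `[n_trials x 4]` of continuous self-report
#'   ratings in the order valence, arousal, dominance, liking.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(subject_id, signal, sampling_rate = 128,
                      channel_names = NULL, ratings = NULL) {
  stopifnot(is.array(signal), length(dim(signal)) == 3)
  dims <- dim(signal)
  if (dims[1] < 1) stop("a recording needs at least one trial")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("CH", seq_len(dims[2]))
  }
  channel_names <- toupper(as.character(channel_names))
  if (length(channel_names) != dims[2]) {
    stop("channel_names must have one entry per channel")
  }
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  if (is.null(ratings)) {
    ratings <- matrix(NA_real_, dims[1], 4)
  }
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != dims[1] || ncol(ratings) != 4) {
    stop("ratings must be an n_trials x 4 matrix")
  }
  colnames(ratings) <- c("valence", "arousal", "dominance", "liking")
  structure(
    list(subject_id = as.character(subject_id), signal = signal,
         sampling_rate = sampling_rate, channel_names = channel_names,
         ratings = ratings),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<eeg_recording> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

#' Keep only the trailing seconds of every trial
#'
#' Emotional engagement builds up over a trial, so only the final portion of
#' each trial is analysed; the default protocol keeps the last 40 s.
#'
#' @param rec An [recording()].
#' @param seconds Positive number of trailing seconds to keep.
#' @return A recording whose trials contain exactly
#'   `round(seconds * sampling_rate)` trailing samples; ratings are unchanged.
#' @export
trim_to_last_seconds <- function(rec, seconds) {
  stopifnot(inherits(rec, "eeg_recording"), seconds > 0)
  n_samples <- dim(rec$signal)[3]
  keep <- round(seconds * rec$sampling_rate)
  if (keep > n_samples) {
    stop(sprintf(
      "requested %g s (%d samples) but trials have only %d samples",
      seconds, keep, n_samples))
  }
  rec$signal <- rec$signal[, , (n_samples - keep + 1):n_samples, drop = FALSE]
  rec
}

#' Binarize continuous valence ratings
#'
#' Ratings at or below the threshold are labelled 0 (negative valence); ratings
#' strictly above it are labelled 1 (positive valence).
#'
#' @param ratings Numeric vector of finite ratings.
#' @param threshold Decision threshold, default 5.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_valence <- function(ratings, threshold = 5) {
  if (!all(is.finite(ratings))) stop("ratings must be finite")
  as.integer(ratings > threshold)
}

#' Cut every trial into contiguous non-overlapping windows
#'
#' @param rec An [recording()].
#' @param window_seconds Window width in seconds (default 10).
#' @param valence_threshold Threshold handed to [binarize_valence()]; every
#'   window inherits its source trial's binarized valence label.
#' @return An object of class `windowed_dataset` with fields `windows`
#'   (`[n_windows x n_channels x window_len]`), `labels`, and per-window
#'   provenance `subject_ids`, `trial_ids`, `window_index`.
#' @export
slice_windows <- function(rec, window_seconds = 10, valence_threshold = 5) {
  stopifnot(inherits(rec, "eeg_recording"), window_seconds > 0)
  d <- dim(rec$signal)
  win_len <- round(window_seconds * rec$sampling_rate)
  if (d[3] %% win_len != 0) {
    stop(sprintf(
      "trial length %d is not divisible by the window length %d; no silent truncation",
      d[3], win_len))
  }
  per_trial <- d[3] %/% win_len
  n_windows <- d[1] * per_trial
  labels <- binarize_valence(rec$ratings[, "valence"], valence_threshold)
  windows <- array(NA_real_, c(n_windows, d[2], win_len))
  trial_ids <- integer(n_windows)
  window_index <- integer(n_windows)
  out_labels <- integer(n_windows)
  row <- 1L
  for (tr in seq_len(d[1])) {
    for (w in seq_len(per_trial)) {
      from <- (w - 1L) * win_len + 1L
      windows[row, , ] <- rec$signal[tr, , from:(from + win_len - 1L)]
      trial_ids[row] <- tr
      window_index[row] <- w
      out_labels[row] <- labels[tr]
      row <- row + 1L
    }
  }
  structure(
    list(windows = windows, labels = out_labels,
         subject_ids = rep(rec$subject_id, n_windows),
         trial_ids = trial_ids, window_index = window_index,
         channel_names = rec$channel_names,
         sampling_rate = rec$sampling_rate),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf(
    "<windowed_dataset> %d windows x %d channels x %d samples, %d subject(s)\n",
    d[1], d[2], d[3], length(unique(x$subject_ids))))
  invisible(x)
}

#' Combine windowed datasets from several subjects
#'
#' @param ... `windowed_dataset` objects (or a single list of them) sharing the
#'   same channel set and sampling rate.
#' @return One `windowed_dataset` with stacked windows and provenance.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "windowed_dataset")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1)
  ref <- parts[[1]]
  for (p in parts) {
    stopifnot(inherits(p, "windowed_dataset"),
              identical(p$channel_names, ref$channel_names),
              identical(p$sampling_rate, ref$sampling_rate))
  }
  n <- sum(vapply(parts, function(p) dim(p$windows)[1], integer(1)))
  d <- dim(ref$windows)
  windows <- array(NA_real_, c(n, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    k <- dim(p$windows)[1]
    windows[at:(at + k - 1L), , ] <- p$windows
    at <- at + k
  }
  structure(
    list(windows = windows,
         labels = unlist(lapply(parts, `[[`, "labels"), use.names = FALSE),
         subject_ids = unlist(lapply(parts, `[[`, "subject_ids"), use.names = FALSE),
         trial_ids = unlist(lapply(parts, `[[`, "trial_ids"), use.names = FALSE),
         window_index = unlist(lapply(parts, `[[`, "window_index"), use.names = FALSE),
         channel_names = ref$channel_names,
         sampling_rate = ref$sampling_rate),
    class = "windowed_dataset"
  )
}

#' Restrict and reorder a recording's channels
#'
#' @param rec An [recording()].
#' @param names Channel labels to keep, in the desired order (matched
#'   case-insensitively). Defaults to the 15-electrode montage of
#'   [emotion_channels()].
#' @return A recording containing exactly the requested channels in the
#'   requested order.
#' @export
select_channels <- function(rec, names = emotion_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  names <- toupper(names)
  pos <- match(names, rec$channel_names)
  if (anyNA(pos)) {
    stop(sprintf("unknown channel(s) %s; available: %s",
                 paste(names[is.na(pos)], collapse = ", "),
                 paste(rec$channel_names, collapse = ", ")))
  }
  rec$signal <- rec$signal[, pos, , drop = FALSE]
  rec$channel_names <- rec$channel_names[pos]
  rec
}

#' Fit feature-wise z-score parameters
#'
#' Means and standard deviations are estimated per column with the population
#' form (denominator N). Constant columns are flagged so that applying the
#' parameters maps them to zero rather than dividing by a vanishing sigma.
#'
#' @param features Numeric matrix (rows = observations) with at least 2 rows.
#' @return An object of class `zscore_params` with fields `mu` and `sigma`.
#' @export
zscore_fit <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 rows to fit z-score parameters")
  mu <- colMeans(features)
  centred <- sweep(features, 2, mu)
  sigma <- sqrt(colMeans(centred^2))
  structure(list(mu = mu, sigma = sigma), class = "zscore_params")
}

#' Apply fitted z-score parameters
#'
#' @param features Numeric matrix with the same number of columns as the fit.
#' @param params A [zscore_fit()] result.
#' @return Standardized matrix; columns whose fitted sigma is below the guard
#'   floor are mapped to 0.
#' @export
zscore_apply <- function(features, params) {
  stopifnot(inherits(params, "zscore_params"))
  features <- as.matrix(features)
  if (ncol(features) != length(params$mu)) {
    stop("feature dimension does not match the fitted parameters")
  }
  sigma <- pmax(params$sigma, .EPS)
  out <- sweep(sweep(features, 2, params$mu), 2, sigma, "/")
  degenerate <- params$sigma < .EPS
  if (any(degenerate)) out[, degenerate] <- 0
  out
}
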
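# Readers and writers: the portable plain-text recording dialect, the
# DEAP-shaped per-subject container, and the feature-table CSV.

# %.17g prints the shortest decimal that round-trips an IEEE double exactly,
# so the portable dialect is lossless.
.format_doubles <- function(x) sprintf("%.17g", x)

#' Write a recording in the portable plain-text dialect
#'
#' The dialect is a directory holding `meta.json` (subject id, sampling rate,
#' channel names, tensor dimensions), `signal.txt` (one line per trial-channel
#' pair, space-separated samples at full precision) and `ratings.txt`.
#'
#' @param rec An [recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording_portable <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(rec$signal)
  meta <- list(subject_id = rec$subject_id,
               sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               n_trials = d[1], n_channels = d[2], n_samples = d[3])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  con <- file(file.path(path, "signal.txt"), "w")
  on.exit(close(con), add = TRUE)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      writeLines(paste(.format_doubles(rec$signal[tr, ch, ]), collapse = " "),
                 con)
    }
  }
  writeLines(apply(rec$ratings, 1,
                   function(r) paste(.format_doubles(r), collapse = " ")),
             file.path(path, "ratings.txt"))
  invisible(path)
}

#' Read a recording written by [write_recording_portable()]
#'
#' @param path Directory produced by the writer.
#' @return An [recording()] identical (bit-exact) to the one written.
#' @export
read_recording_portable <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  lines <- readLines(file.path(path, "signal.txt"))
  stopifnot(length(lines) == meta$n_trials * meta$n_channels)
  signal <- array(NA_real_, c(meta$n_trials, meta$n_channels, meta$n_samples))
  i <- 1L
  for (tr in seq_len(meta$n_trials)) {
    for (ch in seq_len(meta$n_channels)) {
      signal[tr, ch, ] <- as.numeric(strsplit(lines[i], " ", fixed = TRUE)[[1]])
      i <- i + 1L
    }
  }
  rl <- readLines(file.path(path, "ratings.txt"))
  ratings <- do.call(rbind, lapply(strsplit(rl, " ", fixed = TRUE), as.numeric))
  recording(meta$subject_id, signal, as.numeric(meta$sampling_rate),
            meta$channel_names, ratings)
}

#' Write a recording as a DEAP-shaped per-subject container
#'
#' The DEAP preprocessed release stores, per subject, a serialized map with a
#' `data` array `[n_trials x n_channels x n_samples]` and a `labels` array
#' `[n_trials x 4]` of ratings. This writer produces the same structure in R's
#' native serialization (`.rds`).
#'
#' @param rec An [recording()].
#' @param path File path (conventionally `sXX.rds`).
#' @return `path`, invisibly.
#' @export
write_deap_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(list(data = rec$signal, labels = unname(rec$ratings)), path)
  invisible(path)
}

#' Read a DEAP-shaped per-subject container
#'
#' @param path File written by [write_deap_recording()] (a serialized map with
#'   `data` and `labels` entries).
#' @param subject_id Subject identifier to attach; defaults to the file name.
#' @param channel_names Electrode labels; defaults to the 32-channel Geneva
#'   order when the channel count matches, generic labels otherwise.
#' @param sampling_rate Samples per second (default 128, the preprocessed
#'   release's rate).
#' @return An [recording()].
#' @export
read_deap_recording <- function(path, subject_id = NULL, channel_names = NULL,
                                sampling_rate = 128) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels)) {
    stop("not a DEAP-shaped container: expected `data` and `labels` entries")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(channel_names) && dim(obj$data)[2] == 32) {
    channel_names <- deap_channel_names()
  }
  recording(subject_id, obj$data, sampling_rate, channel_names, obj$labels)
}

#' Export window provenance as a data frame / CSV
#'
#' @param wd A [slice_windows()] result.
#' @param path Optional CSV path; when given, the table is also written there.
#' @return Data frame with columns `subject_id`, `trial_id`, `window_index`,
#'   `label`.
#' @export
window_provenance <- function(wd, path = NULL) {
  stopifnot(inherits(wd, "windowed_dataset"))
  df <- data.frame(subject_id = wd$subject_ids, trial_id = wd$trial_ids,
                   window_index = wd$window_index, label = wd$labels,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Write a feature table to CSV
#'
#' Layout: provenance columns `subject_id`, `trial_id`, `window_index`,
#' `label`, followed by one column per named feature.
#'
#' @param ft A `feature_table` (see [extract_features()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(subject_id = ft$subject_ids, trial_id = ft$trial_ids,
                   window_index = ft$window_index, label = ft$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(ft$values, check.names = FALSE)
  write.csv(cbind(df, vals), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "trial_id", "window_index", "label")
  stopifnot(all(meta_cols %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  feature_table(vals, labels = df$label, subject_ids = df$subject_id,
                trial_ids = df$trial_id, window_index = df$window_index)
}
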
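# End-to-end driver: one configuration object, staged artifacts on disk.
# The thin command-line wrapper in inst/cli/eegfusion.R maps subcommands onto
# run_pipeline()'s stages.

#' Full pipeline configuration
#'
#' Every default equals the reference protocol: 40 s trim, 10 s windows,
#' valence threshold 5, the 15-electrode montage, MI fraction 0.5, 65 retained
#' features, KNN k = 41, SVM C = 0.7 / gamma = 0.015, 27/5 hold-out split.
#'
#' @param data_dir Directory of per-subject recordings (`NULL` to simulate).
#' @param dialect Input dialect, `"portable"` or `"deap"`.
#' @param synthetic A [synthetic_config()] used when `data_dir` is `NULL`.
#' @param trim_seconds,window_seconds,valence_threshold Preprocessing.
#' @param channels Channel montage.
#' @param recipe A [feature_recipe()].
#' @param protocol `"holdout"` or `"loso"`.
#' @param n_train,n_test Hold-out subject counts.
#' @param exclude Subjects excluded from LOSO.
#' @param fold A [fold_config()] (selection + fusion + classifiers).
#' @param out_dir Output directory for staged artifacts.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL,
                            dialect = c("portable", "deap"),
                            synthetic = synthetic_config(),
                            trim_seconds = 40, window_seconds = 10,
                            valence_threshold = 5,
                            channels = emotion_channels(),
                            recipe = feature_recipe(channels = channels),
                            protocol = c("holdout", "loso"),
                            n_train = 27, n_test = 5,
                            exclude = character(),
                            fold = fold_config(),
                            out_dir = tempfile("eegfusion_run_"),
                            seed = 1) {
  dialect <- match.arg(dialect)
  protocol <- match.arg(protocol)
  structure(list(data_dir = data_dir, dialect = dialect,
                 synthetic = synthetic, trim_seconds = trim_seconds,
                 window_seconds = window_seconds,
                 valence_threshold = valence_threshold, channels = channels,
                 recipe = recipe, protocol = protocol, n_train = n_train,
                 n_test = n_test, exclude = exclude, fold = fold,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

# Load or simulate the recordings named by the config.
.load_recordings <- function(config) {
  if (is.null(config$data_dir)) {
    return(generate_dataset(config$synthetic)$recordings)
  }
  if (config$dialect == "portable") {
    dirs <- list.dirs(config$data_dir, recursive = FALSE)
    if (!length(dirs)) stop("no portable recordings found; run `simulate` first")
    lapply(dirs, read_recording_portable)
  } else {
    files <- list.files(config$data_dir, pattern = "\\.rds$",
                        full.names = TRUE)
    if (!length(files)) stop("no DEAP containers found; run `simulate` first")
    # the container stores no electrode labels; supply the configured montage
    # when the channel count matches it (the 32-channel Geneva order is the
    # reader's own default otherwise)
    lapply(files, function(f) {
      rec <- read_deap_recording(f)
      if (dim(rec$signal)[2] == length(config$channels)) {
        rec$channel_names <- toupper(config$channels)
      }
      rec
    })
  }
}

#' Run the pipeline end to end
#'
#' Stages: load (or simulate) recordings; trim + window + montage selection;
#' feature extraction; protocol evaluation (selection and fusion are re-fit
#' inside every fold). Artifacts written under `config$out_dir`: the feature
#' table CSV, the window provenance CSV, and the evaluation report as JSON and
#' CSV.
#'
#' @param config A [pipeline_config()].
#' @param verbose Progress messages.
#' @return The `evaluation_report`, invisibly; its `feature_table` attribute
#'   holds the extracted features.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  say("loading recordings")
  recs <- .load_recordings(config)
  say("windowing %d subject(s)", length(recs))
  parts <- lapply(recs, function(rec) {
    rec <- select_channels(rec, config$channels)
    rec <- trim_to_last_seconds(rec, config$trim_seconds)
    slice_windows(rec, config$window_seconds, config$valence_threshold)
  })
  wd <- bind_windows(parts)
  write.csv(window_provenance(wd),
            file.path(config$out_dir, "windows.csv"), row.names = FALSE)
  say("extracting %d features from %d windows",
      length(feature_names(config$recipe)), dim(wd$windows)[1])
  ft <- extract_features(wd, config$recipe, verbose = verbose)
  write_feature_table(ft, file.path(config$out_dir, "features.csv"))
  say("evaluating (%s protocol)", config$protocol)
  report <- if (config$protocol == "loso") {
    loso_cv(ft, config$fold, exclude = config$exclude)
  } else {
    evaluate_holdout(ft, config$fold, config$n_train, config$n_test,
                     split_seed = config$seed)
  }
  write_report(report,
               json_path = file.path(config$out_dir, "report.json"),
               csv_path = file.path(config$out_dir, "report.csv"))
  attr(report, "feature_table") <- ft
  invisible(report)
}
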
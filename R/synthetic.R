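# DEAP-shaped synthetic EEG. Each trial is a sum of band-limited Gaussian
# oscillations (alpha/beta/gamma with log-normal per-trial power) over a 1/f
# background; positive-valence trials get elevated frontal beta power and an
# alpha left/right asymmetry shift, subjects carry multiplicative power
# offsets. Band-limited processes are synthesized in the frequency domain
# (complex-Gaussian spectrum under a smooth band mask), which is exactly a
# stationary Gaussian process band-limited to the band.

.FRONTAL <- c("AF3", "AF4", "F3", "F4", "F7", "F8", "FP1", "FP2")
.LEFT <- c("AF3", "F3", "F7", "FP1", "P7", "T7", "O1", "FC5", "FC1", "C3",
           "CP5", "CP1", "P3", "PO3")

#' Configuration of the synthetic EEG generator
#'
#' Defaults emulate the study shape: 32 subjects x 40 trials x 60 s at 128 Hz
#' on the 15-electrode montage, with moderate class-conditional frontal beta
#' elevation and alpha asymmetry for positive-valence trials.
#'
#' @param n_subjects,n_trials,trial_seconds,sampling_rate Dataset shape.
#' @param channels Channel labels (default [emotion_channels()]).
#' @param beta_effect Relative frontal beta-power elevation for
#'   positive-valence trials (0.6 = +60 %).
#' @param asym_effect Relative left/right alpha-power ratio shift for positive
#'   trials.
#' @param subject_sd Standard deviation of the subject-level log-normal power
#'   offset.
#' @param trial_sd Standard deviation of the per-trial log-normal band-power
#'   fluctuation.
#' @param band_amps Base amplitude of the alpha/beta/gamma oscillations
#'   (decreasing with frequency, consistent with the 1/f background).
#' @param pink_amp Amplitude of the 1/f background.
#' @param rating_margin Distance of the mean rating from the mid-scale point
#'   5.5 for each class.
#' @param rating_noise Standard deviation of the rating noise; at 0 the
#'   binarized ratings recover the true labels exactly.
#' @param bands Band definitions (default [default_bands()]).
#' @param seed Master seed; identical config + seed give identical data.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 32, n_trials = 40,
                             trial_seconds = 60, sampling_rate = 128,
                             channels = emotion_channels(),
                             beta_effect = 0.6, asym_effect = 0.3,
                             subject_sd = 0.3, trial_sd = 0.2,
                             band_amps = c(alpha = 1.0, beta = 0.6,
                                           gamma = 0.3),
                             pink_amp = 1.0, rating_margin = 2.0,
                             rating_noise = 0.5, bands = default_bands(),
                             seed = 1) {
  stopifnot(n_subjects >= 1, n_trials >= 1, trial_seconds > 0,
            sampling_rate > 0, beta_effect >= 0, asym_effect >= 0,
            subject_sd >= 0, trial_sd >= 0, pink_amp >= 0,
            rating_margin > 0, rating_noise >= 0)
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 trial_seconds = trial_seconds, sampling_rate = sampling_rate,
                 channels = toupper(channels), beta_effect = beta_effect,
                 asym_effect = asym_effect, subject_sd = subject_sd,
                 trial_sd = trial_sd, band_amps = band_amps,
                 pink_amp = pink_amp, rating_margin = rating_margin,
                 rating_noise = rating_noise, bands = bands, seed = seed),
            class = "synthetic_config")
}

# Smooth band mask over the rfft frequency grid (0.5 Hz raised-cosine edges).
.band_mask <- function(f, band, ramp = 0.5) {
  lo <- band[1]; hi <- band[2]
  m <- numeric(length(f))
  inside <- f >= lo + ramp & f <= hi - ramp
  m[inside] <- 1
  up <- f > lo - ramp & f < lo + ramp
  m[up] <- 0.5 * (1 + sin(pi * (f[up] - lo) / (2 * ramp)))
  dn <- f > hi - ramp & f < hi + ramp
  m[dn] <- 0.5 * (1 - sin(pi * (f[dn] - hi) / (2 * ramp)))
  m
}

# One trial-channel series from an amplitude spectrum with Gaussian
# coefficients. `amps` is a named vector of band amplitudes.
.synth_series <- function(n, fs, amps, pink_amp, bands) {
  nf <- n %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / n
  A <- numeric(nf)
  for (b in names(bands)) A <- A + amps[[b]] * .band_mask(f, bands[[b]])
  A <- A + pink_amp * c(0, 1 / sqrt(f[-1]))
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * A / sqrt(2)
  z[1] <- 0
  if (n %% 2 == 0) z[nf] <- complex(real = rnorm(1)) * A[nf]
  spec <- c(z, Conj(rev(z[2:(nf - 1)])))
  # scale so a unit-amplitude band yields O(10) microvolt fluctuations
  Re(fft(spec, inverse = TRUE)) / sqrt(n) * 10
}

#' Generate one synthetic subject
#'
#' Deterministic given `config` and `subject_index` (each subject draws from
#' its own derived seed, so subjects can be generated independently and in any
#' order).
#'
#' @param config A [synthetic_config()].
#' @param subject_index Subject number in `1..n_subjects`.
#' @return List with `recording` (an [recording()]) and `truth` (data frame of
#'   subject, trial, rating, true label).
#' @export
generate_recording <- function(config, subject_index) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- round(config$trial_seconds * config$sampling_rate)
  n_ch <- length(config$channels)
  frontal <- config$channels %in% .FRONTAL
  left <- config$channels %in% .LEFT
  with_seed(derive_seed(config$seed, subject_index), {
    subj_gain <- exp(rnorm(1, 0, config$subject_sd))
    labels <- rbinom(config$n_trials, 1, 0.5)
    ratings_v <- pmin(pmax(
      5.5 + (2 * labels - 1) * config$rating_margin +
        rnorm(config$n_trials, 0, config$rating_noise), 1), 9)
    ratings <- cbind(ratings_v,
                     matrix(runif(3 * config$n_trials, 1, 9),
                            config$n_trials, 3))
    signal <- array(NA_real_, c(config$n_trials, n_ch, n))
    for (tr in seq_len(config$n_trials)) {
      trial_gain <- exp(rnorm(length(config$band_amps), 0, config$trial_sd))
      names(trial_gain) <- names(config$band_amps)
      for (ch in seq_len(n_ch)) {
        amps <- config$band_amps * trial_gain * subj_gain
        if (labels[tr] == 1) {
          if (frontal[ch]) {
            amps[["beta"]] <- amps[["beta"]] * sqrt(1 + config$beta_effect)
            asym <- sqrt(sqrt(1 + config$asym_effect))
            amps[["alpha"]] <- amps[["alpha"]] *
              (if (left[ch]) asym else 1 / asym)
          }
        }
        signal[tr, ch, ] <- .synth_series(n, config$sampling_rate, amps,
                                          config$pink_amp * subj_gain,
                                          config$bands)
      }
    }
    rec <- recording(sprintf("s%02d", subject_index), signal,
                     config$sampling_rate, config$channels, ratings)
    list(recording = rec,
         truth = data.frame(subject_id = rec$subject_id,
                            trial = seq_len(config$n_trials),
                            rating = ratings_v, label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Generate the full synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `recordings` (list of [recording()]s) and `truth` (one
#'   data frame of subject, trial, rating, true label).
#' @export
generate_dataset <- function(config) {
  per <- lapply(seq_len(config$n_subjects), generate_recording,
                config = config)
  list(recordings = lapply(per, `[[`, "recording"),
       truth = do.call(rbind, lapply(per, `[[`, "truth")))
}

#' Trim, window and extract features from synthetic recordings in one call
#'
#' Convenience wrapper: per subject, keep the last `trim_seconds`, cut
#' `window_seconds` windows, then extract the feature battery.
#'
#' @param config A [synthetic_config()].
#' @param recipe A [feature_recipe()].
#' @param trim_seconds,window_seconds Preprocessing parameters (defaults 40/10).
#' @param verbose Progress messages.
#' @return A `feature_table`.
#' @export
synthetic_feature_table <- function(config, recipe = feature_recipe(),
                                    trim_seconds = 40, window_seconds = 10,
                                    verbose = FALSE) {
  parts <- lapply(seq_len(config$n_subjects), function(i) {
    rec <- generate_recording(config, i)$recording
    slice_windows(trim_to_last_seconds(rec, trim_seconds), window_seconds)
  })
  wd <- bind_windows(parts)
  extract_features(wd, recipe, verbose = verbose)
}

#' Write synthetic fixture files
#'
#' Writes every subject of a synthetic dataset in the requested dialect plus a
#' `truth.csv` (subject, trial, rating, true label).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param dialect `"portable"` (plain-text directory per subject) or `"deap"`
#'   (per-subject serialized container, see [write_deap_recording()]).
#' @return Character vector of the per-subject paths, invisibly.
#' @export
make_fixture_file <- function(config, dir, dialect = c("portable", "deap")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config)
  paths <- character(config$n_subjects)
  for (i in seq_along(ds$recordings)) {
    rec <- ds$recordings[[i]]
    if (dialect == "portable") {
      paths[i] <- file.path(dir, rec$subject_id)
      write_recording_portable(rec, paths[i])
    } else {
      paths[i] <- file.path(dir, paste0(rec$subject_id, ".rds"))
      write_deap_recording(rec, paths[i])
    }
  }
  write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(paths)
}

#' Configurations of the packaged synthetic benchmark
#'
#' The benchmark generates 8 subjects x 12 trials of 60 s: large enough for a
#' subject-disjoint LOSO comparison of the fusion variants against their
#' no-fusion baselines, small enough to run on one CPU in minutes. The
#' `effect` dataset carries a +60 % frontal beta-power elevation (and a
#' moderate alpha asymmetry) for positive-valence trials; the `null` dataset
#' has both effects switched off, so any LOSO accuracy away from chance there
#' flags information leakage. The fold configuration is the full default
#' pipeline: MI filter at fraction 0.5, SFFS to 65 features, all four fusion
#' variants and the three final classifiers.
#'
#' @param seed Master seed for generation, selection and classifier fits.
#' @return List with `effect` and `null` ([synthetic_config()]s) and `fold`
#'   (a [fold_config()]).
#' @export
benchmark_configs <- function(seed = 1) {
  list(
    effect = synthetic_config(n_subjects = 8, n_trials = 12,
                              beta_effect = 0.6, seed = seed),
    null = synthetic_config(n_subjects = 8, n_trials = 12,
                            beta_effect = 0, asym_effect = 0, seed = seed),
    fold = fold_config(mi_fraction = 0.5, target_dim = 65,
                       selector = "sffs", seed = seed)
  )
}
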
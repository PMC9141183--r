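# The 249-dimension feature battery: per-channel time-domain statistics,
# Butterworth band energies, asymmetry ratios, and nine nonlinear-dynamics
# descriptors, assembled by a configurable recipe.

#' Default frequency bands
#'
#' alpha 8-14 Hz, beta 14-30 Hz, gamma 30-47 Hz. Lower bands are omitted:
#' they contribute little to valence discrimination relative to these three.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(alpha = c(8, 14), beta = c(14, 30), gamma = c(30, 47))
}

#' Time-domain summary of a window
#'
#' Returns the mean, the population standard deviation, the mean absolute
#' first difference `mean(|x(t+1)-x(t)|)` and the mean absolute lag-2
#' difference `mean(|x(t+2)-x(t)|)`. With `diff_mode = "diff1_std"` the fourth
#' statistic is instead the population standard deviation of the first
#' difference (an alternative reading of the same four-feature family).
#'
#' @param x Numeric series of length >= 3.
#' @param diff_mode `"lag2_mean"` (default) or `"diff1_std"`.
#' @return Named numeric vector `mean`, `std`, `diff1_mean`, `diff2`.
#' @export
time_domain_stats <- function(x, diff_mode = c("lag2_mean", "diff1_std")) {
  diff_mode <- match.arg(diff_mode)
  n <- length(x)
  if (n < 3) stop("time_domain_stats needs at least 3 samples")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  d1 <- mean(abs(diff(x)))
  d2 <- if (diff_mode == "lag2_mean") {
    mean(abs(x[3:n] - x[1:(n - 2)]))
  } else {
    dd <- diff(x)
    sqrt(mean((dd - mean(dd))^2))
  }
  c(mean = mu, std = s, diff1_mean = d1, diff2_mean = d2)
}

# Cached Butterworth design for one band (zero-phase application doubles the
# effective order).
.butter_band <- function(band, fs, order = 4) {
  if (band[2] >= fs / 2) {
    stop(sprintf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band[2], fs / 2))
  }
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band edges")
  signal::butter(order, band / (fs / 2), type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param x Numeric series.
#' @param band `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order before the forward-backward pass (default 4).
#' @return Filtered series of the same length.
#' @export
bandpass <- function(x, band, fs, order = 4) {
  bf <- .butter_band(band, fs, order)
  as.numeric(signal::filtfilt(bf, x))
}

#' Band energy of a window
#'
#' Sum of squared samples of the band-passed signal (the time-domain
#' Parseval equivalent of summing the band's spectrum).
#'
#' @inheritParams bandpass
#' @return Non-negative scalar.
#' @export
band_energy <- function(x, band, fs, order = 4) {
  sum(bandpass(x, band, fs, order)^2)
}

#' Rational asymmetry between homologous electrodes
#'
#' @param p_left,p_right Band powers of a left-hemisphere electrode and its
#'   right-hemisphere homologue.
#' @return `p_left / p_right`, with the denominator floored at the guard
#'   epsilon so identically silent channels return a finite value.
#' @export
rasm <- function(p_left, p_right) {
  p_left / max(p_right, .EPS)
}

#' Beta/alpha band-energy ratio of a window
#'
#' @inheritParams bandpass
#' @param bands Band list as in [default_bands()] (needs `alpha` and `beta`).
#' @return `energy(beta) / energy(alpha)`, alpha energy floored at the guard
#'   epsilon.
#' @export
band_ratio <- function(x, fs, bands = default_bands(), order = 4) {
  band_energy(x, bands$beta, fs, order) /
    max(band_energy(x, bands$alpha, fs, order), .EPS)
}

#' Differential entropy of a window (Gaussian closed form)
#'
#' `0.5 * log(2 * pi * e * var(x))` in nats, with the sample variance floored
#' at the guard epsilon so constant windows stay finite.
#'
#' @param x Numeric series of length >= 2.
#' @return Scalar in nats.
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2) stop("differential_entropy needs at least 2 samples")
  0.5 * log(2 * pi * exp(1) * max(var(x), .EPS))
}

#' Sample entropy
#'
#' Negative log ratio of length-`m+1` to length-`m` template matches under the
#' Chebyshev distance, self-matches excluded. When no templates match at
#' either length the result is capped at `log(1e6)` instead of returning
#' infinity.
#'
#' @param x Numeric series of length > `m + 1`.
#' @param m Template length (default 2).
#' @param r Tolerance; defaults to `r_factor * sd(x)`.
#' @param r_factor Multiplier for the default tolerance (default 0.2).
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r = NULL, r_factor = 0.2) {
  if (is.null(r)) r <- r_factor * sd(x)
  if (r <= 0) return(.ENTROPY_CAP)
  cnt <- .entropy_counts_cpp(as.numeric(x), as.integer(m), r)
  if (cnt$B == 0 || cnt$A == 0) return(.ENTROPY_CAP)
  min(-log(cnt$A / cnt$B), .ENTROPY_CAP)
}

#' Approximate entropy
#'
#' `Phi^m(r) - Phi^(m+1)(r)` with self-matches included, Chebyshev distance.
#'
#' @inheritParams sample_entropy
#' @return Scalar (>= 0 up to estimator bias).
#' @export
approximate_entropy <- function(x, m = 2, r = NULL, r_factor = 0.2) {
  if (is.null(r)) r <- r_factor * sd(x)
  if (r <= 0) return(0)
  cnt <- .entropy_counts_cpp(as.numeric(x), as.integer(m), r)
  cnt$phi_m - cnt$phi_m1
}

# --- discrete wavelet transform (Daubechies-4, periodized) ------------------

# 8-tap Daubechies-4 decomposition filters.
.DB4_LO <- c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
             -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
             0.7148465705525415, 0.23037781330885523)
.DB4_HI <- c(-0.23037781330885523, 0.7148465705525415, -0.6308807679295904,
             -0.02798376941698385, 0.18703481171888114, 0.030841381835986965,
             -0.032883011666982945, -0.010597401784997278)

# One periodized analysis step; alignment matches the standard periodization
# convention (energy is conserved exactly).
.dwt_step <- function(x, filt) {
  N <- length(x)
  L <- length(filt)
  rf <- rev(filt)
  idx <- outer(2 * (0:(N %/% 2 - 1)) - 3, 0:(L - 1), "+") %% N + 1
  as.numeric(matrix(x[idx], ncol = L) %*% rf)
}

# Sub-band energies D1..Dlevels, A_levels of a periodized db4 pyramid.
.dwt_energies <- function(x, levels) {
  e <- numeric(levels + 1)
  a <- x
  for (j in seq_len(levels)) {
    if (length(a) < 2) stop("series too short for the requested wavelet depth")
    e[j] <- sum(.dwt_step(a, .DB4_HI)^2)
    a <- .dwt_step(a, .DB4_LO)
  }
  e[levels + 1] <- sum(a^2)
  e
}

#' Shannon entropy of a discrete distribution
#'
#' @param p Non-negative weights (normalized internally); `0 * log(0)` is 0.
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p[p > 0] / tot
  -sum(p * log(p))
}

#' Wavelet entropy of a window
#'
#' Shannon entropy of the relative sub-band energies of a `levels`-deep
#' Daubechies-4 decomposition (`levels` detail bands plus the final
#' approximation). Zero-energy windows return 0 by convention.
#'
#' @param x Numeric series with `length(x) >= 2^levels`.
#' @param levels Decomposition depth (default 5).
#' @return Scalar in `[0, log(levels + 1)]`.
#' @export
wavelet_entropy <- function(x, levels = 5) {
  if (length(x) < 2^levels) stop("series shorter than 2^levels")
  shannon_entropy(.dwt_energies(x, levels))
}

#' Largest Lyapunov exponent (Rosenstein small-data method)
#'
#' Time-delay embedding, nearest-neighbour search outside a Theiler window,
#' then a least-squares fit to the mean log divergence over the first
#' `fit_steps` steps. The slope is returned per sample.
#'
#' @param x Numeric series of length >= 200.
#' @param emb_dim Embedding dimension (default 10).
#' @param delay Embedding lag in samples (default 2).
#' @param theiler Temporal exclusion window for the neighbour search
#'   (default = `delay`).
#' @param fit_steps Number of divergence steps in the regression (default 30).
#' @param ref_stride Divergence is averaged over every `ref_stride`-th
#'   embedded point (default 3); neighbour candidates are always the full
#'   point set. 1 uses every point as a reference.
#' @return Scalar estimate; 0 for (near-)constant input.
#' @export
lyapunov_max <- function(x, emb_dim = 10, delay = 2, theiler = delay,
                         fit_steps = 30, ref_stride = 3) {
  if (length(x) < 200) stop("lyapunov_max needs at least 200 samples")
  if (sd(x) < .EPS) return(0)
  div <- .rosenstein_divergence_cpp(as.numeric(x), as.integer(emb_dim),
                                    as.integer(delay), as.integer(theiler),
                                    as.integer(fit_steps),
                                    as.integer(ref_stride))
  steps <- seq_along(div) - 1
  ok <- is.finite(div)
  if (sum(ok) < 2) return(0)
  unname(coef(lm(div[ok] ~ steps[ok]))[2])
}

#' Higuchi fractal dimension
#'
#' Least-squares slope of `log L(k)` versus `log(1/k)` over `k = 1..k_max`,
#' where `L(k)` is the mean normalized curve length at stride `k`. Reported
#' values are clipped to the theoretical range `[1, 2]`.
#'
#' @param x Numeric series with `length(x) >= 2 * k_max`.
#' @param k_max Maximum stride (default 10).
#' @return Scalar in `[1, 2]`.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  n <- length(x)
  if (n < 2 * k_max) stop("series too short for k_max")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / ((length(idx) - 1) * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2) return(1)
  slope <- unname(coef(lm(log(lk[ok]) ~ log(1 / seq_len(k_max))[ok]))[2])
  min(max(slope, 1), 2)
}

#' Hurst exponent by rescaled-range analysis
#'
#' The series is split into blocks for each dyadic block length
#' `min_block, 2*min_block, ..., <= n/2`; per length the rescaled range R/S is
#' averaged over blocks, and the Hurst exponent is the slope of
#' `log(mean R/S)` against `log(length)`. Reported values are clipped to
#' `[0, 1]`; constant series return 0.5.
#'
#' @param x Numeric series of length >= 64.
#' @param min_block Smallest block length of the dyadic ladder (default 16).
#' @return Scalar in `[0, 1]`.
#' @export
hurst_rs <- function(x, min_block = 16) {
  n <- length(x)
  if (n < 64) stop("hurst_rs needs at least 64 samples")
  if (sd(x) < .EPS) return(0.5)
  sizes <- min_block * 2^(0:floor(log2(n / 2 / min_block)))
  rs_mean <- vapply(sizes, function(l) {
    g <- n %/% l
    rs <- vapply(seq_len(g), function(b) {
      seg <- x[((b - 1) * l + 1):(b * l)]
      s <- sd(seg)
      if (s < .EPS) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs_mean) & rs_mean > 0
  if (sum(ok) < 2) return(0.5)
  h <- unname(coef(lm(log(rs_mean[ok]) ~ log(sizes)[ok]))[2])
  min(max(h, 0), 1)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal. First
#' differences stand in for derivatives.
#'
#' @param x Numeric series of length >= 3.
#' @return Named vector `mobility`, `complexity`; `(0, 0)` for constant input.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("hjorth needs at least 3 samples")
  v0 <- var(x)
  if (v0 < .EPS) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 < .EPS) return(c(mobility = mob, complexity = 0))
  v2 <- var(diff(d1))
  c(mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

# --- recipe and full extraction ---------------------------------------------

#' Feature recipe: what to compute, on which channels, with which parameters
#'
#' The default recipe reproduces the 249-dimension battery: 4 time-domain
#' statistics and 3 band energies per channel on the 15-electrode montage,
#' 4 beta/alpha ratios on the frontal channels, 4 rational-asymmetry features
#' (two frontal pairs x alpha/beta), one summed broadband power over the 7
#' non-frontal channels, and 9 nonlinear descriptors per channel computed on
#' the broadband window.
#'
#' @param channels Channel set (default [emotion_channels()]).
#' @param bands Band definitions as in [default_bands()].
#' @param families Feature families to include, a subset of
#'   `c("time", "band", "ratio", "asym", "power_sum", "nonlinear")`.
#' @param entropy_m,entropy_r_factor Template length and tolerance multiplier
#'   for sample/approximate entropy.
#' @param wavelet_levels Decomposition depth for wavelet entropy.
#' @param higuchi_kmax Maximum stride for the fractal dimension.
#' @param hurst_min_block Smallest block of the R/S ladder.
#' @param lyapunov List of Rosenstein parameters (`emb_dim`, `delay`,
#'   `theiler`, `fit_steps`).
#' @param ratio_channels Channels receiving a beta/alpha ratio feature.
#' @param asym_pairs List of `c(left, right)` electrode pairs for RASM.
#' @param asym_bands Band names used for RASM.
#' @param power_sum_channels Channels entering the summed broadband power.
#' @param diff_mode Fourth time-domain statistic, see [time_domain_stats()].
#' @param butter_order Butterworth design order.
#' @return An object of class `feature_recipe`.
#' @export
feature_recipe <- function(channels = emotion_channels(),
                           bands = default_bands(),
                           families = c("time", "band", "ratio", "asym",
                                        "power_sum", "nonlinear"),
                           entropy_m = 2, entropy_r_factor = 0.2,
                           wavelet_levels = 5, higuchi_kmax = 10,
                           hurst_min_block = 16,
                           lyapunov = list(emb_dim = 10, delay = 2,
                                           theiler = 2, fit_steps = 30),
                           ratio_channels = c("F3", "F4", "AF3", "AF4"),
                           asym_pairs = list(c("F3", "F4"), c("AF3", "AF4")),
                           asym_bands = c("alpha", "beta"),
                           power_sum_channels = c("P7", "T7", "O1", "P8",
                                                  "T8", "O2", "CZ"),
                           diff_mode = c("lag2_mean", "diff1_std"),
                           butter_order = 4) {
  channels <- toupper(channels)
  families <- match.arg(families, several.ok = TRUE)
  diff_mode <- match.arg(diff_mode)
  ratio_channels <- toupper(ratio_channels)
  power_sum_channels <- toupper(power_sum_channels)
  asym_pairs <- lapply(asym_pairs, toupper)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    stopifnot(length(b) == 2, b[1] > 0, b[1] < b[2])
  }
  used <- character(0)
  if ("ratio" %in% families) used <- c(used, ratio_channels)
  if ("asym" %in% families) used <- c(used, unlist(asym_pairs))
  if ("power_sum" %in% families) used <- c(used, power_sum_channels)
  missing <- setdiff(used, channels)
  if (length(missing)) {
    stop(sprintf("recipe references channels outside the channel set: %s",
                 paste(unique(missing), collapse = ", ")))
  }
  structure(
    list(channels = channels, bands = bands, families = families,
         entropy_m = entropy_m, entropy_r_factor = entropy_r_factor,
         wavelet_levels = wavelet_levels, higuchi_kmax = higuchi_kmax,
         hurst_min_block = hurst_min_block, lyapunov = lyapunov,
         ratio_channels = ratio_channels, asym_pairs = asym_pairs,
         asym_bands = asym_bands, power_sum_channels = power_sum_channels,
         diff_mode = diff_mode, butter_order = butter_order),
    class = "feature_recipe"
  )
}

.NONLINEAR_NAMES <- c("sampen", "apen", "de", "we", "lyap", "hfd", "hurst",
                      "mobility", "complexity")

#' Feature names produced by a recipe
#'
#' Names are deterministic: family blocks in a fixed order, channels in recipe
#' order within each block.
#'
#' @param recipe A [feature_recipe()].
#' @return Character vector; `length(feature_names(recipe))` is the feature
#'   count (249 for the default recipe).
#' @export
feature_names <- function(recipe = feature_recipe()) {
  stopifnot(inherits(recipe, "feature_recipe"))
  ch <- recipe$channels
  out <- character(0)
  if ("time" %in% recipe$families) {
    td4 <- if (recipe$diff_mode == "lag2_mean") "diff2_mean" else "diff1_std"
    out <- c(out, as.vector(outer(c("mean", "std", "diff1_mean", td4), ch,
                                  paste, sep = ".")))
  }
  if ("band" %in% recipe$families) {
    out <- c(out, as.vector(outer(paste0("energy_", names(recipe$bands)), ch,
                                  paste, sep = ".")))
  }
  if ("ratio" %in% recipe$families) {
    out <- c(out, paste0("beta_alpha_ratio.", recipe$ratio_channels))
  }
  if ("asym" %in% recipe$families) {
    for (pair in recipe$asym_pairs) {
      out <- c(out, paste0("rasm_", recipe$asym_bands, ".",
                           pair[1], "_", pair[2]))
    }
  }
  if ("power_sum" %in% recipe$families) out <- c(out, "power_sum")
  if ("nonlinear" %in% recipe$families) {
    out <- c(out, as.vector(outer(.NONLINEAR_NAMES, ch, paste, sep = ".")))
  }
  out
}

#' Construct a feature table
#'
#' @param values Numeric matrix `[n_windows x n_features]` with column names.
#' @param labels,subject_ids,trial_ids,window_index Per-window provenance.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels, subject_ids,
                          trial_ids = NULL, window_index = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(length(labels) == n, length(subject_ids) == n,
            !is.null(colnames(values)),
            !anyDuplicated(colnames(values)))
  structure(
    list(values = values, labels = as.integer(labels),
         subject_ids = as.character(subject_ids),
         trial_ids = trial_ids %||% rep(NA_integer_, n),
         window_index = window_index %||% rep(NA_integer_, n)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d windows x %d features, %d subject(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject_ids))))
  invisible(x)
}

#' Extract the full feature battery from a windowed dataset
#'
#' @param wd A [slice_windows()] / [bind_windows()] result whose channels
#'   cover the recipe's channel set.
#' @param recipe A [feature_recipe()]; the default yields 249 features.
#' @param verbose Print progress every 50 windows.
#' @return A `feature_table` with deterministic column order. Any non-finite
#'   value surviving the per-feature guards is replaced by 0 with a warning.
#' @export
extract_features <- function(wd, recipe = feature_recipe(), verbose = FALSE) {
  stopifnot(inherits(wd, "windowed_dataset"))
  ch_pos <- match(recipe$channels, wd$channel_names)
  if (anyNA(ch_pos)) {
    stop(sprintf("dataset lacks recipe channels: %s",
                 paste(recipe$channels[is.na(ch_pos)], collapse = ", ")))
  }
  fs <- wd$sampling_rate
  filters <- lapply(recipe$bands, .butter_band, fs = fs,
                    order = recipe$butter_order)
  names_out <- feature_names(recipe)
  n_win <- dim(wd$windows)[1]
  n_ch <- length(recipe$channels)
  band_names <- names(recipe$bands)
  need_band <- any(c("band", "ratio", "asym") %in% recipe$families)
  values <- matrix(NA_real_, n_win, length(names_out),
                   dimnames = list(NULL, names_out))
  for (w in seq_len(n_win)) {
    sigs <- lapply(seq_len(n_ch), function(j) wd$windows[w, ch_pos[j], ])
    # per-channel band energies, reused by the ratio/asymmetry features
    be <- NULL
    if (need_band) {
      be <- matrix(NA_real_, n_ch, length(band_names),
                   dimnames = list(recipe$channels, band_names))
      for (j in seq_len(n_ch)) {
        for (b in band_names) {
          be[j, b] <- sum(signal::filtfilt(filters[[b]], sigs[[j]])^2)
        }
      }
    }
    row <- numeric(0)
    if ("time" %in% recipe$families) {
      td <- vapply(sigs, time_domain_stats, numeric(4),
                   diff_mode = recipe$diff_mode)
      row <- c(row, as.vector(td))
    }
    if ("band" %in% recipe$families) row <- c(row, as.vector(t(be)))
    if ("ratio" %in% recipe$families) {
      rc <- match(recipe$ratio_channels, recipe$channels)
      row <- c(row, be[rc, "beta"] / pmax(be[rc, "alpha"], .EPS))
    }
    if ("asym" %in% recipe$families) {
      for (pair in recipe$asym_pairs) {
        li <- match(pair[1], recipe$channels)
        ri <- match(pair[2], recipe$channels)
        row <- c(row, vapply(recipe$asym_bands,
                             function(b) rasm(be[li, b], be[ri, b]),
                             numeric(1)))
      }
    }
    if ("power_sum" %in% recipe$families) {
      pc <- match(recipe$power_sum_channels, recipe$channels)
      row <- c(row, sum(vapply(pc, function(j) mean(sigs[[j]]^2), numeric(1))))
    }
    if ("nonlinear" %in% recipe$families) {
      nl <- vapply(sigs, function(x) {
        r_tol <- recipe$entropy_r_factor * sd(x)
        hj <- hjorth(x)
        c(sample_entropy(x, recipe$entropy_m, r_tol),
          approximate_entropy(x, recipe$entropy_m, r_tol),
          differential_entropy(x),
          wavelet_entropy(x, recipe$wavelet_levels),
          lyapunov_max(x, recipe$lyapunov$emb_dim, recipe$lyapunov$delay,
                       recipe$lyapunov$theiler, recipe$lyapunov$fit_steps),
          higuchi_fd(x, recipe$higuchi_kmax),
          hurst_rs(x, recipe$hurst_min_block),
          hj[["mobility"]], hj[["complexity"]])
      }, numeric(9))
      row <- c(row, as.vector(nl))
    }
    values[w, ] <- row
    if (verbose && w %% 50 == 0) {
      message(sprintf("extracted %d / %d windows", w, n_win))
    }
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    warning(sprintf("%d non-finite feature value(s) replaced by 0", sum(bad)))
    values[bad] <- 0
  }
  feature_table(values, wd$labels, wd$subject_ids, wd$trial_ids,
                wd$window_index)
}
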
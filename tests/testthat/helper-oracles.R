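# Brute-force oracles and small data constructors shared across tests.

# Naive O(n^2) sample entropy: template counting from the definition,
# self-matches excluded, N-m templates at both lengths.
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m  # templates that admit an (m+1)-extension
  count <- function(w) {
    cnt <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + w - 1)] - x[j:(j + w - 1)])) <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(log(1e6))
  min(-log(A / B), log(1e6))
}

# Naive approximate entropy from the Phi statistics, self-matches included.
naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(w) {
    N <- n - w + 1
    logs <- vapply(seq_len(N), function(i) {
      ci <- sum(vapply(seq_len(N), function(j) {
        max(abs(x[i:(i + w - 1)] - x[j:(j + w - 1)])) <= r
      }, logical(1)))
      log(ci / N)
    }, numeric(1))
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Small deterministic recording: trial t, channel c, sample s carries a
# recoverable code so window contents can be traced back.
coded_recording <- function(n_trials = 2, n_channels = 3, n_samples = 2560,
                            fs = 128, ratings = NULL,
                            channel_names = NULL) {
  sig <- array(0, c(n_trials, n_channels, n_samples))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_channels)) {
      sig[tr, ch, ] <- tr * 1e6 + ch * 1e4 + seq_len(n_samples)
    }
  }
  if (is.null(ratings)) {
    ratings <- cbind(seq(2, 8, length.out = n_trials),
                     matrix(5, n_trials, 3))
  }
  recording("sub1", sig, fs, channel_names, ratings)
}

# Labeled toy features: first `k_inf` columns shifted by the class label,
# remaining columns pure noise.
toy_features <- function(n = 80, p = 6, k_inf = 2, shift = 1.5, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  if (k_inf > 0) {
    X[, seq_len(k_inf)] <- X[, seq_len(k_inf)] +
      outer(y, rep(shift, k_inf))
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# Feature table with fake values and subject provenance (no EEG involved),
# for exercising the evaluation protocols cheaply.
fake_feature_table <- function(n_subjects = 4, per_subject = 30, p = 8,
                               k_inf = 2, shift = 1.5, seed = 7) {
  set.seed(seed)
  n <- n_subjects * per_subject
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * p), n, p)
  if (k_inf > 0) {
    X[, seq_len(k_inf)] <- X[, seq_len(k_inf)] + outer(y, rep(shift, k_inf))
  }
  colnames(X) <- paste0("f", seq_len(p))
  feature_table(X, labels = y,
                subject_ids = rep(sprintf("s%02d", seq_len(n_subjects)),
                                  each = per_subject))
}

# Logistic map series (fully chaotic regime, analytic Lyapunov exponent ln 2).
logistic_series <- function(n = 2000, x0 = 0.4) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}
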
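test_that("time-domain statistics match their defining formulas", {
  s <- time_domain_stats(c(1, 2, 3, 4))
  expect_equal(unname(s), c(2.5, sqrt(1.25), 1, 2))
  # hand evaluation: |2-0|+|1-2| over 2 terms; lag-2 |1-0| over 1 term
  s2 <- time_domain_stats(c(0, 2, 1))
  expect_equal(s2[["diff1_mean"]], 1.5)
  expect_equal(s2[["diff2_mean"]], 1)
  expect_equal(unname(time_domain_stats(rep(3.7, 10))), c(3.7, 0, 0, 0))
  expect_error(time_domain_stats(c(1, 2)), "3 samples")
  # alternative fourth statistic: sd of the first difference
  s3 <- time_domain_stats(c(0, 2, 1, 5), diff_mode = "diff1_std")
  d <- diff(c(0, 2, 1, 5))
  expect_equal(s3[[4]], sqrt(mean((d - mean(d))^2)))
})

test_that("Butterworth band-pass preserves in-band tones and kills out-of-band", {
  t <- 0:1279
  fs <- 128
  alpha <- c(8, 14)
  s10 <- sin(2 * pi * 10 * t / fs)
  out <- bandpass(s10, alpha, fs)
  expect_length(out, length(s10))
  mid <- 200:1080  # steady-state region away from filter edges
  expect_equal(sqrt(mean(out[mid]^2)) / sqrt(mean(s10[mid]^2)), 1,
               tolerance = 0.05)
  s50 <- sin(2 * pi * 50 * t / fs)
  expect_lt(sqrt(mean(bandpass(s50, alpha, fs)^2)) / sqrt(mean(s50^2)), 0.05)
  expect_identical(bandpass(numeric(1280), alpha, fs), numeric(1280))
  expect_error(bandpass(s10, c(30, 70), fs), "Nyquist")
})

test_that("band energy obeys Parseval on pure tones and is subadditive", {
  t <- 0:1279
  fs <- 128
  expect_equal(band_energy(numeric(1280), c(8, 14), fs), 0)
  s10 <- sin(2 * pi * 10 * t / fs)
  expect_equal(band_energy(s10, c(8, 14), fs), 640, tolerance = 0.05)
  set.seed(11)
  x <- rnorm(1280)
  tot <- sum(x^2)
  bsum <- sum(vapply(default_bands(), band_energy, numeric(1), x = x, fs = fs))
  expect_lte(bsum, tot)
})

test_that("asymmetry ratio and beta/alpha ratio behave on constructed tones", {
  expect_equal(rasm(2, 2), 1)
  expect_equal(rasm(3, 1.5), 2)
  t <- 0:1279
  fs <- 128
  x <- sin(2 * pi * 10 * t / fs) + 0.3 * sin(2 * pi * 20 * t / fs)
  expect_equal(rasm(band_energy(x, c(8, 14), fs), band_energy(x, c(8, 14), fs)),
               1)
  # 10 Hz tone: essentially no beta energy
  s10 <- sin(2 * pi * 10 * t / fs)
  expect_lt(band_ratio(s10, fs), 0.01)
  # 20 Hz tone: essentially no alpha energy
  s20 <- sin(2 * pi * 20 * t / fs)
  expect_gt(band_ratio(s20, fs), 100)
  # equal-power mixture splits evenly between the two bands
  expect_equal(band_ratio(s10 + s20, fs), 1, tolerance = 0.1)
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(2)
  x <- as.vector(scale(rnorm(500)))  # sample variance exactly 1
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  # inverted closed form: variance chosen so DE = 1
  x1 <- x * sqrt(exp(2) / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x1), 1, tolerance = 1e-12)
  # scaling law: doubling the amplitude adds ln 2
  expect_equal(differential_entropy(2 * x) - differential_entropy(x), log(2),
               tolerance = 1e-12)
  # constant input stays finite through the variance guard
  expect_true(is.finite(differential_entropy(rep(1, 100))))
})

test_that("wavelet entropy: closed forms, external oracle, bounds", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.2, 5)), log(5))
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  # frozen reference computed with an independent periodized db4 implementation
  t <- 0:255
  x <- sin(2 * pi * 5 * t / 128) + 0.3 * sin(2 * pi * 30 * t / 128 + 1)
  expect_equal(wavelet_entropy(x), 0.8742611, tolerance = 1e-6)
  expect_equal(wavelet_entropy(numeric(64)), 0)
  set.seed(3)
  for (i in 1:5) {
    we <- wavelet_entropy(rnorm(256))
    expect_gte(we, 0)
    expect_lte(we, log(6))
  }
  expect_error(wavelet_entropy(rnorm(16), levels = 5), "2\\^levels")
})

test_that("Hjorth parameters track frequency and spectral spread", {
  omega <- 0.1
  s <- sin(omega * (0:5000))
  hj <- hjorth(s)
  expect_equal(hj[["mobility"]], omega, tolerance = 0.02 * omega)
  expect_equal(hj[["complexity"]], 1, tolerance = 0.05)
  set.seed(4)
  noise <- rnorm(2000)
  s2 <- sin(omega * (0:1999)) * sd(noise) / sd(sin(omega * (0:1999)))
  expect_gt(hjorth(noise)[["mobility"]], hjorth(s2)[["mobility"]])
  expect_equal(unname(hjorth(rep(2, 100))), c(0, 0))
})

test_that("feature families scale as their formulas dictate", {
  set.seed(5)
  x <- rnorm(1280)
  a <- 2.5
  td1 <- time_domain_stats(x)
  tda <- time_domain_stats(a * x)
  expect_equal(unname(tda), unname(a * td1), tolerance = 1e-12)
  expect_equal(band_energy(a * x, c(8, 14), 128),
               a^2 * band_energy(x, c(8, 14), 128), tolerance = 1e-9)
  # tolerance r proportional to sd makes the entropies scale-invariant
  expect_equal(sample_entropy(a * x), sample_entropy(x), tolerance = 1e-12)
  expect_equal(approximate_entropy(a * x), approximate_entropy(x),
               tolerance = 1e-12)
})
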
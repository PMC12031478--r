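test_that("time-domain features match hand-computed values", {
  f <- time_features(c(1, -1, 2, -2))
  expect_equal(unname(f["mav"]), 1.5)
  expect_equal(unname(f["rms"]), sqrt(2.5))
  expect_equal(unname(f["variance"]), 2.5)
  expect_equal(unname(f["waveform_length"]), 9)
  expect_equal(unname(f["zcr"]), 3)

  g <- time_features(rep(5, 8))
  expect_equal(unname(g), c(5, 5, 0, 0, 0))
})

test_that("exact zero samples break zero crossings (strict product rule)", {
  expect_equal(unname(time_features(c(1, 0, -1))["zcr"]), 0)
  expect_equal(unname(time_features(c(1, -1, 0, 1, -1))["zcr"]), 2)
})

test_that("degenerate inputs error", {
  expect_error(time_features(1), "2 samples")
  expect_error(magnitude_spectrum(c(1, 2), fs = -1), "fs")
  sp <- magnitude_spectrum(rep(0, 16), 16)
  expect_error(freq_features(sp), "all-zero")
})

test_that("pure tones give closed-form spectral features", {
  fs <- 4096; n <- 4096
  t <- (0:(n - 1)) / fs
  y <- 0.7 * sin(2 * pi * 128 * t)
  expect_equal(unname(time_features(y)["rms"]), 0.7 / sqrt(2), tolerance = 1e-9)
  f <- freq_features(magnitude_spectrum(y, fs))
  expect_equal(unname(f), rep(128, 4), tolerance = 1e-9)
  # constant signal: all energy at DC
  spc <- magnitude_spectrum(rep(3, 64), 64)
  expect_equal(which.max(spc$magnitudes), 1L)
})

test_that("two equal tones resolve ties and weights as specified", {
  fs <- 2048; n <- 2048
  t <- (0:(n - 1)) / fs
  y <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  f <- freq_features(magnitude_spectrum(y, fs))
  expect_equal(unname(f["freq_centroid"]), 200, tolerance = 1e-6)
  expect_equal(unname(f["mean_freq"]), 200, tolerance = 1e-6)
  expect_equal(unname(f["dominant_freq"]), 100, tolerance = 1e-9)  # tie -> lowest
  expect_equal(unname(f["median_freq"]), 100, tolerance = 1e-9)
})

test_that("all nine features agree with naive-loop / naive-DFT oracles", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(16:512, 1)
    y <- stats::rnorm(n)
    expect_equal(time_features(y), oracle_time_features(y), tolerance = 1e-12)
    sp <- magnitude_spectrum(y, fs = 256)
    osp <- oracle_spectrum(y, fs = 256)
    expect_equal(sp$magnitudes, osp$magnitudes, tolerance = 1e-9)
    expect_equal(freq_features(sp),
                 oracle_freq_features(osp$freqs, osp$magnitudes),
                 tolerance = 1e-9)
  }
})

test_that("Parseval's identity holds for the one-sided spectrum", {
  set.seed(7)
  for (n in c(64, 255, 1024)) {
    y <- stats::rnorm(n)
    sp <- magnitude_spectrum(y, fs = n)
    w <- rep(2, length(sp$power))
    w[1] <- 1
    if (n %% 2 == 0) w[length(w)] <- 1  # Nyquist bin is unpaired
    expect_equal(sum(w * sp$power) / n^2, mean(y^2), tolerance = 1e-9)
  }
})

test_that("mav <= rms and variance identity hold on random signals", {
  set.seed(11)
  for (rep in 1:50) {
    y <- stats::rnorm(sample(16:256, 1), sd = runif(1, 0.1, 10))
    f <- time_features(y)
    expect_lte(f[["mav"]], f[["rms"]] + 1e-12)
    expect_equal(f[["variance"]], f[["rms"]]^2 - mean(y)^2, tolerance = 1e-9)
  }
})

test_that("self-concatenation changes features only where expected", {
  set.seed(13)
  y <- stats::rnorm(128)
  a <- time_features(y)
  b <- time_features(c(y, y))
  expect_equal(b[c("mav", "rms", "variance")], a[c("mav", "rms", "variance")],
               tolerance = 1e-12)
  expect_gte(b[["waveform_length"]], 2 * a[["waveform_length"]] - 2 * max(abs(y)))
  expect_lte(abs(b[["zcr"]] - 2 * a[["zcr"]]), 1)
})

test_that("extract_features orders EMG block before PZT block", {
  ds <- tiny_dataset(n_per_class = 1, seed = 8)
  tr <- ds[[1]]
  both <- extract_features(tr)
  expect_length(both, 18L)
  expect_identical(names(both)[1:9], paste0("emg_", silentspeech:::feature_names_1ch()))
  expect_identical(names(both)[10:18], paste0("pzt_", silentspeech:::feature_names_1ch()))
  expect_length(extract_features(tr, "emg"), 9L)
  # order of the channels argument does not change block order
  expect_identical(extract_features(tr, c("pzt", "emg")), both)
  expect_error(extract_features(tr, "ecg"), "unknown channel")
  expect_identical(extract_features(tr), both)  # deterministic
})
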
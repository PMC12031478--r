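test_that("generator config validates its inputs", {
  expect_error(generator_config(fs = -1), "fs")
  expect_error(generator_config(separability = 1.5), "separability")
  expect_error(generator_config(n_per_class = 0), "n_per_class")
  expect_error(generator_config(channel_coupling_mode = "bogus"))
})

test_that("templates are distinct, deterministic, and respect invariants", {
  cfg <- generator_config(separability = 1.0, seed = 1)
  tpls <- make_templates(cfg)
  expect_length(tpls, 8L)
  expect_identical(names(tpls), ssr_classes())
  # pairwise distinct in both channels at separability 1
  emg_sig <- vapply(tpls, function(t) paste(unlist(t$emg_bursts), collapse = ","), "")
  pzt_sig <- vapply(tpls, function(t) paste(unlist(t$pzt_tones), collapse = ","), "")
  expect_equal(anyDuplicated(emg_sig), 0L)
  expect_equal(anyDuplicated(pzt_sig), 0L)
  expect_identical(tpls, make_templates(cfg))
  # invariants: burst bands inside (0, Nyquist), events inside the trial
  for (t in tpls) {
    expect_true(all(t$emg_bursts$band_low < t$emg_bursts$band_high))
    expect_true(all(t$emg_bursts$band_high < cfg$fs / 2))
    expect_true(all(t$emg_bursts$onset + t$emg_bursts$duration <= cfg$duration + 1e-9))
    expect_true(all(t$pzt_tones$freq < 100))
  }
})

test_that("cross-channel mode reuses each single-channel motif across classes", {
  cfg <- generator_config(channel_coupling_mode = "cross_channel_only", seed = 1)
  tpls <- make_templates(cfg)
  emg_m <- vapply(tpls, `[[`, integer(1), "emg_motif")
  pzt_m <- vapply(tpls, `[[`, integer(1), "pzt_motif")
  expect_true(all(table(emg_m) >= 2))
  expect_true(all(table(pzt_m) >= 2))
  # the (EMG, PZT) pair is unique per class
  expect_equal(anyDuplicated(paste(emg_m, pzt_m)), 0L)
})

test_that("trials are deterministic given (seed, label, index) and sized fs*duration", {
  cfg <- tiny_config(jitter = 0)
  tpl <- make_templates(cfg)[["E"]]
  tr1 <- generate_trial(tpl, cfg, 3)
  tr2 <- generate_trial(tpl, cfg, 3)
  expect_identical(tr1$emg, tr2$emg)
  expect_identical(tr1$pzt, tr2$pzt)
  expect_length(tr1$emg, round(cfg$fs * cfg$duration))
  expect_length(tr1$pzt, length(tr1$emg))
  expect_false(identical(tr1$emg, generate_trial(tpl, cfg, 4)$emg))
})

test_that("trial synthesis is amplitude-linear", {
  cfg <- tiny_config(jitter = 0)
  tpl <- make_templates(cfg)[["T"]]
  tpl2 <- tpl
  tpl2$emg_bursts$amplitude <- 2 * tpl$emg_bursts$amplitude
  tpl2$pzt_tones$amplitude <- 2 * tpl$pzt_tones$amplitude
  a <- generate_trial(tpl, cfg, 1)
  b <- generate_trial(tpl2, cfg, 1)
  expect_equal(b$emg, 2 * a$emg, tolerance = 1e-12)
  expect_equal(b$pzt, 2 * a$pzt, tolerance = 1e-12)
})

test_that("datasets are balanced, shuffled deterministically, and byte-identical per config", {
  ds <- tiny_dataset(n_per_class = 4, seed = 5)
  expect_length(ds, 32L)
  expect_true(all(table(trial_labels(ds)) == 4L))
  expect_identical(ds, tiny_dataset(n_per_class = 4, seed = 5))
  expect_false(identical(trial_ids(ds), sort(trial_ids(ds))))  # shuffled
  ds1 <- tiny_dataset(n_per_class = 1, seed = 5)
  expect_setequal(trial_labels(ds1), ssr_classes())
})

test_that("inter-class feature distance grows with separability", {
  dist_at <- function(s) {
    ds <- generate_dataset(generator_config(fs = 2048, duration = 0.125,
                                            n_per_class = 6, separability = s,
                                            seed = 42))
    f <- featurize_dataset(ds)
    xy <- silentspeech:::feature_xy(f)
    xs <- scale(xy$x)
    xs[!is.finite(xs)] <- 0
    centers <- t(vapply(levels(xy$y), function(lv) colMeans(xs[xy$y == lv, , drop = FALSE]),
                        numeric(ncol(xs))))
    mean(dist(centers))
  }
  d <- vapply(c(0.2, 0.6, 1.0), dist_at, numeric(1))
  expect_true(all(diff(d) >= 0))
})
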
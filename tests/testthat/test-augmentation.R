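test_that("SMOTE synthetics are convex combinations of same-class points", {
  x <- rbind(c(0, 0), c(1, 2))
  out <- smote_oversample(x, c("a", "a"), target_per_class = 6, k_neighbors = 1,
                          seed = 3)
  synth <- out$x[out$synthetic, , drop = FALSE]
  expect_equal(nrow(synth), 4L)
  # every synthetic point lies on the segment [p, q], componentwise between
  lam <- synth[, 1] / 1
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(synth[, 2], 2 * lam, tolerance = 1e-12)
})

test_that("SMOTE of an identical-point class reproduces the point; counts balance", {
  x <- matrix(1.5, nrow = 6, ncol = 3)
  y <- rep("a", 6)
  out <- smote_oversample(x, y, target_per_class = 10, seed = 1)
  expect_true(all(out$x == 1.5))
  expect_equal(nrow(out$x), 10L)

  set.seed(4)
  xb <- matrix(stats::rnorm(8 * 100 * 4), ncol = 4)
  yb <- rep(ssr_classes(), each = 100)
  big <- smote_oversample(xb, yb, target_per_class = 200, seed = 2)
  expect_equal(nrow(big$x), 1600L)
  expect_true(all(table(big$y) == 200L))
  expect_error(smote_oversample(xb[1:3, ], yb[1:3], k_neighbors = 5), "fewer than")
  expect_error(smote_oversample(xb, yb, target_per_class = 50), ">=")
})

test_that("SMOTE class-conditional mean stays near the original class mean", {
  set.seed(9)
  x <- matrix(stats::rnorm(40 * 3, mean = 5), 40, 3)
  y <- rep("a", 40)
  out <- smote_oversample(x, y, target_per_class = 1040, seed = 7)
  synth <- out$x[out$synthetic, ]
  se <- apply(x, 2, stats::sd) / sqrt(nrow(synth))
  expect_true(all(abs(colMeans(synth) - colMeans(x)) < 6 * se + 0.05))
})

test_that("hang, gauss, noise and downsample modify only their window", {
  x <- c(0, 1, 2, 3, 4, 5, 6, 7)
  h <- augment_local(x, "hang", window = c(3, 6))
  expect_equal(as.numeric(h), c(0, 1, 2, 2, 2, 5, 6, 7))
  expect_equal(as.numeric(augment_local(rep(2, 32), "gauss")), rep(2, 32))
  expect_equal(as.numeric(augment_local(rep(2, 32), "noise")), rep(2, 32))
  ramp <- seq(0, 1, length.out = 64)
  d <- augment_local(ramp, "downsample", window = c(5, 40))
  expect_equal(as.numeric(d), ramp, tolerance = 1e-9)  # linear interp is exact on lines
  set.seed(1)
  z <- stats::rnorm(64)
  n <- augment_local(z, "noise", window = c(10, 20))
  expect_identical(n[-(10:19)], z[-(10:19)])
  expect_error(augment_local(1:4, "hang"), "8 samples")
})

test_that("global operators follow their printed forms", {
  x <- c(0, 1, 2, 3, 4, 5, 10, 2)
  set.seed(2)
  s <- augment_global(x, "scale")
  ratio <- as.numeric(s)[x != 0] / x[x != 0]
  expect_equal(stats::sd(ratio), 0, tolerance = 1e-12)
  expect_true(ratio[1] >= 0.95 && ratio[1] <= 1.05)

  # circular shift convention, checked via the recorded draw
  x64 <- as.numeric(1:64)
  set.seed(3)
  repeat {
    sh <- augment_global(x64, "shift_x")
    if (attr(sh, "aug_params")$shift != 0) break
  }
  k <- attr(sh, "aug_params")$shift
  expect_equal(as.numeric(sh), x64[((seq_along(x64) - 1 + k) %% 64) + 1])

  expect_equal(as.numeric(augment_global(rep(0, 16), "slope")), rep(0, 16))
  set.seed(4)
  sy <- augment_global(x, "shift_y")
  expect_equal(stats::sd(as.numeric(sy) - x), 0, tolerance = 1e-12)
})

test_that("drawn parameters respect the printed bounds over many seeded draws", {
  set.seed(99)
  x <- stats::rnorm(128)
  for (i in 1:200) {
    sl <- attr(augment_global(x, "slope"), "aug_params")$rise
    expect_true(sl >= 0 && sl < 10 * stats::sd(x))
    sx <- attr(augment_global(x, "shift_x"), "aug_params")$shift
    expect_lte(abs(sx), 0.05 * 128)
    sy <- attr(augment_global(x, "shift_y"), "aug_params")$offset
    expect_lte(abs(sy), 0.05 * diff(range(x)))
    sc <- attr(augment_global(x, "scale"), "aug_params")$scale
    expect_true(sc >= 0.95 && sc <= 1.05)
    fr <- attr(augment_local(x, "downsample"), "aug_params")$fraction
    expect_true(fr >= 0.01 && fr <= 0.25)
    nr <- attr(augment_local(x, "noise"), "aug_params")$noise_range
    expect_true(nr[1] >= 0 && nr[2] <= 1)
  }
})

test_that("composition is seeded, length-preserving, and the empty plan is the identity", {
  x <- sin(seq(0, 20, length.out = 200))
  empty <- augmentation_plan(seed = 1, p_include = 0)
  expect_length(empty$operators, 0L)
  expect_equal(as.numeric(compose(x, empty)), x)

  plan <- augmentation_plan(seed = 5, p_include = 1)
  expect_setequal(plan$operators, signal_operator_names())
  a <- compose(x, plan)
  expect_length(a, length(x))
  expect_identical(as.numeric(a), as.numeric(compose(x, plan)))
  # different seeds give varied outputs
  outs <- vapply(1:25, function(s) sum(compose(x, augmentation_plan(seed = s))),
                 numeric(1))
  expect_gt(length(unique(outs)), 1L)
  expect_error(augmentation_plan(operators = "warp"), "unknown operator")
})

test_that("augment_trials keeps originals and appends length-preserving copies", {
  ds <- tiny_dataset(n_per_class = 1, seed = 3)[1:4]
  aug <- augment_trials(ds, n_copies = 2, seed = 8)
  expect_length(aug, 12L)
  expect_identical(aug[1:4], ds)
  expect_true(all(vapply(aug, function(t) length(t$emg), integer(1)) ==
                  length(ds[[1]]$emg)))
  expect_match(aug[[5]]$trial_id, "_aug1$")
})
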
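# The backward passes are pinned by central finite differences through the
# full forward computation; everything else checks architectural contracts.

numeric_gradcheck <- function(net, inputs, y, n_per_param = 3, eps = 1e-6) {
  lossfn <- function(net) {
    fe <- silentspeech:::nn_embed(net, inputs, training = TRUE)
    logits <- net$params[["head.W"]] %*% fe$emb + net$params[["head.b"]]
    silentspeech:::softmax_ce(logits, y)$loss
  }
  fe <- silentspeech:::nn_embed(net, inputs, training = TRUE)
  sm <- silentspeech:::softmax_ce(
    net$params[["head.W"]] %*% fe$emb + net$params[["head.b"]], y)
  dEmb <- crossprod(net$params[["head.W"]], sm$dlogits)
  grads <- c(silentspeech:::nn_embed_backward(net, fe$cache, dEmb),
             list("head.W" = tcrossprod(sm$dlogits, fe$emb),
                  "head.b" = rowSums(sm$dlogits)))
  worst <- 0
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    expect_false(is.null(g), label = paste("gradient present for", nm))
    for (i in sample(length(net$params[[nm]]), min(n_per_param, length(net$params[[nm]])))) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
      nn <- net; nn$params[[nm]][i] <- nn$params[[nm]][i] - eps
      num <- (lossfn(np) - lossfn(nn)) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])))
    }
  }
  worst
}

test_that("analytic gradients match finite differences (single FEN + CN)", {
  set.seed(1)
  spec <- fen_spec(2L, channels = c(3L, 4L), kernel = 3L,
                   pool_lengths = c(8L, 4L), input_length = 16L)
  net <- silentspeech:::nn_init(spec, cn_spec(6L, 5L), head = "softmax",
                                n_classes = 3L, seed = 2)
  inputs <- list(x = array(stats::rnorm(1 * 24 * 4), c(1, 24, 4)))
  expect_lt(numeric_gradcheck(net, inputs, c(1L, 2L, 3L, 1L)), 1e-5)
})

test_that("analytic gradients match finite differences (PMLDF fusion)", {
  set.seed(2)
  sp <- pmldf_spec(
    list(a = fen_spec(2L, c(3L, 4L), 3L, c(8L, 4L), input_length = 20L),
         b = fen_spec(2L, c(2L, 3L), 3L, c(8L, 4L), input_length = NULL)),
    fusion_channels = c(3L, 4L), fusion_kernel = 3L,
    fusion_pool_lengths = c(6L, 4L))
  net <- silentspeech:::nn_init(sp, cn_spec(6L, 5L), head = "softmax",
                                n_classes = 3L, seed = 3)
  inputs <- list(a = array(stats::rnorm(1 * 24 * 4), c(1, 24, 4)),
                 b = array(stats::rnorm(1 * 16 * 4), c(1, 16, 4)))
  expect_lt(numeric_gradcheck(net, inputs, c(1L, 2L, 3L, 1L)), 1e-5)
})

test_that("adaptive pooling makes output shapes input-length invariant", {
  spec <- tiny_fen(2L)
  out1 <- fen_forward(matrix(stats::rnorm(48 * 3), 48, 3), spec, seed = 4)
  out2 <- fen_forward(matrix(stats::rnorm(32 * 3), 32, 3), spec, seed = 4)
  expect_identical(lapply(out1$outputs, dim), lapply(out2$outputs, dim))
  expect_equal(dim(out1$outputs[[2]]), c(6L, 8L, 3L))
  expect_length(out1$outputs, 2L)
  expect_error(fen_forward(matrix(0, 4, 2), spec), "shorter")
})

test_that("zero input stays zero through inference with unit statistics", {
  spec <- tiny_fen(2L)
  out <- fen_forward(matrix(0, 48, 2), spec, training = FALSE, seed = 5)
  for (l in 1:2) expect_equal(max(abs(out$outputs[[l]])), 0)
})

test_that("the scheduler follows lr0 * gamma^floor(epochs/step) exactly", {
  expect_identical(scheduled_lr(1e-3, 20), 1e-3 * 0.992^2)
  expect_identical(scheduled_lr(1e-3, 9), 1e-3)
  expect_identical(scheduled_lr(1e-3, 10), 1e-3 * 0.992)
  expect_identical(scheduled_lr(0.05, 70, step = 10, gamma = 0.992),
                   0.05 * 0.992^7)
  expect_error(train_config(scheduler_gamma = 1.5), "gamma")
  expect_error(train_config(patience = 0), "patience")
})

test_that("training stops within patience of the best epoch", {
  ds <- tiny_dataset(n_per_class = 5, seed = 6)
  sp <- stratified_split(ds, seed = 1)
  tr <- subset_trials(ds, sp$train)
  va <- subset_trials(ds, sp$validation)
  m <- cnn_train(tr, va, channels = "emg", spec = tiny_fen(2L),
                 config = train_config(lr = 0, patience = 1, max_epochs = 50,
                                       batch_size = 16, seed = 2))
  expect_lte(m$epochs_trained, m$best_epoch + 1L)
  expect_lt(m$epochs_trained, 50L)
})

test_that("siamese loss is zero iff samples coincide with their reference and clear the margin", {
  R <- diag(4)[, 1:3]                   # three orthogonal references
  emb <- R                              # each sample equals its class reference
  out <- silentspeech:::siamese_loss_grad(emb, 1:3, R, margin = 0)
  expect_equal(out$loss, 0, tolerance = 1e-12)
  expect_equal(max(abs(out$dEmb)), 0, tolerance = 1e-12)
  # a sample aligned with a wrong reference is penalized
  out2 <- silentspeech:::siamese_loss_grad(R[, c(2, 2, 3)], 1:3, R, margin = 0)
  expect_gt(out2$loss, 0)
})

test_that("the shared-weight embedder gives identical embeddings on both branches", {
  ds <- tiny_dataset(n_per_class = 1, seed = 7)[1:3]
  spec <- tiny_fen(2L)
  net <- silentspeech:::nn_init(spec, cn_spec(8L, 8L), head = "siamese",
                                n_classes = 8L, seed = 1)
  ins <- silentspeech:::nn_inputs(ds, "emg")
  e1 <- silentspeech:::nn_embed(net, ins, training = FALSE)$emb
  e2 <- silentspeech:::nn_embed(net, ins, training = FALSE)$emb
  expect_identical(e1, e2)
})

test_that("few-shot training returns a complete reference set and usable predictions", {
  ds <- tiny_dataset(n_per_class = 5, seed = 9)
  sp <- stratified_split(ds, seed = 2)
  tr <- subset_trials(ds, sp$train)
  va <- subset_trials(ds, sp$validation)
  m <- snn_train(tr, va, channels = "pzt", spec = tiny_fen(2L),
                 cn = cn_spec(16L, 16L),
                 config = train_config(max_epochs = 2, batch_size = 16, seed = 5),
                 n_ref = 2)
  expect_s3_class(m$refs, "ssr_embedding_set")
  expect_equal(ncol(m$refs$vectors), 8L)
  expect_true(all(is.finite(m$refs$vectors)))
  expect_true(all(sqrt(colSums(m$refs$vectors^2)) > 0))
  expect_true(all(m$refs$provenance %in% trial_ids(tr)))
  pred <- snn_predict(m, va)
  expect_s3_class(pred, "factor")
  expect_length(pred, length(va))
  expect_setequal(levels(pred), ssr_classes())
  # a trial whose embedding equals a reference vector classifies as that class:
  # score the references against themselves
  R <- m$refs$vectors
  Cs <- crossprod(R / rep(sqrt(colSums(R^2)), each = nrow(R)))
  expect_equal(apply(Cs, 2, which.max), seq_len(8), ignore_attr = TRUE)
  # references must cover every class
  tr_noA <- tr[trial_labels(tr) != "A"]
  expect_error(snn_train(tr_noA, va, channels = "pzt", spec = tiny_fen(2L),
                         config = train_config(max_epochs = 1, seed = 1)),
               "A")
})

test_that("PMLDF accepts heterogeneous lengths and scales to three streams", {
  sp2 <- pmldf_spec(list(emg = tiny_fen(2L), pzt = tiny_fen(2L)),
                    fusion_channels = c(4L, 4L), fusion_kernel = 3L,
                    fusion_pool_lengths = c(8L, 4L))
  ins <- list(emg = array(stats::rnorm(64 * 3), c(1, 64, 3)),
              pzt = array(stats::rnorm(40 * 3), c(1, 40, 3)))
  out <- pmldf_forward(ins, sp2, seed = 6)
  expect_equal(dim(out$fused), c(4L, 4L, 3L))
  expect_equal(nrow(out$embedding), 256L)

  sp3 <- pmldf_spec(list(emg = tiny_fen(2L), pzt = tiny_fen(2L),
                         imu = tiny_fen(2L)),
                    fusion_channels = c(4L, 4L), fusion_kernel = 3L,
                    fusion_pool_lengths = c(8L, 4L))
  ins3 <- c(ins, list(imu = array(stats::rnorm(24 * 3), c(1, 24, 3))))
  out3 <- pmldf_forward(ins3, sp3, seed = 6)
  expect_equal(dim(out3$fused), dim(out$fused))

  ins_bad <- ins
  ins_bad$pzt <- ins_bad$pzt[, , 1:2, drop = FALSE]
  expect_error(pmldf_forward(ins_bad, sp2, seed = 6), "batch size")
  expect_error(pmldf_forward(list(emg = ins$emg), sp2, seed = 6), "stream names")
})

test_that("cnn training is reproducible given the seed", {
  ds <- tiny_dataset(n_per_class = 5, seed = 8)
  sp <- stratified_split(ds, seed = 3)
  tr <- subset_trials(ds, sp$train)
  va <- subset_trials(ds, sp$validation)
  cfg <- train_config(lr = 1e-3, max_epochs = 3, batch_size = 16, seed = 11)
  m1 <- cnn_train(tr, va, channels = "pzt", spec = tiny_fen(2L), config = cfg)
  m2 <- cnn_train(tr, va, channels = "pzt", spec = tiny_fen(2L), config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, va), predict(m2, va))
})
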
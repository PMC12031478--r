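# Low-level neural building blocks with hand-derived backward passes.
#
# Batches are arrays laid out [channels, length, batch]; a 1D convolution is
# computed as k kernel-slice matrix products ([C_out, C_in] %*% [C_in, L*N]),
# which keeps everything inside BLAS. Correctness of every backward pass is
# pinned by finite-difference gradient checks in the test suite.

# Adaptive average pooling: output bin i averages input positions
# [floor((i-1)L/Lout)+1, ceiling(iL/Lout)], so output length is fixed
# regardless of input length (bins may overlap when Lout does not divide L).
adaptive_pool_forward <- function(X, L_out) {
  L <- dim(X)[2L]
  if (L == L_out) return(list(Y = X, cache = list(identity = TRUE)))
  list(Y = pool_fwd_cpp(X, L_out), cache = list(identity = FALSE, L = L))
}

adaptive_pool_backward <- function(dY, cache) {
  if (isTRUE(cache$identity)) return(dY)
  pool_bwd_cpp(dY, cache$L)
}

linear_forward <- function(X, W, b) {
  list(Y = W %*% X + b, cache = list(X = X))
}

linear_backward <- function(dY, W, cache) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, cache$X), db = rowSums(dY))
}

# Softmax cross-entropy over columns; y is an integer class vector.
softmax_ce <- function(logits, y) {
  K <- nrow(logits); n <- ncol(logits)
  z <- logits - rep(apply(logits, 2L, max), each = K)
  p <- exp(z)
  p <- p * rep(1 / colSums(p), each = K)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-300)))
  dlogits <- p
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# Adam optimizer over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Scheduled learning rate after a number of completed epochs
#'
#' Step decay: the learning rate is multiplied by `gamma` every `step` epochs,
#' so after `k * step` completed epochs it equals `lr0 * gamma^k` exactly.
#'
#' @param lr0 Initial learning rate.
#' @param epochs_completed Number of epochs already completed.
#' @param step Scheduler step in epochs (default 10).
#' @param gamma Decay factor per step (default 0.992).
#' @export
scheduled_lr <- function(lr0, epochs_completed, step = 10L, gamma = 0.992) {
  lr0 * gamma^(epochs_completed %/% step)
}
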
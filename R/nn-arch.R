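# Network architectures.
#
# FEN: stacked blocks of conv1d -> tanh -> batchnorm -> adaptive average
# pooling; because every block ends in adaptive pooling to a spec'd length,
# output shapes depend only on the spec, never on the input length.
# CN: two fully connected layers reducing the flattened FEN output to a
# 256-dimensional embedding.
# PMLDF: one FEN per sensor stream; a central fusion network whose layer l
# consumes the channel-concatenation of its own previous output and every
# stream's layer-l output, all adaptively pooled to a common length.

#' Feature Extraction Network specification
#'
#' @param n_layers Number of conv-tanh-batchnorm-pool blocks (default 7).
#' @param channels Output channels per layer; default doubles from 16 capped
#'   at 64.
#' @param kernel Odd convolution kernel size (default 7).
#' @param pool_lengths Adaptive-pooling output length per layer; default
#'   halves down to a final length of 16. Must be non-increasing.
#' @param input_length Working length the raw input is adaptively pooled to
#'   before the first convolution (default 1024). This front pooling makes
#'   every downstream shape independent of the recorded length and sampling
#'   rate; `NULL` disables it.
#' @return An `ssr_fen_spec`.
#' @export
fen_spec <- function(n_layers = 7L, channels = NULL, kernel = 7L,
                     pool_lengths = NULL, input_length = 1024L) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("`n_layers` must be >= 1", call. = FALSE)
  if (kernel %% 2L != 1L) stop("`kernel` must be odd", call. = FALSE)
  if (is.null(channels)) channels <- pmin(16L * 2L^(0:(n_layers - 1L)), 64L)
  if (is.null(pool_lengths)) pool_lengths <- 16L * 2L^((n_layers - 1L):0)
  channels <- as.integer(channels); pool_lengths <- as.integer(pool_lengths)
  if (length(channels) != n_layers || length(pool_lengths) != n_layers) {
    stop("`channels` and `pool_lengths` must have length `n_layers`", call. = FALSE)
  }
  if (any(diff(pool_lengths) > 0)) {
    stop("`pool_lengths` must be non-increasing", call. = FALSE)
  }
  structure(list(n_layers = n_layers, channels = channels, kernel = kernel,
                 pool_lengths = pool_lengths,
                 input_length = if (is.null(input_length)) NULL else as.integer(input_length)),
            class = "ssr_fen_spec")
}

#' Classification Network specification
#'
#' Two consecutive fully connected layers reducing the flattened feature maps
#' to the embedding.
#'
#' @param embedding_dim Embedding dimension (default 256).
#' @param hidden_dim Width of the first fully connected layer (default 256).
#' @export
cn_spec <- function(embedding_dim = 256L, hidden_dim = 256L) {
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim)),
            class = "ssr_cn_spec")
}

#' PMLDF multi-sensor fusion specification
#'
#' @param streams Named list of one [fen_spec()] per sensor stream (>= 1;
#'   with a single stream PMLDF degenerates to that stream's FEN).
#' @param fusion_channels Channels per fusion layer; default mirrors the FEN
#'   default for `min` stream depth layers.
#' @param fusion_kernel Odd kernel for fusion convolutions.
#' @param fusion_pool_lengths Pooling schedule of the fusion network.
#' @return An `ssr_pmldf_spec`.
#' @export
pmldf_spec <- function(streams, fusion_channels = NULL, fusion_kernel = 7L,
                       fusion_pool_lengths = NULL) {
  if (!length(streams) || is.null(names(streams)) || any(names(streams) == "")) {
    stop("`streams` must be a named list of fen_spec objects", call. = FALSE)
  }
  for (s in streams) stopifnot(inherits(s, "ssr_fen_spec"))
  n_f <- min(vapply(streams, function(s) s$n_layers, integer(1)))
  if (is.null(fusion_channels)) fusion_channels <- pmin(16L * 2L^(0:(n_f - 1L)), 64L)
  if (is.null(fusion_pool_lengths)) fusion_pool_lengths <- 16L * 2L^((n_f - 1L):0)
  if (length(fusion_channels) > n_f) {
    stop("fusion depth cannot exceed the shallowest stream FEN", call. = FALSE)
  }
  structure(list(streams = streams, n_fusion = length(fusion_channels),
                 fusion_channels = as.integer(fusion_channels),
                 fusion_kernel = as.integer(fusion_kernel),
                 fusion_pool_lengths = as.integer(fusion_pool_lengths)),
            class = "ssr_pmldf_spec")
}

xavier_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_fen_params <- function(spec, prefix, c_in, params, state) {
  for (l in seq_len(spec$n_layers)) {
    c_out <- spec$channels[l]
    k <- spec$kernel
    params[[sprintf("%s.conv%d.W", prefix, l)]] <-
      xavier_init(c(c_out, c_in, k), c_in * k, c_out * k)
    params[[sprintf("%s.conv%d.b", prefix, l)]] <- numeric(c_out)
    params[[sprintf("%s.bn%d.gamma", prefix, l)]] <- rep(1, c_out)
    params[[sprintf("%s.bn%d.beta", prefix, l)]] <- numeric(c_out)
    state[[sprintf("%s.bn%d.mean", prefix, l)]] <- numeric(c_out)
    state[[sprintf("%s.bn%d.var", prefix, l)]] <- rep(1, c_out)
    c_in <- c_out
  }
  list(params = params, state = state)
}

# Initialize a full network. `arch` is "single" (one FEN + CN) or "pmldf".
nn_init <- function(spec, cn = cn_spec(), head = c("softmax", "siamese"),
                    n_classes = 8L, seed = 1L) {
  head <- match.arg(head)
  with_seed(substream_seed(seed, 7777L), {
    params <- list(); state <- list()
    if (inherits(spec, "ssr_fen_spec")) {
      arch <- "single"
      streams <- list(x = spec)
      ini <- init_fen_params(spec, "x", 1L, params, state)
      params <- ini$params; state <- ini$state
      flat_dim <- spec$channels[spec$n_layers] * spec$pool_lengths[spec$n_layers]
      fusion <- NULL
    } else if (inherits(spec, "ssr_pmldf_spec")) {
      arch <- "pmldf"
      streams <- spec$streams
      for (nm in names(streams)) {
        ini <- init_fen_params(streams[[nm]], nm, 1L, params, state)
        params <- ini$params; state <- ini$state
      }
      n_f <- spec$n_fusion
      for (l in seq_len(n_f)) {
        c_in <- sum(vapply(streams, function(s) s$channels[l], integer(1))) +
          if (l > 1L) spec$fusion_channels[l - 1L] else 0L
        c_out <- spec$fusion_channels[l]
        k <- spec$fusion_kernel
        params[[sprintf("fusion.conv%d.W", l)]] <-
          xavier_init(c(c_out, c_in, k), c_in * k, c_out * k)
        params[[sprintf("fusion.conv%d.b", l)]] <- numeric(c_out)
        params[[sprintf("fusion.bn%d.gamma", l)]] <- rep(1, c_out)
        params[[sprintf("fusion.bn%d.beta", l)]] <- numeric(c_out)
        state[[sprintf("fusion.bn%d.mean", l)]] <- numeric(c_out)
        state[[sprintf("fusion.bn%d.var", l)]] <- rep(1, c_out)
      }
      flat_dim <- spec$fusion_channels[n_f] * spec$fusion_pool_lengths[n_f]
      fusion <- spec
    } else {
      stop("`spec` must be an ssr_fen_spec or ssr_pmldf_spec", call. = FALSE)
    }
    params[["cn.fc1.W"]] <- xavier_init(c(cn$hidden_dim, flat_dim), flat_dim, cn$hidden_dim)
    params[["cn.fc1.b"]] <- numeric(cn$hidden_dim)
    params[["cn.fc2.W"]] <- xavier_init(c(cn$embedding_dim, cn$hidden_dim),
                                        cn$hidden_dim, cn$embedding_dim)
    params[["cn.fc2.b"]] <- numeric(cn$embedding_dim)
    if (head == "softmax") {
      params[["head.W"]] <- xavier_init(c(n_classes, cn$embedding_dim),
                                        cn$embedding_dim, n_classes)
      params[["head.b"]] <- numeric(n_classes)
    }
    list(arch = arch, streams = streams, fusion = fusion, cn = cn, head = head,
         n_classes = as.integer(n_classes), params = params, state = state,
         flat_dim = flat_dim)
  })
}

# One FEN block: conv -> tanh -> batchnorm -> adaptive pool (fused in C++).
fen_block_forward <- function(X, net, prefix, l, spec, training) {
  p <- net$params; s <- net$state
  L_out <- if (prefix == "fusion") net$fusion$fusion_pool_lengths[l]
           else spec$pool_lengths[l]
  f <- block_fwd_cpp(X, p[[sprintf("%s.conv%d.W", prefix, l)]],
                     p[[sprintf("%s.conv%d.b", prefix, l)]],
                     p[[sprintf("%s.bn%d.gamma", prefix, l)]],
                     p[[sprintf("%s.bn%d.beta", prefix, l)]],
                     s[[sprintf("%s.bn%d.mean", prefix, l)]],
                     s[[sprintf("%s.bn%d.var", prefix, l)]],
                     training, 0.1, 1e-5, L_out)
  list(Y = f$Y,
       cache = list(X = X, tanh_out = f$T, xhat = f$xhat,
                    inv = as.numeric(f$inv), training = training),
       state_updates = stats::setNames(
         list(as.numeric(f$new_mean), as.numeric(f$new_var)),
         c(sprintf("%s.bn%d.mean", prefix, l), sprintf("%s.bn%d.var", prefix, l))))
}

fen_block_backward <- function(dY, net, prefix, l, cache, grads, need_dx = TRUE) {
  b <- block_bwd_cpp(dY, cache$X, net$params[[sprintf("%s.conv%d.W", prefix, l)]],
                     cache$tanh_out, cache$xhat, cache$inv,
                     net$params[[sprintf("%s.bn%d.gamma", prefix, l)]],
                     cache$training, need_dx)
  grads[[sprintf("%s.bn%d.gamma", prefix, l)]] <- as.numeric(b$dgamma)
  grads[[sprintf("%s.bn%d.beta", prefix, l)]] <- as.numeric(b$dbeta)
  grads[[sprintf("%s.conv%d.W", prefix, l)]] <- b$dW
  grads[[sprintf("%s.conv%d.b", prefix, l)]] <- as.numeric(b$db)
  list(dX = if (need_dx) b$dX else NULL, grads = grads)
}

#' Forward pass through a Feature Extraction Network
#'
#' Returns all per-layer (post-pooling) feature maps; multi-layer fusion taps
#' every one of them. Output shapes are fixed by the spec, independent of the
#' input length.
#'
#' @param X Input batch, array `[1, length, batch]` (or a matrix
#'   `[length, batch]`, promoted automatically).
#' @param spec An [fen_spec()].
#' @param net Optional initialized network (from the internal constructor);
#'   freshly initialized from `seed` when omitted.
#' @param training Use batch statistics (TRUE) or running statistics.
#' @param seed Seed for the fresh initialization.
#' @return List with `outputs` (one `[channels, pooled length, batch]` array
#'   per layer), `caches`, and `state_updates`.
#' @export
fen_forward <- function(X, spec, net = NULL, training = FALSE, seed = 1L) {
  if (is.matrix(X)) X <- array(X, c(1L, nrow(X), ncol(X)))
  if (is.null(net)) net <- nn_init(spec, head = "softmax", seed = seed)
  if (dim(X)[2L] < spec$pool_lengths[spec$n_layers]) {
    stop("input shorter than the final pooled length", call. = FALSE)
  }
  prefix <- if (net$arch == "single") "x" else stop("use pmldf_forward for fusion nets")
  stream_forward(X, net, prefix, spec, training)
}

# Internal per-stream forward usable for any prefix.
stream_forward <- function(X, net, prefix, spec, training) {
  outputs <- vector("list", spec$n_layers)
  caches <- vector("list", spec$n_layers)
  updates <- list()
  input_cache <- NULL
  cur <- X
  if (!is.null(spec$input_length)) {
    ip <- adaptive_pool_forward(X, spec$input_length)
    cur <- ip$Y
    input_cache <- ip$cache
  }
  for (l in seq_len(spec$n_layers)) {
    blk <- fen_block_forward(cur, net, prefix, l, spec, training)
    outputs[[l]] <- blk$Y
    caches[[l]] <- blk$cache
    updates[names(blk$state_updates)] <- blk$state_updates
    cur <- blk$Y
  }
  list(outputs = outputs, caches = caches, input_cache = input_cache,
       state_updates = updates)
}

# Backward through a stream given per-layer output gradients (`extra[[l]]`
# from fusion taps and/or the downstream consumer of the final output).
stream_backward <- function(net, prefix, spec, caches, extra, grads,
                            input_cache = NULL) {
  dCur <- NULL
  for (l in rev(seq_len(spec$n_layers))) {
    dOut <- extra[[l]]
    if (!is.null(dCur)) dOut <- if (is.null(dOut)) dCur else dOut + dCur
    if (is.null(dOut)) next
    # the gradient w.r.t. the raw input is never consumed, so layer 1 of a
    # sensor stream skips its dX
    bb <- fen_block_backward(dOut, net, prefix, l, caches[[l]], grads,
                             need_dx = l > 1L)
    grads <- bb$grads
    dCur <- bb$dX
  }
  if (!is.null(dCur) && !is.null(input_cache)) {
    dCur <- adaptive_pool_backward(dCur, input_cache)
  }
  list(dX = dCur, grads = grads)
}

cn_forward <- function(net, flat) {
  f1 <- linear_forward(flat, net$params[["cn.fc1.W"]], net$params[["cn.fc1.b"]])
  h <- tanh(f1$Y)
  f2 <- linear_forward(h, net$params[["cn.fc2.W"]], net$params[["cn.fc2.b"]])
  list(emb = f2$Y, cache = list(f1 = f1$cache, h = h, f2 = f2$cache))
}

cn_backward <- function(net, cache, dEmb, grads) {
  l2 <- linear_backward(dEmb, net$params[["cn.fc2.W"]], cache$f2)
  grads[["cn.fc2.W"]] <- l2$dW; grads[["cn.fc2.b"]] <- l2$db
  dH <- l2$dX * (1 - cache$h^2)
  l1 <- linear_backward(dH, net$params[["cn.fc1.W"]], cache$f1)
  grads[["cn.fc1.W"]] <- l1$dW; grads[["cn.fc1.b"]] <- l1$db
  list(dFlat = l1$dX, grads = grads)
}

#' PMLDF forward pass
#'
#' Each sensor stream traverses its own FEN; fusion layer `l` consumes the
#' channel-concatenation of the previous fusion output and every stream's
#' layer-`l` output, with all inputs adaptively pooled to a common temporal
#' length, so streams of different lengths (different sampling rates) fuse
#' without shape constraints.
#'
#' @param inputs Named list of input batches (`[1, length, batch]` arrays or
#'   `[length, batch]` matrices), names matching the spec's streams. Batch
#'   sizes must agree.
#' @param spec An [pmldf_spec()].
#' @param net Optional initialized network; freshly initialized when omitted.
#' @param training Batch-statistics mode.
#' @param seed Seed for fresh initialization.
#' @return List with `fused` (final fusion feature map), `embedding`
#'   (`[256, batch]` after the CN head), `stream_outputs`, and caches.
#' @export
pmldf_forward <- function(inputs, spec, net = NULL, training = FALSE, seed = 1L) {
  if (is.null(net)) net <- nn_init(spec, head = "softmax", seed = seed)
  inputs <- lapply(inputs, function(X) {
    if (is.matrix(X)) array(X, c(1L, nrow(X), ncol(X))) else X
  })
  if (!setequal(names(inputs), names(spec$streams))) {
    stop("input names must match the spec's stream names", call. = FALSE)
  }
  ns <- vapply(inputs, function(X) dim(X)[3L], integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all streams must carry the same batch size", call. = FALSE)
  }
  sf <- list(); updates <- list()
  for (nm in names(spec$streams)) {
    sf[[nm]] <- stream_forward(inputs[[nm]], net, nm, spec$streams[[nm]], training)
    updates[names(sf[[nm]]$state_updates)] <- sf[[nm]]$state_updates
  }
  n_f <- spec$n_fusion
  fpl <- spec$fusion_pool_lengths
  fusion_caches <- vector("list", n_f)
  prev <- NULL
  for (l in seq_len(n_f)) {
    target_len <- if (l == 1L) 2L * fpl[1L] else fpl[l - 1L]
    tap_caches <- list(); parts <- list()
    if (l > 1L) parts$prev <- prev
    for (nm in names(spec$streams)) {
      tp <- adaptive_pool_forward(sf[[nm]]$outputs[[l]], target_len)
      tap_caches[[nm]] <- tp$cache
      parts[[nm]] <- tp$Y
    }
    if (l > 1L) {
      pp <- adaptive_pool_forward(prev, target_len)  # identity: prev is at fpl[l-1]
      parts$prev <- pp$Y
    }
    Xcat <- do.call(abind_channels, parts)
    blk <- fen_block_forward(Xcat, net, "fusion", l, NULL, training)
    updates[names(blk$state_updates)] <- blk$state_updates
    fusion_caches[[l]] <- list(block = blk$cache, taps = tap_caches,
                               part_channels = vapply(parts, function(p) dim(p)[1L], integer(1)),
                               part_names = names(parts))
    prev <- blk$Y
  }
  flat <- matrix(prev, net$flat_dim, dim(prev)[3L])
  cn <- cn_forward(net, flat)
  list(fused = prev, embedding = cn$emb,
       stream_outputs = lapply(sf, `[[`, "outputs"),
       cache = list(streams = lapply(sf, `[[`, "caches"),
                    stream_inputs = lapply(sf, `[[`, "input_cache"),
                    fusion = fusion_caches, cn = cn$cache,
                    fused_dim = dim(prev)),
       state_updates = updates, net = net)
}

# Concatenate arrays [C_i, L, N] along the channel dimension.
abind_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  C_total <- sum(vapply(parts, function(p) dim(p)[1L], integer(1)))
  out <- array(0, c(C_total, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    C <- dim(p)[1L]
    out[at + seq_len(C), , ] <- p
    at <- at + C
  }
  out
}

pmldf_backward <- function(net, cache, dEmb) {
  grads <- list()
  cb <- cn_backward(net, cache$cn, dEmb, grads)
  grads <- cb$grads
  spec <- net$fusion
  n_f <- spec$n_fusion
  dPrev <- array(cb$dFlat, cache$fused_dim)
  n_streams <- length(spec$streams)
  extra <- lapply(spec$streams, function(s) vector("list", s$n_layers))
  for (l in rev(seq_len(n_f))) {
    fc <- cache$fusion[[l]]
    bb <- fen_block_backward(dPrev, net, "fusion", l, fc$block, grads)
    grads <- bb$grads
    dXcat <- bb$dX
    at <- 0L
    dPrev <- NULL
    for (i in seq_along(fc$part_names)) {
      nm <- fc$part_names[i]
      C <- fc$part_channels[i]
      dPart <- dXcat[at + seq_len(C), , , drop = FALSE]
      at <- at + C
      if (nm == "prev") {
        dPrev <- dPart                    # tap pooling of prev is the identity
      } else {
        dTap <- adaptive_pool_backward(dPart, fc$taps[[nm]])
        cur <- extra[[nm]][[l]]
        extra[[nm]][[l]] <- if (is.null(cur)) dTap else cur + dTap
      }
    }
  }
  for (nm in names(spec$streams)) {
    sb <- stream_backward(net, nm, spec$streams[[nm]], cache$streams[[nm]],
                          extra[[nm]], grads, cache$stream_inputs[[nm]])
    grads <- sb$grads
  }
  grads
}

# Unified embedding forward/backward over both architectures.
nn_embed <- function(net, inputs, training = FALSE) {
  if (net$arch == "single") {
    X <- inputs[[1L]]
    if (is.matrix(X)) X <- array(X, c(1L, nrow(X), ncol(X)))
    spec <- net$streams[[1L]]
    sf <- stream_forward(X, net, "x", spec, training)
    last <- sf$outputs[[spec$n_layers]]
    flat <- matrix(last, net$flat_dim, dim(last)[3L])
    cn <- cn_forward(net, flat)
    list(emb = cn$emb,
         cache = list(kind = "single", stream = sf$caches,
                      input_cache = sf$input_cache, cn = cn$cache,
                      last_dim = dim(last)),
         state_updates = sf$state_updates)
  } else {
    pf <- pmldf_forward(inputs, net$fusion, net = net, training = training)
    list(emb = pf$embedding, cache = c(pf$cache, kind = "pmldf"),
         state_updates = pf$state_updates)
  }
}

nn_embed_backward <- function(net, cache, dEmb) {
  if (identical(cache$kind, "single")) {
    grads <- list()
    cb <- cn_backward(net, cache$cn, dEmb, grads)
    grads <- cb$grads
    spec <- net$streams[[1L]]
    extra <- vector("list", spec$n_layers)
    extra[[spec$n_layers]] <- array(cb$dFlat, cache$last_dim)
    stream_backward(net, "x", spec, cache$stream, extra, grads,
                    cache$input_cache)$grads
  } else {
    pmldf_backward(net, cache, dEmb)
  }
}
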
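# Network training: minibatch Adam with step-decay learning-rate schedule
# (gamma every `step` epochs), best-validation checkpointing, and early
# stopping on validation accuracy. Two heads share the loop: a softmax
# classifier (CNN) and a Siamese cosine-similarity head classifying against
# per-class reference feature vectors (few-shot SNN).

#' Training configuration
#'
#' @param lr Initial learning rate.
#' @param scheduler_step Epochs between learning-rate decays (default 10).
#' @param scheduler_gamma Multiplicative decay per step (default 0.992).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 150).
#' @param max_epochs Upper bound on epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed; batching, initialization and reference draws all
#'   derive from it.
#' @return An `ssr_train_config`.
#' @export
train_config <- function(lr = 1e-3, scheduler_step = 10L, scheduler_gamma = 0.992,
                         patience = 150L, max_epochs = 500L, batch_size = 32L,
                         seed = 1L) {
  if (scheduler_gamma <= 0 || scheduler_gamma > 1) {
    stop("`scheduler_gamma` must lie in (0, 1]", call. = FALSE)
  }
  if (patience < 1L) stop("`patience` must be >= 1", call. = FALSE)
  structure(list(lr = lr, scheduler_step = as.integer(scheduler_step),
                 scheduler_gamma = scheduler_gamma, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ssr_train_config")
}

# Per-trial standardized input arrays, one [1, L, N] array per channel.
nn_inputs <- function(trials, channels) {
  out <- list()
  for (ch in channels) {
    sigs <- lapply(trials, function(tr) {
      y <- tr[[ch]]
      s <- stats::sd(y)
      (y - mean(y)) / if (s < 1e-12) 1 else s
    })
    L <- length(sigs[[1L]])
    out[[ch]] <- array(unlist(sigs), c(1L, L, length(sigs)))
  }
  out
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(A) A[, , idx, drop = FALSE])
}

# Mean reference embedding per class (inference mode).
compute_refs <- function(net, inputs_train, ref_idx, labels, provenance = NULL) {
  d <- nrow(net$params[["cn.fc2.W"]])
  R <- matrix(0, d, length(labels), dimnames = list(NULL, labels))
  for (c_i in seq_along(labels)) {
    fe <- nn_embed(net, slice_inputs(inputs_train, ref_idx[[labels[c_i]]]),
                   training = FALSE)
    R[, c_i] <- rowMeans(fe$emb)
  }
  if (any(!is.finite(R)) || any(sqrt(colSums(R^2)) < 1e-12)) {
    stop("degenerate reference feature vector (zero norm or non-finite)",
         call. = FALSE)
  }
  structure(list(vectors = R, labels = labels, provenance = provenance),
            class = "ssr_embedding_set")
}

#' @export
print.ssr_embedding_set <- function(x, ...) {
  cat(sprintf("<ssr_embedding_set: %d classes, %d-dim reference vectors>\n",
              ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

# Cosine-similarity few-shot loss:
#   L_i = (1 - cos(f_i, r_{y_i})) + (1/(K-1)) * sum_{c != y_i} max(0, cos(f_i, r_c) - m)
siamese_loss_grad <- function(emb, y_int, R, margin = 0) {
  d <- nrow(emb); n <- ncol(emb); K <- ncol(R)
  fn <- sqrt(colSums(emb^2)); fn[fn < 1e-12] <- 1e-12
  Fn <- emb * rep(1 / fn, each = d)
  rn <- sqrt(colSums(R^2))
  Rn <- R * rep(1 / rn, each = d)
  Cs <- crossprod(Fn, Rn)                 # n x K cosine similarities
  pos_idx <- cbind(seq_len(n), y_int)
  neg <- pmax(Cs - margin, 0)
  neg[pos_idx] <- 0
  loss <- mean(1 - Cs[pos_idx]) + mean(rowSums(neg) / (K - 1))
  G <- (neg > 0) / (K - 1)
  G[pos_idx] <- -1
  G <- G / n
  s <- rowSums(G * Cs)
  dEmb <- (Rn %*% t(G) - Fn * rep(s, each = d)) * rep(1 / fn, each = d)
  list(loss = loss, dEmb = dEmb)
}

nn_scores <- function(net, inputs, refs = NULL) {
  fe <- nn_embed(net, inputs, training = FALSE)
  if (net$head == "softmax") {
    net$params[["head.W"]] %*% fe$emb + net$params[["head.b"]]
  } else {
    d <- nrow(fe$emb)
    fn <- sqrt(colSums(fe$emb^2))
    if (any(fn < 1e-12)) stop("zero-norm embedding: cannot score", call. = FALSE)
    R <- refs$vectors
    rn <- sqrt(colSums(R^2))
    t(crossprod(fe$emb * rep(1 / fn, each = d), R * rep(1 / rn, each = d)))
  }
}

# Core loop shared by CNN and SNN training.
train_network <- function(net, inputs_train, y_train, inputs_val, y_val,
                          config, ref_idx = NULL, margin = 0) {
  labels <- levels(y_train)
  y_int <- as.integer(y_train)
  yv_int <- as.integer(factor(y_val, levels = labels))
  n <- length(y_int)
  opt <- adam_init(net$params)
  best <- list(acc = -Inf, epoch = 0L)
  history <- list()
  refs <- NULL
  ref_ids <- if (!is.null(ref_idx)) unlist(ref_idx) else NULL
  for (epoch in seq_len(config$max_epochs)) {
    lr <- scheduled_lr(config$lr, epoch - 1L, config$scheduler_step,
                       config$scheduler_gamma)
    if (net$head == "siamese") {
      refs <- compute_refs(net, inputs_train, ref_idx, labels, ref_ids)
    }
    ord <- with_seed(substream_seed(config$seed, 31L, epoch), sample.int(n))
    batch_starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (b0 in batch_starts) {
      sel <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      bin <- slice_inputs(inputs_train, sel)
      fe <- nn_embed(net, bin, training = TRUE)
      net$state[names(fe$state_updates)] <- fe$state_updates
      if (net$head == "softmax") {
        logits <- net$params[["head.W"]] %*% fe$emb + net$params[["head.b"]]
        sm <- softmax_ce(logits, y_int[sel])
        loss <- sm$loss
        dEmb <- crossprod(net$params[["head.W"]], sm$dlogits)
        head_grads <- list("head.W" = tcrossprod(sm$dlogits, fe$emb),
                           "head.b" = rowSums(sm$dlogits))
      } else {
        sl <- siamese_loss_grad(fe$emb, y_int[sel], refs$vectors, margin)
        loss <- sl$loss
        dEmb <- sl$dEmb
        head_grads <- list()
      }
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d: non-finite loss", epoch),
             call. = FALSE)
      }
      grads <- c(nn_embed_backward(net, fe$cache, dEmb), head_grads)
      st <- adam_step(net$params, grads, opt, lr)
      net$params <- st$params
      opt <- st$opt
      epoch_loss <- epoch_loss + loss * length(sel)
    }
    if (net$head == "siamese") {
      refs <- compute_refs(net, inputs_train, ref_idx, labels, ref_ids)
    }
    scores <- nn_scores(net, inputs_val, refs)
    val_acc <- mean(apply(scores, 2L, which.max) == yv_int)
    history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                   train_loss = epoch_loss / n, val_acc = val_acc)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, params = net$params,
                   state = net$state, refs = refs)
    }
    if (epoch - best$epoch >= config$patience) break
  }
  net$params <- best$params
  net$state <- best$state
  list(net = net, refs = best$refs, best_epoch = best$epoch,
       best_val_acc = best$acc, history = do.call(rbind, history),
       epochs_trained = epoch)
}

resolve_spec <- function(spec, channels) {
  if (!is.null(spec)) return(spec)
  if (length(channels) == 1L) fen_spec()
  else pmldf_spec(stats::setNames(lapply(channels, function(ch) fen_spec()),
                                  channels))
}

build_nn_model <- function(fit, spec, channels, config, head) {
  structure(list(net = fit$net, spec = spec, channels = channels,
                 labels = NULL,
                 refs = fit$refs, history = fit$history,
                 best_epoch = fit$best_epoch, best_val_acc = fit$best_val_acc,
                 epochs_trained = fit$epochs_trained, config = config,
                 head = head),
            class = "ssr_nn_model")
}

#' Train a CNN classifier on raw signals
#'
#' Feature Extraction Network + Classification Network + softmax over the
#' eight classes, minimizing cross-entropy with Adam, a step-decay
#' learning-rate schedule, best-validation checkpointing and early stopping.
#' Signals are standardized per trial (zero mean, unit variance) before the
#' network. With two channels the PMLDF fusion architecture is used.
#'
#' @param trials_train,trials_val Lists of `ssr_trial` objects.
#' @param channels `"emg"`, `"pzt"`, or both (both implies PMLDF).
#' @param spec An [fen_spec()] (one channel) or [pmldf_spec()] (two); a
#'   default is built when omitted.
#' @param cn An [cn_spec()].
#' @param config An [train_config()].
#' @return An `ssr_nn_model`.
#' @export
cnn_train <- function(trials_train, trials_val, channels = "emg", spec = NULL,
                      cn = cn_spec(), config = train_config()) {
  spec <- resolve_spec(spec, channels)
  y_train <- droplevels(factor(trial_labels(trials_train), levels = ssr_classes()))
  bad <- setdiff(unique(trial_labels(trials_val)), levels(y_train))
  if (length(bad)) {
    stop("validation labels absent from training: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y_val <- factor(trial_labels(trials_val), levels = levels(y_train))
  net <- nn_init(spec, cn, head = "softmax", n_classes = nlevels(y_train),
                 seed = config$seed)
  fit <- train_network(net, nn_inputs(trials_train, channels), y_train,
                       nn_inputs(trials_val, channels), y_val, config)
  m <- build_nn_model(fit, spec, channels, config, "softmax")
  m$labels <- levels(y_train)
  m
}

#' Train a Siamese few-shot classifier on raw signals
#'
#' A single shared-weight embedder maps reference trials and training trials
#' to 256-dimensional feature vectors; the cosine-similarity loss pulls each
#' sample toward its class's reference feature vector (the mean embedding of
#' that class's reference trials, recomputed every epoch) and pushes it away
#' from the other classes' references.
#'
#' @inheritParams cnn_train
#' @param n_ref Reference trials per class, drawn from the training partition
#'   (few-shot default 5).
#' @param margin Hinge margin on negative cosine similarities (default 0).
#' @return An `ssr_nn_model` whose `refs` field is the final `ssr_embedding_set`.
#' @export
snn_train <- function(trials_train, trials_val, channels = "emg", spec = NULL,
                      cn = cn_spec(), config = train_config(), n_ref = 5L,
                      margin = 0) {
  spec <- resolve_spec(spec, channels)
  missing <- setdiff(ssr_classes(), unique(trial_labels(trials_train)))
  if (length(missing)) {
    stop("no reference trials available for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y_train <- factor(trial_labels(trials_train), levels = ssr_classes())
  y_val <- factor(trial_labels(trials_val), levels = levels(y_train))
  labels <- levels(y_train)
  ref_idx <- lapply(stats::setNames(labels, labels), function(lb) {
    cand <- which(y_train == lb)
    with_seed(substream_seed(config$seed, 47L, match(lb, labels)),
              sample(cand, min(n_ref, length(cand))))
  })
  net <- nn_init(spec, cn, head = "siamese", n_classes = nlevels(y_train),
                 seed = config$seed)
  fit <- train_network(net, nn_inputs(trials_train, channels), y_train,
                       nn_inputs(trials_val, channels), y_val, config,
                       ref_idx = ref_idx, margin = margin)
  fit$refs$provenance <- trial_ids(trials_train)[unlist(ref_idx)]
  m <- build_nn_model(fit, spec, channels, config, "siamese")
  m$labels <- labels
  m
}

#' Predict letter classes with a trained network
#'
#' Softmax models take the argmax class score; Siamese models take the class
#' whose reference feature vector has the highest cosine similarity to the
#' trial's embedding (ties resolve to the lexicographically first label).
#'
#' @param object An `ssr_nn_model`.
#' @param trials List of `ssr_trial` objects.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.ssr_nn_model <- function(object, trials, ...) {
  inputs <- nn_inputs(trials, object$channels)
  scores <- nn_scores(object$net, inputs, object$refs)
  factor(object$labels[apply(scores, 2L, which.max)], levels = object$labels)
}

#' @rdname predict.ssr_nn_model
#' @param model An `ssr_nn_model` trained by [snn_train()].
#' @export
snn_predict <- function(model, trials) {
  stopifnot(identical(model$head, "siamese"))
  predict(model, trials)
}

#' Embed trials with a trained network
#'
#' @param model An `ssr_nn_model`.
#' @param trials List of `ssr_trial` objects.
#' @return Matrix `[embedding_dim, n_trials]`.
#' @export
nn_embed_trials <- function(model, trials) {
  nn_embed(model$net, nn_inputs(trials, model$channels), training = FALSE)$emb
}

#' Evaluate a trained network on a test partition
#'
#' @param model An `ssr_nn_model`.
#' @param trials_test List of `ssr_trial` objects.
#' @return An `ssr_result`.
#' @export
evaluate_nn <- function(model, trials_test) {
  pred <- predict(model, trials_test)
  scenario_result(trial_labels(trials_test), as.character(pred), model$labels)
}

#' @export
print.ssr_nn_model <- function(x, ...) {
  cat(sprintf("<ssr_nn_model: %s head, channels %s, best val acc %.2f%% (epoch %d/%d)>\n",
              x$head, paste(x$channels, collapse = "+"),
              100 * x$best_val_acc, x$best_epoch, x$epochs_trained))
  invisible(x)
}
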
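# Training-set augmentation.
#
# Feature space: SMOTE interpolation between same-class nearest neighbours.
# Signal space: eight operators -- four local (hang, gauss, noise,
# downsample: only a contiguous window is touched) and four global (slope,
# shift_x, shift_y, scale) -- composed in seeded random order. Every
# operator preserves signal length; drawn parameters respect the printed
# bounds (audited by test).

#' SMOTE feature-space oversampling
#'
#' New samples are `x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest same-class neighbours of `x_i`;
#' originals are retained.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels.
#' @param target_per_class Desired per-class count after augmentation; a
#'   single number or a named vector. Default: twice the largest class.
#' @param k_neighbors Neighbourhood size (default 5).
#' @param seed Integer seed.
#' @return List: `x` (augmented matrix), `y` (labels), `synthetic` (logical
#'   flag per row).
#' @export
smote_oversample <- function(x, y, target_per_class = NULL, k_neighbors = 5L,
                             seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  counts <- table(y)
  too_small <- names(counts)[counts < k_neighbors + 1L]
  if (length(too_small)) {
    stop(sprintf("class(es) %s have fewer than k_neighbors + 1 = %d samples",
                 paste(too_small, collapse = ", "), k_neighbors + 1L), call. = FALSE)
  }
  if (is.null(target_per_class)) target_per_class <- 2L * max(counts)
  if (is.null(names(target_per_class))) {
    target <- stats::setNames(rep(target_per_class[1L], nlevels(y)), levels(y))
  } else {
    target <- target_per_class[levels(y)]
  }
  if (any(target < counts)) {
    stop("target_per_class must be >= the current count of every class", call. = FALSE)
  }
  new_x <- list(); new_y <- character(0)
  for (lv in levels(y)) {
    xi <- x[y == lv, , drop = FALSE]
    need <- target[[lv]] - nrow(xi)
    if (need <= 0) next
    d <- as.matrix(stats::dist(xi))
    diag(d) <- Inf
    nn_raw <- apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)])
    nn <- if (k_neighbors == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)
    synth <- with_seed(substream_seed(seed, match(lv, levels(y))), {
      i_base <- sample.int(nrow(xi), need, replace = TRUE)
      i_nn <- nn[cbind(i_base, sample.int(k_neighbors, need, replace = TRUE))]
      lambda <- stats::runif(need)
      xi[i_base, , drop = FALSE] +
        lambda * (xi[i_nn, , drop = FALSE] - xi[i_base, , drop = FALSE])
    })
    new_x[[lv]] <- synth
    new_y <- c(new_y, rep(lv, need))
  }
  add <- if (length(new_x)) do.call(rbind, new_x) else x[0, , drop = FALSE]
  list(x = rbind(x, add),
       y = factor(c(as.character(y), new_y), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(add))))
}

local_operator_names <- function() c("hang", "gauss", "noise", "downsample")
global_operator_names <- function() c("slope", "shift_x", "shift_y", "scale")

#' Signal operator names
#' @return Character vector of the eight raw-signal augmentation operators.
#' @export
signal_operator_names <- function() c(local_operator_names(), global_operator_names())

# Draw a contiguous window [i, j) with at least `min_len` samples; redraw on
# degenerate windows rather than erroring.
draw_window <- function(n, min_len = 2L) {
  repeat {
    len <- sample(seq.int(min_len, max(min_len, floor(n / 2))), 1L)
    start <- sample.int(n - len + 1L, 1L)
    if (len >= min_len) return(c(start, start + len))  # half-open [start, end)
  }
}

gauss_kernel <- function(width) {
  sigma <- width / 6                      # kernel truncated at 3 sigma
  half <- (width - 1L) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Local (windowed) signal augmentation operators
#'
#' Only a randomly drawn contiguous window of the signal is modified; the
#' output has the input's length. Draws come from the current RNG state.
#' `hang` freezes the window at its first sample; `gauss` smooths the window
#' with a normalized Gaussian kernel of random odd width in 3..31 (edge
#' samples replicated); `noise` adds `U(0, 1)` (or `U(-1, 1)` with
#' `zero_centered_noise`) scaled by the signal's standard deviation;
#' `downsample` linearly resamples the window to a random 1--25\% of its
#' length and back.
#'
#' @param x Numeric signal, length >= 8.
#' @param kind One of `"hang"`, `"gauss"`, `"noise"`, `"downsample"`.
#' @param window Optional fixed window `c(start, end)` (half-open, 1-based)
#'   overriding the random draw.
#' @param zero_centered_noise Use a zero-centered noise draw (the printed
#'   one-sided draw adds a positive bias).
#' @return Augmented signal with an `aug_params` attribute recording draws.
#' @export
augment_local <- function(x, kind = c("hang", "gauss", "noise", "downsample"),
                          window = NULL, zero_centered_noise = FALSE) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 8L) stop("signal must have at least 8 samples", call. = FALSE)
  if (is.null(window)) window <- draw_window(n, min_len = if (kind == "downsample") 8L else 2L)
  i <- window[1L]; j <- window[2L]
  w <- j - i                             # window length
  idx <- i:(j - 1L)
  out <- x
  params <- list(kind = kind, window = window)
  if (kind == "hang") {
    out[idx[-1L]] <- x[i]
  } else if (kind == "gauss") {
    width <- sample(seq(3L, 31L, by = 2L), 1L)
    params$kernel_width <- width
    seg <- x[idx]
    half <- (width - 1L) / 2
    padded <- c(rep(seg[1L], half), seg, rep(seg[w], half))
    out[idx] <- stats::filter(padded, gauss_kernel(width), sides = 2)[(half + 1L):(half + w)]
  } else if (kind == "noise") {
    draws <- if (zero_centered_noise) stats::runif(w, -1, 1) else stats::runif(w)
    params$noise_range <- range(draws)
    out[idx] <- x[idx] + draws * stats::sd(x)
  } else {                               # downsample
    frac <- stats::runif(1L, 0.01, 0.25)
    params$fraction <- frac
    m <- max(2L, round(frac * w))
    down <- stats::approx(seq_len(w), x[idx], xout = seq(1, w, length.out = m))$y
    out[idx] <- stats::approx(seq(1, w, length.out = m), down, xout = seq_len(w))$y
  }
  attr(out, "aug_params") <- params
  out
}

#' Global (whole-signal) augmentation operators
#'
#' `slope` adds a linear ramp with total rise drawn in `[0, 10 * sd(x))`;
#' `shift_x` shifts circularly by up to 5\% of the length; `shift_y` adds a
#' constant offset bounded by 5\% of the signal's range; `scale` multiplies
#' by a factor in `[0.95, 1.05]`.
#'
#' @param x Numeric signal, length >= 8.
#' @param kind One of `"slope"`, `"shift_x"`, `"shift_y"`, `"scale"`.
#' @param circular Circular x-shift (default); otherwise the vacated tail is
#'   zero-padded.
#' @return Augmented signal with an `aug_params` attribute.
#' @export
augment_global <- function(x, kind = c("slope", "shift_x", "shift_y", "scale"),
                           circular = TRUE) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 8L) stop("signal must have at least 8 samples", call. = FALSE)
  params <- list(kind = kind)
  out <- x
  if (kind == "slope") {
    rise <- stats::runif(1L, 0, 10 * stats::sd(x))
    params$rise <- rise
    out <- x + (rise / n) * (seq_len(n) - 1L)
  } else if (kind == "shift_x") {
    smax <- floor(0.05 * n)
    s <- sample(seq.int(-smax, smax), 1L)
    params$shift <- s
    if (s != 0) {
      if (circular) {
        out <- x[((seq_len(n) - 1L + s) %% n) + 1L]
      } else {
        out <- numeric(n)
        if (s > 0) out[seq_len(n - s)] <- x[(s + 1L):n]
        else out[(1L - s):n] <- x[seq_len(n + s)]
      }
    }
  } else if (kind == "shift_y") {
    dy <- diff(range(x))
    off <- stats::runif(1L, -0.05 * dy, 0.05 * dy)
    params$offset <- off
    out <- x + off
  } else {
    sc <- stats::runif(1L, 0.95, 1.05)
    params$scale <- sc
    out <- x * sc
  }
  attr(out, "aug_params") <- params
  out
}

#' Build a seeded signal-augmentation plan
#'
#' Each operator is independently included with probability `p_include`, and
#' the included operators are applied in a seed-shuffled random order.
#'
#' @param seed Integer seed.
#' @param operators Operator pool (default all eight).
#' @param p_include Per-operator inclusion probability (default 0.5).
#' @return An `ssr_aug_plan`: ordered operator names plus the seed.
#' @export
augmentation_plan <- function(seed = 1L, operators = signal_operator_names(),
                              p_include = 0.5) {
  bad <- setdiff(operators, signal_operator_names())
  if (length(bad)) stop("unknown operator(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ops <- with_seed(substream_seed(seed, 1L), {
    keep <- operators[stats::runif(length(operators)) < p_include]
    if (length(keep) > 1L) sample(keep) else keep
  })
  structure(list(operators = ops, seed = as.integer(seed), p_include = p_include),
            class = "ssr_aug_plan")
}

#' Apply an augmentation plan to a signal
#'
#' Operators are applied sequentially in the plan's order, with all parameter
#' draws taken from the plan's seeded stream; a plan with no included
#' operators is the identity.
#'
#' @param x Numeric signal.
#' @param plan An `ssr_aug_plan`.
#' @param zero_centered_noise Passed to [augment_local()].
#' @return Augmented signal of the same length, with an `applied` attribute
#'   listing each operator's drawn parameters.
#' @export
compose <- function(x, plan, zero_centered_noise = FALSE) {
  stopifnot(inherits(plan, "ssr_aug_plan"))
  applied <- list()
  out <- as.numeric(x)
  with_seed(substream_seed(plan$seed, 2L), {
    for (op in plan$operators) {
      out <- if (op %in% local_operator_names()) {
        augment_local(out, op, zero_centered_noise = zero_centered_noise)
      } else {
        augment_global(out, op)
      }
      applied[[length(applied) + 1L]] <- attr(out, "aug_params")
      attr(out, "aug_params") <- NULL
    }
  })
  attr(out, "applied") <- applied
  out
}

#' Augment a training set of trials in signal space
#'
#' Generates `n_copies` augmented copies of each trial (originals retained),
#' with independent seeded plans per trial, copy and channel. Intended for
#' the training partition only.
#'
#' @param trials List of `ssr_trial` objects (the training partition).
#' @param n_copies Augmented copies per trial (default 1).
#' @param seed Integer seed.
#' @param p_include Per-operator inclusion probability.
#' @return List of `ssr_trial` objects: originals followed by copies (copy
#'   ids get an `_augN` suffix).
#' @export
augment_trials <- function(trials, n_copies = 1L, seed = 1L, p_include = 0.5) {
  out <- trials
  for (c_i in seq_len(n_copies)) {
    for (t_i in seq_along(trials)) {
      tr <- trials[[t_i]]
      plan_e <- augmentation_plan(substream_seed(seed, c_i, t_i, 1L), p_include = p_include)
      plan_p <- augmentation_plan(substream_seed(seed, c_i, t_i, 2L), p_include = p_include)
      aug <- tr
      aug$emg <- as.numeric(compose(tr$emg, plan_e))
      aug$pzt <- as.numeric(compose(tr$pzt, plan_p))
      aug$trial_id <- sprintf("%s_aug%d", tr$trial_id, c_i)
      out[[length(out) + 1L]] <- aug
    }
  }
  out
}
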
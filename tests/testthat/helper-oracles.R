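# Independent reference implementations (naive loops / naive DFT) used as
# oracles, plus small fixture builders. Deliberately written without reusing
# any package internals.

oracle_time_features <- function(y) {
  n <- length(y)
  s_abs <- 0; s_sq <- 0; s_mu <- 0
  for (v in y) {
    s_abs <- s_abs + abs(v)
    s_sq <- s_sq + v^2
    s_mu <- s_mu + v
  }
  mu <- s_mu / n
  s_var <- 0
  for (v in y) s_var <- s_var + (v - mu)^2
  wl <- 0; zc <- 0
  for (i in seq_len(n - 1)) {
    wl <- wl + abs(y[i + 1] - y[i])
    if (y[i] * y[i + 1] < 0) zc <- zc + 1
  }
  c(mav = s_abs / n, rms = sqrt(s_sq / n), variance = s_var / n,
    waveform_length = wl, zcr = zc)
}

# One-sided magnitude spectrum by explicit DFT summation (outer-product).
oracle_spectrum <- function(y, fs) {
  n <- length(y)
  ks <- 0:(n %/% 2)
  W <- exp(-2i * pi * outer(ks, 0:(n - 1)) / n)
  mag <- Mod(as.vector(W %*% y))
  list(freqs = ks * fs / n, magnitudes = mag, power = mag^2)
}

oracle_freq_features <- function(freqs, mag) {
  pw <- mag^2
  dominant <- freqs[which(mag == max(mag))[1]]
  mean_f <- 0; tot_p <- 0; cent <- 0; tot_m <- 0
  for (i in seq_along(freqs)) {
    mean_f <- mean_f + freqs[i] * pw[i]
    tot_p <- tot_p + pw[i]
    cent <- cent + freqs[i] * mag[i]
    tot_m <- tot_m + mag[i]
  }
  acc <- 0; med <- freqs[length(freqs)]
  for (i in seq_along(freqs)) {
    acc <- acc + pw[i]
    if (acc >= tot_p / 2) { med <- freqs[i]; break }
  }
  c(dominant_freq = dominant, mean_freq = mean_f / tot_p,
    median_freq = med, freq_centroid = cent / tot_m)
}

# Ground-truth feature tables: 8 classes coded in dedicated informative
# dimensions (dim j separates classes 2j-1 and 2j; dropping any informative
# dimension merges exactly one class pair), plus pure-noise dimensions.
# The planted effect (a = 8, noise sd 1) puts the informative subset at
# ceiling accuracy, so "the right answer" is unambiguous for selection.
make_selection_data <- function(n_per_class, n_noise, seed, a = 8) {
  set.seed(seed)
  y <- factor(rep(ssr_classes(), each = n_per_class))
  n <- length(y)
  x_inf <- matrix(0, n, 4)
  for (ci in 1:8) {
    rows <- which(as.integer(y) == ci)
    j <- ceiling(ci / 2)
    x_inf[rows, j] <- a * (2 * (ci %% 2) - 1)
  }
  x <- cbind(x_inf + matrix(stats::rnorm(n * 4), n, 4),
             matrix(stats::rnorm(n * n_noise), n, n_noise))
  colnames(x) <- c(paste0("inf", 1:4), paste0("noise", seq_len(n_noise)))
  list(x = x, y = y)
}

# Small, fast synthetic dataset (64-sample trials) for unit tests.
tiny_config <- function(n_per_class = 6, seed = 1, ...) {
  generator_config(fs = 1024, duration = 0.0625, n_per_class = n_per_class,
                   seed = seed, ...)
}

tiny_dataset <- function(n_per_class = 6, seed = 1, ...) {
  generate_dataset(tiny_config(n_per_class, seed, ...))
}

# Tiny network specs so neural unit tests stay fast.
tiny_fen <- function(n_layers = 2L) {
  fen_spec(n_layers, channels = c(4L, 6L)[seq_len(n_layers)], kernel = 3L,
           pool_lengths = c(16L, 8L)[seq_len(n_layers)], input_length = NULL)
}

# Datasets for the acceptance benchmarks are built once and cached.
.acc_cache <- new.env(parent = emptyenv())

acceptance_dataset <- function(mode = "independent", seed = 2024) {
  key <- paste0(mode, "_", seed)
  if (is.null(.acc_cache[[key]])) {
    cfg <- generator_config(n_per_class = 100, seed = seed,
                            channel_coupling_mode = mode)
    .acc_cache[[key]] <- generate_dataset(cfg)
  }
  .acc_cache[[key]]
}
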
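# Time- and frequency-domain descriptors of a single-trial biosignal.
#
# The nine features per channel, in fixed order:
#   mav, rms, variance, waveform_length, zcr,
#   dominant_freq, mean_freq, median_freq, freq_centroid
#
# Conventions (degenerate printed formulas resolved once, documented in the
# methods vignette): population variance (1/N); zero crossings counted with
# the strict product rule y_i * y_{i+1} < 0, so exact-zero samples break a
# crossing; mean frequency is power-weighted, frequency centroid is
# magnitude-weighted; the DC bin participates in all spectral weights;
# dominant-frequency ties resolve to the lowest frequency; no windowing or
# detrending before the transform.

feature_names_1ch <- function() {
  c("mav", "rms", "variance", "waveform_length", "zcr",
    "dominant_freq", "mean_freq", "median_freq", "freq_centroid")
}

#' Time-domain features of a signal
#'
#' @param y Numeric sample vector (mV), length >= 2.
#' @return Named numeric vector: `mav` (mean absolute value, mV), `rms` (mV),
#'   `variance` (population, mV^2), `waveform_length` (summed absolute first
#'   differences, mV), `zcr` (strict zero-crossing count).
#' @export
time_features <- function(y) {
  n <- length(y)
  if (n < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  if (!is.numeric(y) || anyNA(y)) stop("signal must be numeric without NA", call. = FALSE)
  mu <- mean(y)
  c(mav = mean(abs(y)),
    rms = sqrt(mean(y^2)),
    variance = mean((y - mu)^2),
    waveform_length = sum(abs(diff(y))),
    zcr = sum(y[-n] * y[-1L] < 0))
}

#' One-sided discrete magnitude spectrum
#'
#' Raw DFT over bins 0..floor(N/2); no windowing, no detrending.
#'
#' @param y Numeric sample vector, length >= 2.
#' @param fs Sampling rate, Hz.
#' @return An `ssr_spectrum`: list with `freqs` (Hz), `magnitudes` (|Y_k|) and
#'   `power` (|Y_k|^2).
#' @export
magnitude_spectrum <- function(y, fs) {
  if (length(y) < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  n <- length(y)
  k <- 0:(n %/% 2)
  mag <- Mod(stats::fft(y))[k + 1L]
  structure(list(freqs = k * fs / n, magnitudes = mag, power = mag^2),
            class = "ssr_spectrum")
}

#' Spectral features from a magnitude spectrum
#'
#' @param spec An `ssr_spectrum` from [magnitude_spectrum()].
#' @return Named numeric vector (all Hz): `dominant_freq` (argmax magnitude,
#'   ties to the lowest frequency), `mean_freq` (power-weighted mean),
#'   `median_freq` (smallest frequency at which cumulative power reaches half
#'   the total), `freq_centroid` (magnitude-weighted mean).
#' @export
freq_features <- function(spec) {
  stopifnot(inherits(spec, "ssr_spectrum"))
  ptot <- sum(spec$power)
  if (ptot <= 0) stop("all-zero spectrum: spectral features undefined", call. = FALSE)
  f <- spec$freqs
  c(dominant_freq = f[which.max(spec$magnitudes)],
    mean_freq = sum(f * spec$power) / ptot,
    median_freq = f[which(cumsum(spec$power) >= ptot / 2)[1L]],
    freq_centroid = sum(f * spec$magnitudes) / sum(spec$magnitudes))
}

#' Extract the per-channel feature vector of a trial
#'
#' @param trial An `ssr_trial`.
#' @param channels Channels to include, subset of `c("emg", "pzt")`; with both,
#'   the vector is the EMG block followed by the PZT block (18 values).
#' @return Named numeric vector, names prefixed `emg_` / `pzt_`.
#' @export
extract_features <- function(trial, channels = c("emg", "pzt")) {
  stopifnot(inherits(trial, "ssr_trial"))
  unknown <- setdiff(channels, c("emg", "pzt"))
  if (length(unknown)) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  channels <- intersect(c("emg", "pzt"), channels)  # fixed EMG-then-PZT order
  out <- numeric(0)
  for (ch in channels) {
    y <- trial[[ch]]
    fv <- c(time_features(y), freq_features(magnitude_spectrum(y, trial$fs)))
    names(fv) <- paste(ch, feature_names_1ch(), sep = "_")
    out <- c(out, fv)
  }
  out
}

#' Feature table for a whole dataset
#'
#' @param trials List of `ssr_trial` objects.
#' @param channels As in [extract_features()].
#' @return data.frame with `trial_id`, `label`, and one named column per
#'   feature.
#' @export
featurize_dataset <- function(trials, channels = c("emg", "pzt")) {
  feats <- t(vapply(trials, extract_features, channels = channels,
                    FUN.VALUE = extract_features(trials[[1L]], channels)))
  df <- data.frame(trial_id = trial_ids(trials), label = trial_labels(trials),
                   feats, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# Split a feature data.frame into (x matrix, y factor, ids).
feature_xy <- function(df) {
  feat_cols <- setdiff(names(df), c("trial_id", "label"))
  list(x = as.matrix(df[, feat_cols, drop = FALSE]),
       y = factor(df$label, levels = sort(unique(df$label))),
       ids = df$trial_id)
}
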
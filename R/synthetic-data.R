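# Synthetic two-channel (EMG + PZT) trial generator.
#
# Emulates the qualitative morphology of chin-worn sensor recordings during
# silent articulation: the EMG channel carries enveloped band-limited noise
# bursts (muscle activity, 50-500 Hz), the PZT channel carries decaying
# low-frequency sinusoids (skin vibration, < 40 Hz). Class identity is coded
# in band placement, tone frequency and onset timing; `separability`
# interpolates every class template between a shared baseline (0) and fully
# distinct motifs (1).

#' Configuration for the synthetic trial generator
#'
#' @param fs Sampling rate in Hz per channel (default 4096, the hardware rate).
#' @param duration Trial duration in seconds.
#' @param n_per_class Number of trials generated per letter class.
#' @param separability Real in \[0, 1\]; 0 collapses all class templates onto a
#'   shared baseline, 1 uses fully distinct per-class motifs.
#' @param jitter Fractional per-trial variability applied to amplitudes and
#'   onsets (0.1 = +/-10\% amplitude, +/-`0.1 * 50` ms onset shifts).
#' @param channel_coupling_mode `"independent"`: every class has distinct
#'   motifs in both channels. `"cross_channel_only"`: the 8 classes are built
#'   from 4 EMG motifs x 4 PZT motifs with every motif reused in two classes,
#'   so class identity is only recoverable from the channel *pair*.
#' @param snr_db Signal-to-noise ratio of the additive white noise floor, dB.
#' @param seed Integer seed; all randomness flows from it through per-trial
#'   substreams keyed by (label, trial index).
#' @return An object of class `ssr_generator_config`.
#' @export
generator_config <- function(fs = 4096, duration = 1.0, n_per_class = 100,
                             separability = 1.0, jitter = 0.1,
                             channel_coupling_mode = c("independent", "cross_channel_only"),
                             snr_db = 20, seed = 1L) {
  channel_coupling_mode <- match.arg(channel_coupling_mode)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 1) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(separability) || separability < 0 || separability > 1) {
    stop("`separability` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(jitter) || jitter < 0) {
    stop("`jitter` must be >= 0", call. = FALSE)
  }
  structure(
    list(fs = fs, duration = duration, n_per_class = as.integer(n_per_class),
         separability = separability, jitter = jitter,
         channel_coupling_mode = channel_coupling_mode,
         snr_db = snr_db, seed = as.integer(seed)),
    class = "ssr_generator_config"
  )
}

validate_template <- function(tpl, config) {
  dur <- config$duration
  nyq <- config$fs / 2
  eb <- tpl$emg_bursts
  pt <- tpl$pzt_tones
  stopifnot(
    all(eb$onset >= 0), all(eb$onset + eb$duration <= dur + 1e-9),
    all(eb$band_low < eb$band_high), all(eb$band_high < nyq),
    all(pt$onset >= 0), all(pt$onset <= dur),
    all(pt$freq < 100)
  )
  invisible(tpl)
}

# Linear interpolation between the shared baseline template and a distinct
# motif, controlled by separability s.
blend <- function(base, motif, s) (1 - s) * base + s * motif

emg_motif <- function(m, mode) {
  if (mode == "independent") {
    cf <- 90 + 42 * (m - 1)                     # 90 .. 384 Hz
    data.frame(
      onset     = c(0.10 + 0.05 * ((m - 1) %% 4), 0.55 + 0.02 * (m - 1)),
      duration  = c(0.35, 0.25),
      band_low  = c(cf - 35, 55),
      band_high = c(cf + 35, 125 + 6 * (m - 1)),
      amplitude = c(0.50 + 0.05 * (m %% 2), 0.30)
    )
  } else {
    cf <- 100 + 80 * (m - 1)                    # 4 motifs: 100 .. 340 Hz
    data.frame(
      onset     = 0.10 + 0.06 * (m - 1),
      duration  = 0.40,
      band_low  = cf - 40,
      band_high = cf + 40,
      amplitude = 0.55
    )
  }
}

pzt_motif <- function(m, mode) {
  if (mode == "independent") {
    data.frame(
      onset     = 0.12 + 0.04 * ((m - 1) %% 4),
      freq      = 6 + 4 * (m - 1),              # 6 .. 34 Hz
      decay     = 4 + 0.5 * m,
      amplitude = 0.8
    )
  } else {
    data.frame(
      onset     = 0.12 + 0.05 * (m - 1),
      freq      = 8 + 8 * (m - 1),              # 4 motifs: 8 .. 32 Hz
      decay     = 5,
      amplitude = 0.8
    )
  }
}

emg_baseline <- function() {
  data.frame(onset = c(0.30, 0.55), duration = c(0.35, 0.25),
             band_low = c(150, 60), band_high = c(300, 140),
             amplitude = c(0.5, 0.3))
}

pzt_baseline <- function() {
  data.frame(onset = 0.25, freq = 18, decay = 6, amplitude = 0.8)
}

# Motif index layout for cross_channel_only: unique (EMG, PZT) pairs with
# every single-channel motif appearing in exactly two classes.
cross_channel_pairs <- function() {
  list(emg = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
       pzt = c(1L, 2L, 3L, 4L, 2L, 1L, 4L, 3L))
}

#' Build the eight class templates
#'
#' Deterministic given the config. In `cross_channel_only` mode the marginal
#' motif set of each channel contains duplicates across classes, so no single
#' channel can separate all eight classes.
#'
#' @param config An [generator_config()] object.
#' @return A named list of 8 `ssr_class_template` objects, one per letter.
#' @export
make_templates <- function(config) {
  if (!inherits(config, "ssr_generator_config")) {
    stop("`config` must be created by generator_config()", call. = FALSE)
  }
  labels <- ssr_classes()
  mode <- config$channel_coupling_mode
  s <- config$separability
  pairs <- cross_channel_pairs()
  templates <- lapply(seq_along(labels), function(k) {
    if (mode == "independent") {
      e_idx <- k
      p_idx <- k
    } else {
      e_idx <- pairs$emg[k]
      p_idx <- pairs$pzt[k]
    }
    eb_base <- emg_baseline()
    eb_mot <- emg_motif(e_idx, mode)
    # baseline and motif tables may have different burst counts; recycle the
    # baseline's first burst where needed
    if (nrow(eb_mot) != nrow(eb_base)) {
      eb_base <- eb_base[rep(1L, nrow(eb_mot)), , drop = FALSE]
    }
    eb <- as.data.frame(Map(blend, eb_base, eb_mot, MoreArgs = list(s = s)))
    pt <- as.data.frame(Map(blend, pzt_baseline(), pzt_motif(p_idx, mode),
                            MoreArgs = list(s = s)))
    # motif timings are fractions of the trial; rescale to seconds
    eb$onset <- eb$onset * config$duration
    eb$duration <- eb$duration * config$duration
    pt$onset <- pt$onset * config$duration
    tpl <- structure(
      list(label = labels[k], emg_bursts = eb, pzt_tones = pt,
           emg_motif = e_idx, pzt_motif = p_idx),
      class = "ssr_class_template"
    )
    validate_template(tpl, config)
  })
  names(templates) <- labels
  templates
}

# Band-limited unit-RMS Gaussian noise of length n (FFT brick-wall mask).
band_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  if (n < 4) return(w / max(stats::sd(w), 1e-12))
  spec <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided bin frequencies
  spec[freqs < lo | freqs > hi] <- 0 + 0i
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r < 1e-12) return(numeric(n))
  x / r
}

#' Generate a single synthetic trial
#'
#' Deterministic given `(config$seed, template$label, trial_index)`; the trial
#' substream makes datasets reproducible under reordering.
#'
#' @param template One template from [make_templates()].
#' @param config The [generator_config()] the template was built with.
#' @param trial_index 1-based index of the trial within its class.
#' @return An `ssr_trial`: list with `emg`, `pzt` (mV sample vectors), `fs`,
#'   `label`, `trial_id`.
#' @export
generate_trial <- function(template, config, trial_index = 1L) {
  if (!inherits(template, "ssr_class_template")) {
    stop("`template` must come from make_templates()", call. = FALSE)
  }
  k <- match(template$label, ssr_classes())
  seed <- substream_seed(config$seed, k, trial_index)
  with_seed(seed, {
    n <- round(config$fs * config$duration)
    t <- (seq_len(n) - 1) / config$fs
    j <- config$jitter

    synth_channel <- function(rows, synth_row) {
      sig <- numeric(n)
      for (r in seq_len(nrow(rows))) {
        amp_scale <- 1 + j * stats::runif(1, -1, 1)
        onset_shift <- j * 0.05 * stats::runif(1, -1, 1)
        sig <- sig + synth_row(rows[r, ], amp_scale, onset_shift)
      }
      sig
    }

    emg_clean <- synth_channel(template$emg_bursts, function(b, amp_scale, onset_shift) {
      onset <- min(max(b$onset + onset_shift, 0), config$duration)
      i0 <- floor(onset * config$fs) + 1
      len <- min(round(b$duration * config$fs), n - i0 + 1)
      out <- numeric(n)
      if (len >= 4) {
        env <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))  # Hann
        out[i0:(i0 + len - 1)] <-
          b$amplitude * amp_scale * env * band_noise(len, config$fs, b$band_low, b$band_high)
      }
      out
    })

    pzt_clean <- synth_channel(template$pzt_tones, function(p, amp_scale, onset_shift) {
      onset <- min(max(p$onset + onset_shift, 0), config$duration)
      out <- numeric(n)
      act <- t >= onset
      tt <- t[act] - onset
      out[act] <- p$amplitude * amp_scale * exp(-p$decay * tt) * sin(2 * pi * p$freq * tt)
      out
    })

    add_floor <- function(x) {
      r <- sqrt(mean(x^2))
      sdn <- r / 10^(config$snr_db / 20)
      x + stats::rnorm(n) * sdn
    }

    structure(
      list(emg = add_floor(emg_clean), pzt = add_floor(pzt_clean),
           fs = config$fs, label = template$label,
           trial_id = sprintf("%s_%03d", template$label, as.integer(trial_index))),
      class = "ssr_trial"
    )
  })
}

#' Generate a full balanced synthetic dataset
#'
#' @param config A [generator_config()].
#' @return List of `ssr_trial` objects, `n_per_class` per letter (8 classes),
#'   deterministically shuffled by the seed.
#' @export
generate_dataset <- function(config) {
  templates <- make_templates(config)
  trials <- list()
  for (tpl in templates) {
    for (i in seq_len(config$n_per_class)) {
      trials[[length(trials) + 1L]] <- generate_trial(tpl, config, i)
    }
  }
  ord <- with_seed(substream_seed(config$seed, 999L), sample.int(length(trials)))
  trials[ord]
}

#' @export
print.ssr_trial <- function(x, ...) {
  cat(sprintf("<ssr_trial %s: label %s, %d samples/channel @ %g Hz>\n",
              x$trial_id, x$label, length(x$emg), x$fs))
  invisible(x)
}

#' Labels and ids of a trial list
#'
#' @param trials List of `ssr_trial` objects.
#' @return Character vector, one element per trial.
#' @export
trial_labels <- function(trials) {
  vapply(trials, function(tr) tr$label, character(1))
}

#' @rdname trial_labels
#' @export
trial_ids <- function(trials) {
  vapply(trials, function(tr) tr$trial_id, character(1))
}
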
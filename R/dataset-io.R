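# Trial/manifest storage and the stratified train/validation/test split.
#
# One delimited text file per trial (columns emg_mV, pzt_mV) plus a CSV
# manifest (trial_id, path, label, fs, n_samples). The recording format of
# the original deposit is undocumented, so the package defines its own plain
# text layout.

#' Write a trial to a delimited text file
#'
#' Two comma-separated columns `emg_mV`, `pzt_mV` with a header line; samples
#' are written at full double precision so a round trip is lossless.
#'
#' @param trial An `ssr_trial`.
#' @param path Output file path.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "ssr_trial"))
  lines <- c("emg_mV,pzt_mV",
             paste(format(trial$emg, digits = 17, trim = TRUE, scientific = FALSE),
                   format(trial$pzt, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial file
#'
#' @param path Trial file written by [write_trial()].
#' @param fs Sampling rate in Hz (from the manifest).
#' @param label Class label (from the manifest).
#' @param trial_id Trial identifier.
#' @return An `ssr_trial`.
#' @export
read_trial <- function(path, fs, label, trial_id = basename(path)) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop(sprintf("parse error in '%s': file has no data rows", path), call. = FALSE)
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad)) {
    stop(sprintf("parse error in '%s' line %d: expected 2 columns, found %d",
                 path, bad[1], nf[bad[1]]), call. = FALSE)
  }
  body <- fields[-1L]
  emg <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 1L)))
  pzt <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 2L)))
  if (anyNA(emg) || anyNA(pzt)) {
    ln <- min(which(is.na(emg) | is.na(pzt))) + 1L
    stop(sprintf("parse error in '%s' line %d: non-numeric value", path, ln),
         call. = FALSE)
  }
  structure(list(emg = emg, pzt = pzt, fs = fs, label = label, trial_id = trial_id),
            class = "ssr_trial")
}

#' Save a dataset as per-trial files plus a manifest
#'
#' @param trials List of `ssr_trial` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
save_dataset <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    fname <- paste0(tr$trial_id, ".csv")
    write_trial(tr, file.path(dir, fname))
    data.frame(trial_id = tr$trial_id, path = fname, label = tr$label,
               fs = tr$fs, n_samples = length(tr$emg))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a dataset from a manifest
#'
#' @param manifest_path Path to `manifest.csv` written by [save_dataset()].
#' @return List of `ssr_trial` objects in manifest order.
#' @export
load_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "path", "label", "fs", "n_samples")
  if (!all(needed %in% names(manifest))) {
    stop("manifest is missing columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    tr <- read_trial(file.path(base, manifest$path[i]), fs = manifest$fs[i],
                     label = manifest$label[i], trial_id = manifest$trial_id[i])
    if (length(tr$emg) != manifest$n_samples[i]) {
      stop(sprintf("trial '%s': %d samples on disk but manifest says %d",
                   tr$trial_id, length(tr$emg), manifest$n_samples[i]), call. = FALSE)
    }
    tr
  })
}

#' Stratified train/validation/test split
#'
#' Splits per class so each partition keeps the global class balance; the
#' protocol fractions are 60/20/20. Invariant to input ordering given the
#' seed (ids are sorted before shuffling).
#'
#' @param trials List of `ssr_trial` objects (or a character label vector named
#'   by trial id).
#' @param fractions Numeric length 3 (train, validation, test), summing to 1.
#' @param seed Integer seed.
#' @return An `ssr_split`: list of `train`, `validation`, `test` id vectors.
#' @export
stratified_split <- function(trials, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be 3 nonnegative numbers summing to 1", call. = FALSE)
  }
  if (is.list(trials)) {
    labels <- trial_labels(trials)
    ids <- trial_ids(trials)
  } else {
    labels <- as.character(trials)
    ids <- names(trials)
    if (is.null(ids)) stop("label vector must be named by trial id", call. = FALSE)
  }
  counts <- table(labels)
  too_few <- names(counts)[counts < 5L]
  if (length(too_few)) {
    stop("classes with fewer than 5 trials cannot be split 60/20/20: ",
         paste(too_few, collapse = ", "), call. = FALSE)
  }
  parts <- list(train = character(0), validation = character(0), test = character(0))
  for (lab in sort(unique(labels))) {
    cls_ids <- sort(ids[labels == lab])
    n <- length(cls_ids)
    perm <- with_seed(substream_seed(seed, match(lab, sort(unique(labels)))),
                      sample(cls_ids))
    n_train <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    if (n_train + n_val >= n) n_val <- max(0L, n - n_train - 1L)
    parts$train <- c(parts$train, perm[seq_len(n_train)])
    parts$validation <- c(parts$validation, perm[n_train + seq_len(n_val)])
    parts$test <- c(parts$test, perm[(n_train + n_val + 1L):n])
  }
  structure(parts, class = "ssr_split")
}

#' @export
print.ssr_split <- function(x, ...) {
  cat(sprintf("<ssr_split: %d train / %d validation / %d test>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Write / read a split as JSON
#'
#' @param split An `ssr_split`.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(x[c("train", "validation", "test")], as.character),
            class = "ssr_split")
}

#' Subset a trial list by trial ids
#'
#' @param trials List of `ssr_trial` objects.
#' @param ids Trial ids to keep, in the order requested.
#' @return List of `ssr_trial` objects.
#' @export
subset_trials <- function(trials, ids) {
  all_ids <- trial_ids(trials)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) {
    stop("unknown trial ids: ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  trials[idx]
}
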
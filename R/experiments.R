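# The nine training scenarios: sensor channel(s) x feature treatment x model
# family, all sharing the stratified 60/20/20 split with augmentation applied
# to the training partition only.

scenario_modes <- function() {
  data.frame(
    id = 1:9,
    input = c("emg-features", "pzt-features", "both-features",
              "optimized-emg", "optimized-pzt", "optimized-both",
              "raw-emg", "raw-pzt", "raw-both-pmldf"),
    kind = c(rep("features", 6), rep("raw", 3)),
    channels = c("emg", "pzt", "emg,pzt", "emg", "pzt", "emg,pzt",
                 "emg", "pzt", "emg,pzt"),
    optimized = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Scenario specification
#'
#' Scenarios 1-6 are feature-based (SVM / decision tree / random forest on
#' the per-channel descriptors, scenarios 4-6 after RFE optimization);
#' scenarios 7-9 feed standardized raw signals to the networks, scenario 9
#' fusing both sensors with PMLDF.
#'
#' @param id Scenario number 1-9.
#' @param model `"svm"`, `"rf"`, `"dt"` (scenarios 1-6) or `"cnn"`, `"snn"`
#'   (7-9).
#' @param augment Apply training-set augmentation (SMOTE for features,
#'   randomized signal operators for raw scenarios).
#' @param seed Integer seed driving split, augmentation and training.
#' @param nn_spec Network spec for raw scenarios; default is a 4-layer FEN
#'   (PMLDF of two such FENs for scenario 9).
#' @param train_cfg [train_config()] for raw scenarios; default caps training
#'   at 100 epochs.
#' @param fixed_subset Optional fixed feature-name subset (suffixes such as
#'   `c("waveform_length", "rms", "freq_centroid", "mean_freq")`) used in
#'   optimized scenarios instead of re-running RFE.
#' @param grid Optional hyperparameter grid override for feature models.
#' @return An `ssr_scenario_spec`.
#' @export
scenario_spec <- function(id, model, augment = TRUE, seed = 1L, nn_spec = NULL,
                          train_cfg = NULL, fixed_subset = NULL, grid = NULL) {
  modes <- scenario_modes()
  if (!id %in% modes$id) stop("`id` must be 1..9", call. = FALSE)
  mode <- modes[modes$id == id, ]
  feature_models <- c("svm", "rf", "dt")
  raw_models <- c("cnn", "snn")
  if (mode$kind == "features" && !model %in% feature_models) {
    stop(sprintf("scenario %d takes a feature-based model (%s), not '%s'",
                 id, paste(feature_models, collapse = "/"), model), call. = FALSE)
  }
  if (mode$kind == "raw" && !model %in% raw_models) {
    stop(sprintf("scenario %d takes a raw-signal model (%s), not '%s'",
                 id, paste(raw_models, collapse = "/"), model), call. = FALSE)
  }
  channels <- strsplit(mode$channels, ",")[[1L]]
  if (is.null(train_cfg)) {
    train_cfg <- train_config(lr = 3e-3, max_epochs = 100L, seed = seed)
  }
  structure(list(id = id, input = mode$input, kind = mode$kind,
                 channels = channels, optimized = mode$optimized,
                 model = model, augment = augment, seed = as.integer(seed),
                 nn_spec = nn_spec, train_cfg = train_cfg,
                 fixed_subset = fixed_subset, grid = grid),
            class = "ssr_scenario_spec")
}

# Desk-scale default: a 4-layer FEN with a narrow first layer and a gentle
# pooling taper; converges within the 100-epoch scenario cap on the
# synthetic datasets.
scenario_fen_default <- function() {
  fen_spec(4L, channels = c(8L, 16L, 32L, 64L),
           pool_lengths = c(512L, 128L, 32L, 16L))
}

resolve_scenario_nn_spec <- function(spec) {
  if (!is.null(spec$nn_spec)) return(spec$nn_spec)
  if (length(spec$channels) == 1L) {
    scenario_fen_default()
  } else {
    pmldf_spec(stats::setNames(
      lapply(spec$channels, function(ch) scenario_fen_default()), spec$channels))
  }
}

match_feature_subset <- function(colnames_all, subset_suffixes) {
  keep <- colnames_all[sub("^(emg|pzt)_", "", colnames_all) %in% subset_suffixes]
  if (!length(keep)) stop("fixed feature subset matched no columns", call. = FALSE)
  keep
}

#' Run one scenario end to end
#'
#' Performs the stratified 60/20/20 split, applies augmentation to the
#' training partition only, runs feature extraction / selection or feeds raw
#' signals to the networks, trains the scenario's model, and evaluates it on
#' the held-out test partition. Deterministic given the spec's seed.
#'
#' @param trials Full list of `ssr_trial` objects (>= 5 per class).
#' @param spec An [scenario_spec()].
#' @return An `ssr_result` with accuracy (\%), macro-F1 (\%), 8x8 confusion
#'   matrix, chosen hyperparameters and a config snapshot.
#' @export
run_scenario <- function(trials, spec) {
  stopifnot(inherits(spec, "ssr_scenario_spec"))
  t0 <- proc.time()[["elapsed"]]
  split <- stratified_split(trials, c(0.6, 0.2, 0.2), seed = spec$seed)
  tr <- subset_trials(trials, split$train)
  va <- subset_trials(trials, split$validation)
  te <- subset_trials(trials, split$test)
  extra <- list(split = split)

  if (spec$kind == "features") {
    f_tr <- featurize_dataset(tr, spec$channels)
    f_va <- featurize_dataset(va, spec$channels)
    f_te <- featurize_dataset(te, spec$channels)
    xy_tr <- feature_xy(f_tr); xy_va <- feature_xy(f_va); xy_te <- feature_xy(f_te)
    lv <- levels(xy_tr$y)
    xy_va$y <- factor(as.character(xy_va$y), levels = lv)
    xy_te$y <- factor(as.character(xy_te$y), levels = lv)

    cols <- colnames(xy_tr$x)
    if (spec$optimized) {
      if (!is.null(spec$fixed_subset)) {
        cols <- match_feature_subset(cols, spec$fixed_subset)
      } else {
        ranking <- rfe_rank(xy_tr$x, xy_tr$y, seed = spec$seed)
        sel <- select_subset(ranking, xy_tr$x, xy_tr$y, xy_va$x, xy_va$y,
                             seed = spec$seed)
        cols <- sel$selected
        extra$selection <- sel
      }
    }
    x_tr <- xy_tr$x[, cols, drop = FALSE]
    y_tr <- xy_tr$y
    if (spec$augment) {
      sm <- smote_oversample(x_tr, y_tr, seed = spec$seed)
      x_tr <- sm$x; y_tr <- sm$y
    }
    model <- grid_search_train(x_tr, y_tr, xy_va$x[, cols, drop = FALSE], xy_va$y,
                               family = spec$model, grid = spec$grid,
                               seed = spec$seed)
    res <- evaluate_classic(model, xy_te$x[, cols, drop = FALSE], xy_te$y)
    res$hyperparams <- model$best
    extra$features <- cols
  } else {
    nn_spec <- resolve_scenario_nn_spec(spec)
    tr_aug <- if (spec$augment) augment_trials(tr, n_copies = 1L, seed = spec$seed) else tr
    model <- if (spec$model == "cnn") {
      cnn_train(tr_aug, va, channels = spec$channels, spec = nn_spec,
                config = spec$train_cfg)
    } else {
      snn_train(tr_aug, va, channels = spec$channels, spec = nn_spec,
                config = spec$train_cfg)
    }
    res <- evaluate_nn(model, te)
    res$hyperparams <- list(best_epoch = model$best_epoch,
                            best_val_acc = model$best_val_acc)
    extra$model <- model
  }
  res$config <- c(list(scenario = spec$id, input = spec$input, model = spec$model,
                       augment = spec$augment, seed = spec$seed), extra["split"])
  res$extra <- extra
  res$runtime_s <- proc.time()[["elapsed"]] - t0
  res
}

#' Run a batch of scenarios and tabulate the comparison
#'
#' @param trials Full list of `ssr_trial` objects.
#' @param scenarios Scenario ids to run (default all nine).
#' @param feature_models,raw_models Model families per scenario kind.
#' @param seed Integer seed shared by every scenario.
#' @param augment Apply training-set augmentation.
#' @param ... Passed to [scenario_spec()] (e.g. `nn_spec`, `train_cfg`).
#' @return An `ssr_run`: `results` (named list of `ssr_result` / error
#'   strings) and `table` (long data.frame: scenario, input, model,
#'   accuracy, macro_f1).
#' @export
run_all <- function(trials, scenarios = 1:9, feature_models = c("svm", "rf", "dt"),
                    raw_models = c("cnn", "snn"), seed = 1L, augment = TRUE, ...) {
  modes <- scenario_modes()
  results <- list()
  rows <- list()
  for (id in scenarios) {
    fams <- if (modes$kind[modes$id == id] == "features") feature_models else raw_models
    for (fam in fams) {
      key <- sprintf("s%d_%s", id, fam)
      res <- tryCatch(
        run_scenario(trials, scenario_spec(id, fam, augment = augment,
                                           seed = seed, ...)),
        error = function(e) conditionMessage(e)
      )
      results[[key]] <- res
      rows[[key]] <- data.frame(
        scenario = id, input = modes$input[modes$id == id], model = fam,
        accuracy = if (inherits(res, "ssr_result")) res$accuracy else NA_real_,
        macro_f1 = if (inherits(res, "ssr_result")) res$macro_f1 else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(results = results, table = do.call(rbind, rows), seed = seed),
            class = "ssr_run")
}

#' Format a scenario run as aligned comparison tables
#'
#' One block per scenario kind: rows are inputs, column pairs are accuracy
#' and F1 per model family.
#'
#' @param run An `ssr_run` from [run_all()].
#' @return Character vector of formatted lines.
#' @export
format_results_table <- function(run) {
  tb <- run$table
  out <- character(0)
  for (kind in c("features", "raw")) {
    ids <- scenario_modes()$id[scenario_modes()$kind == kind]
    sub <- tb[tb$scenario %in% ids, ]
    if (!nrow(sub)) next
    models <- unique(sub$model)
    header <- c("Training Inputs",
                paste0("Acc(", models, ")"), paste0("F1(", models, ")"))
    lines <- lapply(unique(sub$input), function(inp) {
      r <- sub[sub$input == inp, ]
      acc <- vapply(models, function(m) r$accuracy[r$model == m][1], numeric(1))
      f1 <- vapply(models, function(m) r$macro_f1[r$model == m][1], numeric(1))
      c(inp, sprintf("%.2f", acc), sprintf("%.2f", f1))
    })
    mat <- rbind(header, do.call(rbind, lines))
    widths <- apply(nchar(mat), 2L, max)
    fmt_row <- function(r) {
      paste(mapply(function(s, w) formatC(s, width = w, flag = "-"), r, widths),
            collapse = "  ")
    }
    out <- c(out,
             if (kind == "features") "Feature-based models" else "Raw-signal models",
             apply(mat, 1L, fmt_row), "")
  }
  out
}

#' @export
print.ssr_run <- function(x, ...) {
  cat(format_results_table(x), sep = "\n")
  invisible(x)
}
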
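# Feature-based classifiers (SVM / decision tree / random forest) with the
# exhaustive grid-search protocol: every grid point is trained on the
# training partition and scored on the validation partition; the best
# configuration (ties -> first in grid order) is refit and returned.

default_grid <- function(family) {
  switch(family,
    svm = expand.grid(cost = c(0.01, 0.1, 1, 10, 100),
                      kernel = c("radial", "linear", "polynomial"),
                      gamma = c(0.001, 0.01, 0.1, 1),
                      stringsAsFactors = FALSE),
    dt = expand.grid(maxdepth = c(3, 5, 10, 30), minbucket = c(1, 5, 10)),
    rf = expand.grid(num.trees = c(100, 300), max.depth = c(0, 10),
                     mtry_rule = c("sqrt", "all"), stringsAsFactors = FALSE),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

fit_classic <- function(family, cfg, x, y, seed, scale_stats = NULL) {
  if (family == "svm") {
    xs <- scale(x, scale_stats$center, scale_stats$scale)
    e1071::svm(x = xs, y = y, cost = cfg$cost, kernel = cfg$kernel,
               gamma = cfg$gamma, scale = FALSE)
  } else if (family == "dt") {
    df <- data.frame(.y = y, x, check.names = FALSE)
    rpart::rpart(.y ~ ., data = df, method = "class",
                 control = rpart::rpart.control(maxdepth = cfg$maxdepth,
                                                minbucket = cfg$minbucket,
                                                cp = 0.001, xval = 0))
  } else {
    mtry <- if (cfg$mtry_rule == "sqrt") max(1L, floor(sqrt(ncol(x)))) else ncol(x)
    ranger::ranger(x = as.data.frame(x), y = y, num.trees = cfg$num.trees,
                   max.depth = cfg$max.depth, mtry = mtry, seed = seed,
                   num.threads = 1L)
  }
}

predict_classic <- function(model, family, x, scale_stats = NULL) {
  if (family == "svm") {
    predict(model, scale(x, scale_stats$center, scale_stats$scale))
  } else if (family == "dt") {
    predict(model, newdata = data.frame(x, check.names = FALSE), type = "class")
  } else {
    predict(model, data = as.data.frame(x))$predictions
  }
}

#' Grid-search training of a feature-based classifier
#'
#' Exhaustively evaluates the hyperparameter grid, selecting the
#' configuration with the highest validation accuracy (ties go to the first
#' grid point), then refits it on the training partition. Features are
#' standardized with training-partition statistics for the SVM only (trees
#' are scale-invariant).
#'
#' @param x_train,y_train Training features (matrix) and labels.
#' @param x_val,y_val Validation features and labels; must be disjoint from
#'   training.
#' @param family `"svm"`, `"dt"` (decision tree) or `"rf"` (random forest).
#' @param grid Hyperparameter grid data.frame (default: [default_grid()]
#'   spanning several orders of magnitude for continuous parameters).
#' @param seed Integer seed.
#' @return An `ssr_classic_model`: fitted model, `best` configuration row,
#'   full validation `trace`, label levels and scaling statistics.
#' @export
grid_search_train <- function(x_train, y_train, x_val, y_val,
                              family = c("svm", "dt", "rf"), grid = NULL,
                              seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty", call. = FALSE)
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- factor(y_train)
  y_val <- factor(y_val, levels = levels(y_train))
  if (nlevels(y_train) < 2L) stop("need >= 2 classes", call. = FALSE)

  scale_stats <- NULL
  if (family == "svm") {
    ctr <- colMeans(x_train)
    scl <- apply(x_train, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    scale_stats <- list(center = ctr, scale = scl)
  }
  val_acc <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- with_seed(substream_seed(seed, i),
                     fit_classic(family, grid[i, , drop = FALSE], x_train, y_train,
                                 substream_seed(seed, i), scale_stats))
    mean(predict_classic(fit, family, x_val, scale_stats) == y_val)
  }, numeric(1))
  best_i <- which.max(val_acc)           # ties -> first in grid order
  best_cfg <- grid[best_i, , drop = FALSE]
  model <- with_seed(substream_seed(seed, best_i),
                     fit_classic(family, best_cfg, x_train, y_train,
                                 substream_seed(seed, best_i), scale_stats))
  structure(
    list(model = model, family = family, best = best_cfg, best_index = best_i,
         trace = cbind(grid, val_accuracy = val_acc),
         levels = levels(y_train), scale_stats = scale_stats, seed = seed),
    class = "ssr_classic_model"
  )
}

#' Evaluate a trained feature-based model on a test partition
#'
#' @param model An `ssr_classic_model` from [grid_search_train()].
#' @param x_test,y_test Test features and labels; labels must be a subset of
#'   the training label set.
#' @return An `ssr_result` with accuracy (\%), macro-F1 (\%) and the
#'   confusion matrix.
#' @export
evaluate_classic <- function(model, x_test, y_test) {
  stopifnot(inherits(model, "ssr_classic_model"))
  unknown <- setdiff(unique(as.character(y_test)), model$levels)
  if (length(unknown)) {
    stop("test labels outside the training label set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pred <- predict_classic(model$model, model$family, as.matrix(x_test),
                          model$scale_stats)
  scenario_result(as.character(y_test), as.character(pred), model$levels,
                  hyperparams = model$best)
}
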
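# Recursive Feature Elimination: backward elimination dropping the least
# important feature per refit until one remains, then validation-driven
# choice of the smallest near-optimal nested subset.

fit_importance <- function(x, y, importance = c("rf", "svm_weights"), seed,
                           num_trees = 200) {
  importance <- match.arg(importance)
  if (importance == "rf") {
    # permutation importance: a feature whose information is duplicated
    # elsewhere scores near zero (its marginal contribution is nil), which is
    # the elimination semantics wanted here
    # mtry = d so every split sees every feature: a duplicated feature is
    # shadowed by its copy and its permutation importance collapses
    fit <- ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = num_trees,
      importance = "permutation", seed = seed, num.threads = 1L,
      mtry = ncol(x)
    )
    imp <- fit$variable.importance
  } else {
    # linear multiclass SVM: importance_j = sum over pairwise machines of w_j^2
    xs <- scale(x)
    xs[!is.finite(xs)] <- 0
    fit <- e1071::svm(x = xs, y = y, kernel = "linear", scale = FALSE)
    w <- t(fit$coefs) %*% fit$SV          # aggregated weights
    imp <- colSums(w^2)
    names(imp) <- colnames(x)
  }
  imp[colnames(x)]
}

#' Recursive feature elimination ranking
#'
#' Starts from all features, refits the importance estimator, removes the
#' least important feature, and repeats until one feature remains. The round
#' at which a feature is eliminated is recorded (the survivor gets the final
#' round), so rounds are a permutation of `1..d`.
#'
#' @param x Numeric feature matrix (columns named).
#' @param y Class labels (factor or character).
#' @param importance Importance estimator: `"rf"` (impurity importance of a
#'   tree ensemble, default) or `"svm_weights"` (squared weights of a linear
#'   multiclass SVM).
#' @param seed Integer seed passed to the estimator.
#' @param num_trees Trees per ensemble refit.
#' @return An `ssr_ranking`: `elimination_order` (feature names, first
#'   eliminated first), `rounds` (named permutation of 1..d), and
#'   `subsets` (nested subsets along the path, largest first).
#' @export
rfe_rank <- function(x, y, importance = c("rf", "svm_weights"), seed = 1L,
                     num_trees = 200) {
  importance <- match.arg(importance)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (ncol(x) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (nlevels(y) < 2L) stop("labels are constant; RFE needs >= 2 classes", call. = FALSE)

  remaining <- colnames(x)
  order_out <- character(0)
  subsets <- list()
  round_i <- 1L
  while (length(remaining) > 1L) {
    subsets[[length(subsets) + 1L]] <- remaining
    imp <- fit_importance(x[, remaining, drop = FALSE], y, importance,
                          seed = substream_seed(seed, round_i), num_trees = num_trees)
    worst <- remaining[which.min(imp)]
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
    round_i <- round_i + 1L
  }
  subsets[[length(subsets) + 1L]] <- remaining
  order_out <- c(order_out, remaining)
  rounds <- seq_along(order_out)
  names(rounds) <- order_out
  structure(list(elimination_order = order_out, rounds = rounds, subsets = subsets,
                 importance = importance, num_trees = num_trees),
            class = "ssr_ranking")
}

#' Select the smallest near-optimal feature subset along the RFE path
#'
#' Each nested subset from the elimination path is evaluated by training the
#' importance estimator's model family on the training partition and scoring
#' accuracy on the validation partition; the smallest subset whose validation
#' accuracy is within `tolerance` of the best is returned (dimensionality
#' reduction is the point of the exercise).
#'
#' @param ranking An `ssr_ranking` from [rfe_rank()].
#' @param x_train,y_train Training features and labels.
#' @param x_val,y_val Validation features and labels (non-empty).
#' @param tolerance Accuracy slack for "near-optimal", as a fraction
#'   (default 0.005 = 0.5 percentage points).
#' @param seed Integer seed.
#' @return List: `selected` (feature names), `trace` (data.frame of subset
#'   size vs validation accuracy).
#' @export
select_subset <- function(ranking, x_train, y_train, x_val, y_val,
                          tolerance = 0.005, seed = 1L) {
  stopifnot(inherits(ranking, "ssr_ranking"))
  if (is.null(dim(x_val)) || nrow(x_val) == 0L) {
    stop("validation partition is empty", call. = FALSE)
  }
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- factor(y_train); y_val <- factor(y_val, levels = levels(y_train))
  accs <- vapply(seq_along(ranking$subsets), function(i) {
    feats <- ranking$subsets[[i]]
    if (ranking$importance == "rf") {
      fit <- ranger::ranger(x = as.data.frame(x_train[, feats, drop = FALSE]),
                            y = y_train, num.trees = ranking$num_trees,
                            seed = substream_seed(seed, i), num.threads = 1L)
      pred <- predict(fit, data = as.data.frame(x_val[, feats, drop = FALSE]))$predictions
    } else {
      ctr <- colMeans(x_train[, feats, drop = FALSE])
      scl <- apply(x_train[, feats, drop = FALSE], 2, stats::sd)
      scl[scl < 1e-12] <- 1
      xt <- scale(x_train[, feats, drop = FALSE], ctr, scl)
      xv <- scale(x_val[, feats, drop = FALSE], ctr, scl)
      fit <- e1071::svm(x = xt, y = y_train, kernel = "linear", scale = FALSE)
      pred <- predict(fit, xv)
    }
    mean(pred == y_val)
  }, numeric(1))
  sizes <- lengths(ranking$subsets)
  best <- max(accs)
  ok <- which(accs >= best - tolerance)
  pick <- ok[which.min(sizes[ok])]
  list(selected = ranking$subsets[[pick]],
       trace = data.frame(size = sizes, val_accuracy = accs))
}
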
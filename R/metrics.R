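# Classification metrics: confusion matrix, accuracy, macro-averaged F1.

#' Confusion matrix over a fixed label set
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Label set (default: union of observed labels, sorted).
#' @return Square integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth), as.character(pred))))
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  unclass(table(truth = truth, pred = pred))
}

#' Accuracy from a confusion matrix (fraction)
#' @param cm Square confusion matrix.
#' @export
accuracy_from_cm <- function(cm) sum(diag(cm)) / sum(cm)

#' Macro-averaged F1 from a confusion matrix (fraction)
#'
#' Per-class F1 = 2PR/(P+R) with the 0/0 case scored 0; the macro average is
#' the unweighted class mean (the protocol's classes are balanced).
#' @param cm Square confusion matrix.
#' @export
macro_f1_from_cm <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[, k])
    rec_den <- sum(cm[k, ])
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- if (rec_den > 0) tp / rec_den else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

# Assemble a ScenarioResult from truth/prediction vectors.
scenario_result <- function(truth, pred, levels, hyperparams = NULL,
                            config = NULL, runtime = NA_real_) {
  cm <- confusion_matrix(truth, pred, levels)
  structure(
    list(accuracy = 100 * accuracy_from_cm(cm),
         macro_f1 = 100 * macro_f1_from_cm(cm),
         confusion = cm, hyperparams = hyperparams, config = config,
         runtime_s = runtime),
    class = "ssr_result"
  )
}

#' @export
print.ssr_result <- function(x, ...) {
  cat(sprintf("<ssr_result: accuracy %.2f%%, macro-F1 %.2f%%, n = %d>\n",
              x$accuracy, x$macro_f1, sum(x$confusion)))
  invisible(x)
}
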
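#' Classification metrics for disease prediction
#'
#' AUC-ROC (via \pkg{pROC}), accuracy, precision, recall (sensitivity) and
#' F1 at the given probability threshold. When only one class is present the
#' AUC is undefined and reported as \code{NA}.
#'
#' @param probabilities numeric vector in [0, 1].
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold (default 0.5).
#' @return named list: \code{auc}, \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}, plus the confusion counts \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}.
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  ok <- !is.na(probabilities) & !is.na(labels)
  p <- probabilities[ok]; y <- as.integer(labels[ok])
  pred <- as.integer(p > threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- if (length(unique(y)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  } else NA_real_
  list(auc = auc, accuracy = (tp + tn) / length(y),
       precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
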
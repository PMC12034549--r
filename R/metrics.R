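#' Confusion matrix for binary labels
#'
#' Counts with 1 as the positive (anxious) class.
#'
#' @param truth,estimate Equal-length 0/1 vectors.
#' @return An object of class `ppd_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate lengths differ", class = "ppd_shape_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    abort("labels must be binary 0/1", class = "ppd_validation_error")
  }
  structure(
    list(tp = sum(truth == 1 & estimate == 1),
         fp = sum(truth == 0 & estimate == 1),
         fn = sum(truth == 1 & estimate == 0),
         tn = sum(truth == 0 & estimate == 0)),
    class = "ppd_confusion"
  )
}

#' @export
print.ppd_confusion <- function(x, ...) {
  cat("<ppd_confusion> tp =", x$tp, " fp =", x$fp,
      " fn =", x$fn, " tn =", x$tn, "\n")
  invisible(x)
}

# ratio with the zero-denominator convention: 0, plus the metric name
# recorded in the `flagged` accumulator of the caller
safe_ratio <- function(num, den) {
  if (den == 0) c(0, 1) else c(num / den, 0)
}

#' The nine-metric evaluation report
#'
#' Accuracy, precision, recall, F1-score, Matthews correlation coefficient,
#' specificity, negative predictive value, false positive rate and false
#' negative rate from a confusion matrix. Any metric whose denominator is
#' zero (possible on small test sets) is reported as 0 and its name listed
#' in the `flagged` column. The identities `fpr = 1 - specificity` and
#' `fnr = 1 - recall` hold whenever the corresponding denominators are
#' non-zero.
#'
#' @param x A `ppd_confusion`, or a 0/1 truth vector (with `estimate`
#'   supplied).
#' @param estimate 0/1 predicted labels when `x` is a truth vector.
#' @return A one-row tibble: the nine metrics, `n`, and `flagged`
#'   (comma-separated names of zero-denominator metrics, `""` if none).
#' @examples
#' metric_report(confusion_matrix(c(1, 1, 0), c(1, 0, 0)))
#' @export
metric_report <- function(x, estimate = NULL) {
  cm <- if (inherits(x, "ppd_confusion")) x else confusion_matrix(x, estimate)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0) abort("empty confusion matrix", class = "ppd_validation_error")
  flagged <- character(0)
  take <- function(name, num, den) {
    r <- safe_ratio(num, den)
    if (r[2] == 1) flagged <<- c(flagged, name)
    r[1]
  }
  precision <- take("precision", tp, tp + fp)
  recall <- take("recall", tp, tp + fn)
  f1 <- take("f1", 2 * precision * recall, precision + recall)
  specificity <- take("specificity", tn, tn + fp)
  npv <- take("npv", tn, tn + fn)
  fpr <- take("fpr", fp, fp + tn)
  fnr <- take("fnr", fn, fn + tp)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- take("mcc", as.numeric(tp) * tn - as.numeric(fp) * fn, mcc_den)
  tibble(accuracy = (tp + tn) / n, precision = precision, recall = recall,
         f1 = f1, mcc = mcc, specificity = specificity, npv = npv,
         fpr = fpr, fnr = fnr, n = n,
         flagged = paste(unique(flagged), collapse = ","))
}
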
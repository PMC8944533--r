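#' Three-class confusion matrix
#'
#' Cross-tabulates true against predicted locomotion score classes
#' (`0`, `1`, `>=2`): rows are the truth, columns the prediction.
#' `confusion_matrix3()` counts from paired class vectors;
#' `confusion_matrix3_from_counts()` wraps an existing 3 x 3 count matrix
#' (e.g. a published one).
#'
#' @param truth,predicted Vectors of classes (`0`, `1`, `>=2`, or locomotion
#'   scores coercible via [ls_class3()]), equal length.
#' @return A `confusion_matrix3` object (an integer matrix).
#' @export
#' @examples
#' confusion_matrix3(ls_class3(c(0, 1, 2, 2)), ls_class3(c(0, 1, 1, 2)))
confusion_matrix3 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "parlourscore_validation_error")
  }
  coerce <- function(x) {
    if (is.factor(x) && identical(levels(x), LS_CLASSES)) {
      return(x)
    }
    if (all(x %in% LS_CLASSES)) {
      return(factor(x, levels = LS_CLASSES))
    }
    ls_class3(x)
  }
  counts <- table(truth = coerce(truth), predicted = coerce(predicted))
  confusion_matrix3_from_counts(unclass(counts))
}

#' @rdname confusion_matrix3
#' @param counts A 3 x 3 matrix of non-negative counts, rows = true class.
#' @export
confusion_matrix3_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || anyNA(counts) || any(counts < 0)) {
    abort("`counts` must be a 3 x 3 matrix of non-negative counts.",
          class = "parlourscore_validation_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth = LS_CLASSES, predicted = LS_CLASSES)
  structure(counts, class = c("confusion_matrix3", "matrix"))
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("Confusion matrix (rows = locomotion score, columns = predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.4f\n", accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' The share of observations on the diagonal of the confusion matrix — the
#' ratio of correctly classified observations to the total.
#'
#' @param cm A [confusion_matrix3()].
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' cm <- confusion_matrix3_from_counts(
#'   rbind(c(697, 21, 0), c(4, 274, 2), c(0, 8, 24))
#' )
#' accuracy(cm)  # 0.966
accuracy <- function(cm) {
  if (!inherits(cm, "confusion_matrix3")) {
    abort("`cm` must be a `confusion_matrix3` object.",
          class = "parlourscore_argument_error")
  }
  total <- sum(cm)
  if (total == 0L) {
    abort("Empty confusion matrix.", class = "parlourscore_argument_error")
  }
  sum(diag(cm)) / total
}

#' Per-class one-vs-rest classifier metrics
#'
#' For each locomotion score class: true positive rate (class sensitivity,
#' `tp / (tp + fn)`), false positive rate (`fp / (fp + tn)`, i.e. one minus
#' the one-vs-rest specificity) and precision (`tp / (tp + fp)`). Metrics with
#' a zero denominator are returned as `NA` (undefined). Values are at full
#' precision; reports round to one decimal on the percent scale.
#'
#' @inheritParams accuracy
#' @return A tibble with columns `class`, `n`, `tpr`, `fpr`, `precision`.
#' @export
per_class_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix3")) {
    abort("`cm` must be a `confusion_matrix3` object.",
          class = "parlourscore_argument_error")
  }
  total <- sum(cm)
  purrr::map(seq_along(LS_CLASSES), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
    tibble::tibble(
      class = LS_CLASSES[i],
      n = sum(cm[i, ]),
      tpr = ratio(tp, tp + fn),
      fpr = ratio(fp, fp + tn),
      precision = ratio(tp, tp + fp)
    )
  }) |>
    dplyr::bind_rows()
}
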
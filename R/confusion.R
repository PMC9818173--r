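#' Confusion-matrix evaluation of a classifier
#'
#' Predicts on a labelled dataset and tallies the 9 x 9 confusion matrix
#' (rows true classes, columns predicted), its row-normalized form, the
#' 3 x 3 macro-class aggregation over healthy / ischemic / haemorrhagic,
#' and the overall and macro-class accuracies.
#'
#' @param model A `stroke_classifier` (or skip and pass predictions via
#'   [confusion_result()]).
#' @param data Labelled dataset to evaluate on.
#' @return A `confusion_result`; see [confusion_result()].
#' @export
evaluate_classifier <- function(model, data) {
  if (nrow(data) == 0) abort("empty test set")
  confusion_result(data$label, predict(model, data))
}

#' Build a confusion result from truth and predictions
#'
#' @param truth,predicted Factors/characters over [class_levels()].
#' @return A `confusion_result`: list with `counts` (9 x 9), `normalized`
#'   (row-normalized; zero rows stay zero), `macro` (3 x 3 counts),
#'   `macro_normalized`, `accuracy`, `macro_accuracy`, `n`.
#' @export
confusion_result <- function(truth, predicted) {
  lv <- class_levels()
  truth <- factor(as.character(truth), levels = lv)
  predicted <- factor(as.character(predicted), levels = lv)
  if (anyNA(truth) || anyNA(predicted)) {
    abort("labels outside the 9 admissible classes")
  }
  counts <- table(truth = truth, predicted = predicted)
  counts <- matrix(counts, 9, 9, dimnames = list(truth = lv, predicted = lv))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  mt <- macro_class(truth); mp <- macro_class(predicted)
  macro <- table(truth = mt, predicted = mp)
  macro <- matrix(macro, 3, 3, dimnames = list(truth = levels(mt),
                                               predicted = levels(mt)))
  mrs <- rowSums(macro)
  structure(list(
    counts = counts, normalized = normalized, macro = macro,
    macro_normalized = macro / ifelse(mrs == 0, 1, mrs),
    accuracy = sum(diag(counts)) / sum(counts),
    macro_accuracy = sum(diag(macro)) / sum(macro),
    n = sum(counts)
  ), class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat("<confusion_result> n =", x$n,
      " accuracy =", format(x$accuracy, digits = 4),
      " macro accuracy =", format(x$macro_accuracy, digits = 4), "\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a confusion result into a long tibble
#' @param x A `confusion_result`.
#' @param ... Unused.
#' @return Tibble with `truth`, `predicted`, `count`, `proportion`.
#' @export
tidy.confusion_result <- function(x, ...) {
  lv <- class_levels()
  tibble::tibble(
    truth = factor(rep(lv, times = 9), levels = lv),
    predicted = factor(rep(lv, each = 9), levels = lv),
    count = as.vector(x$counts),
    proportion = as.vector(x$normalized)
  )
}

#' One-row accuracy summary of a confusion result
#' @param x A `confusion_result`.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `macro_accuracy`,
#'   `misclassification` (percent).
#' @export
glance.confusion_result <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_accuracy = x$macro_accuracy,
                 misclassification = 100 * (1 - x$accuracy))
}

#' Report a confusion result as JSON
#' @param x A `confusion_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(x, path) {
  jsonlite::write_json(
    list(counts = x$counts, normalized = x$normalized, macro = x$macro,
         macro_normalized = x$macro_normalized, accuracy = x$accuracy,
         macro_accuracy = x$macro_accuracy, n = x$n),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
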
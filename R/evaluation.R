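#' Confusion matrix over the four epileptic states
#'
#' @param true_labels,predicted_labels Equal-length vectors/factors over
#'   [state_labels()] (or the supplied `levels`).
#' @param levels Class order (default [state_labels()]).
#' @return Object of class `confusion_matrix`: integer `counts` (rows = true,
#'   columns = predicted) plus the class order.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             levels = state_labels()) {
  t_ <- as.character(true_labels)
  p_ <- as.character(predicted_labels)
  if (length(t_) != length(p_))
    stopf("label vectors differ in length (%d vs %d)", length(t_), length(p_))
  bad <- setdiff(unique(c(t_, p_)), levels)
  if (length(bad))
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  counts <- table(factor(t_, levels = levels), factor(p_, levels = levels))
  counts <- matrix(as.integer(counts), length(levels), length(levels),
                   dimnames = list(true = levels, predicted = levels))
  structure(list(counts = counts, class_order = levels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Row-normalized confusion matrix (per-class classification rates)
#' @param cm A [confusion_matrix()].
#' @return Matrix of row proportions (rows with no samples give NaN).
#' @export
confusion_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sweep(cm$counts, 1, rowSums(cm$counts), "/")
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' The binary definitions `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)` and `accuracy = (TP+TN)/total` are applied
#' one-vs-rest per class; overall accuracy is `trace/total`. Classes with a
#' zero denominator report `NA` (undefined), not 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report`: list with `overall_accuracy` and
#'   a `per_class` data frame (TP, FN, FP, TN, sensitivity, specificity,
#'   accuracy).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- cm$counts
  total <- sum(M)
  if (total == 0) stopf("empty confusion matrix")
  tp <- diag(M)
  fn <- rowSums(M) - tp
  fp <- colSums(M) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  per_class <- data.frame(
    class = cm$class_order,
    TP = as.integer(tp), FN = as.integer(fn), FP = as.integer(fp),
    TN = as.integer(tn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / total,
    row.names = NULL)
  structure(list(overall_accuracy = sum(tp) / total, per_class = per_class,
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.4f on %d samples\n",
              x$overall_accuracy, x$total))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Write / read a metrics report (JSON) and confusion matrix (CSV)
#'
#' @param report A [metrics()] result.
#' @param cm The matching [confusion_matrix()].
#' @param dir Output directory; writes `metrics.json`, `confusion_counts.csv`
#'   and `confusion_rates.csv`.
#' @return `dir` invisibly; `read_metrics()` returns the report and counts.
#' @export
write_metrics <- function(report, cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(overall_accuracy = report$overall_accuracy, total = report$total,
         per_class = report$per_class),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cm$counts, file.path(dir, "confusion_counts.csv"))
  utils::write.csv(confusion_rates(cm), file.path(dir, "confusion_rates.csv"))
  invisible(dir)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "metrics.json"),
                           simplifyVector = TRUE)
  counts <- as.matrix(utils::read.csv(file.path(dir, "confusion_counts.csv"),
                                      row.names = 1, check.names = FALSE))
  list(overall_accuracy = j$overall_accuracy, total = j$total,
       per_class = j$per_class, counts = counts)
}
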
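#' Confusion matrix from label vectors
#'
#' `counts[i, j]` is the number of samples with true class `i` and
#' predicted class `j` (0-based labels, 1-based matrix indices).
#'
#' @param true_labels,predicted_labels Integer vectors of 0-based labels
#'   of equal length, values in `[0, K)`.
#' @param K Number of classes.
#' @param class_names Optional class names for dimnames.
#' @return An object of class `confusion_matrix`: a `K x K` integer
#'   matrix with rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, K,
                             class_names = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length", call. = FALSE)
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (any(c(true_labels, predicted_labels) < 0L) ||
      any(c(true_labels, predicted_labels) >= K))
    stop(sprintf("labels must lie in [0, %d)", K), call. = FALSE)
  lev <- 0:(K - 1L)
  cm <- unname(as.matrix(table(factor(true_labels, levels = lev),
                               factor(predicted_labels, levels = lev))))
  storage.mode(cm) <- "integer"
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Accuracy and per-class/macro recall and precision
#'
#' Accuracy is `trace / total`; per-class recall divides the diagonal by
#' its row sum, precision by its column sum; macro values are unweighted
#' means over classes. A class never predicted (zero column sum)
#' contributes precision 0 -- the pessimistic convention, documented here.
#'
#' @param cm A [confusion_matrix()] (any square count matrix works).
#' @return List with `accuracy`, `per_class_recall`,
#'   `per_class_precision`, `macro_recall`, `macro_precision`.
#' @examples
#' cm <- matrix(c(26, 0, 0, 1, 20, 0, 0, 1, 13), 3, 3)
#' metrics_from_confusion(cm)$accuracy  # 59/61
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts", call. = FALSE)
  diag_c <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  recall <- ifelse(rs > 0, diag_c / rs, 0)
  precision <- ifelse(cs > 0, diag_c / cs, 0)
  list(accuracy = sum(diag_c) / total,
       per_class_recall = recall,
       per_class_precision = precision,
       macro_recall = mean(recall),
       macro_precision = mean(precision))
}

#' Evaluate a model on a test set
#'
#' Predicts by argmax over softmax probabilities (ties toward the lower
#' class index) and returns the confusion matrix together with its
#' metrics.
#'
#' @param model A `resmini_model`.
#' @param test_set List with `x` and 0-based labels `y`, e.g. from
#'   [load_dataset()].
#' @param class_names Optional class names for the matrix dimnames.
#' @return List with `confusion` ([confusion_matrix()]) and `metrics`
#'   ([metrics_from_confusion()]).
#' @export
evaluate <- function(model, test_set, class_names = NULL) {
  y <- as.integer(test_set$y)
  if (length(y) == 0L) stop("empty test set", call. = FALSE)
  K <- model$config$num_classes
  check_labels(y, K)
  pred <- predict_classes(model, test_set$x)
  cm <- confusion_matrix(y, pred, K, class_names)
  list(confusion = cm, metrics = metrics_from_confusion(cm))
}

#' Parameter-economy comparison report
#'
#' Tabulates accuracy and total parameter count per model and the full
#' matrix of pairwise parameter ratios (each model's total as a
#' percentage of every other's, rounded to 2 decimals) -- the form in
#' which small networks are compared against larger baselines.
#'
#' @param totals Named numeric vector of total parameter counts.
#' @param accuracies Optional named numeric vector of accuracies
#'   (aligned with `totals`).
#' @return An object of class `comparison_report`: list with `table`
#'   (data frame of model, parameters, accuracy) and `ratio_percent`
#'   (matrix; entry `[i, j]` is `100 * totals[i] / totals[j]`, 2 d.p.).
#' @examples
#' comparison_report(c(small = 98907, large = 196595))$ratio_percent
#' @export
comparison_report <- function(totals, accuracies = NULL) {
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("totals must be named", call. = FALSE)
  n <- length(totals)
  ratio <- round(100 * outer(totals, totals, "/"), 2)
  dimnames(ratio) <- list(names(totals), names(totals))
  tab <- data.frame(model = names(totals),
                    parameters = as.numeric(totals),
                    accuracy = if (is.null(accuracies)) NA_real_
                               else as.numeric(accuracies[names(totals)]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ratio_percent = ratio),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%-12s %14s %10s\n", "model", "parameters", "accuracy"))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("%-12s %14s %10s\n", x$table$model[i],
                format(x$table$parameters[i], big.mark = ","),
                ifelse(is.na(x$table$accuracy[i]), "-",
                       sprintf("%.3f", x$table$accuracy[i]))))
  cat("\nparameter ratios (% of column model):\n")
  print(x$ratio_percent)
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' @param cm A [confusion_matrix()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
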
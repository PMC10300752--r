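#' Classification accuracy in percent
#'
#' `100 x (number of matching pairs) / (number of pairs)` — the fraction of
#' test samples whose predicted label equals the true label.
#'
#' @param predictions,truths equal-length label vectors (factor, character
#'   or integer).
#' @return accuracy in percent.
#' @export
accuracy_pct <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (length(truths) == 0L) stop("empty input")
  100 * mean(as.character(predictions) == as.character(truths))
}

#' Confusion matrix and per-class recall
#'
#' Rows are true labels, columns predicted labels.  Recall per class is the
#' diagonal over the row sum; the row-normalized matrix divides each row by
#' its sum.  A class absent from the truths yields an undefined (`NA`)
#' recall and normalized row — never a silent zero.
#'
#' @param predictions,truths label vectors.
#' @param class_order the fixed class order; defaults to
#'   [breathing_conditions()].
#' @return list with `confusion` (counts), `normalized` (row-normalized),
#'   and `recall` (named vector, `NA` where undefined).
#' @export
confusion_and_recall <- function(predictions, truths,
                                 class_order = breathing_conditions()) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  unknown <- setdiff(unique(c(predictions, truths)), class_order)
  if (length(unknown))
    stop("label(s) outside class order: ", paste(unknown, collapse = ", "))
  p <- factor(predictions, levels = class_order)
  t_ <- factor(truths, levels = class_order)
  confusion <- table(true = t_, predicted = p)
  rs <- rowSums(confusion)
  normalized <- sweep(confusion, 1L, rs, "/")       # NaN rows where rs == 0
  normalized[rs == 0L, ] <- NA_real_
  recall <- diag(confusion) / rs
  recall[rs == 0L] <- NA_real_
  list(confusion = unclass(confusion), normalized = unclass(normalized),
       recall = stats::setNames(as.numeric(recall), class_order))
}

#' Balanced accuracy in percent
#'
#' The unweighted mean of the per-class recalls, times 100 — insensitive to
#' class imbalance, unlike plain accuracy.
#'
#' @param per_class_recall numeric vector of per-class recall fractions.
#' @return balanced accuracy in percent.
#' @export
balanced_accuracy_pct <- function(per_class_recall) {
  if (anyNA(per_class_recall))
    stop("undefined recall (empty class); balanced accuracy is undefined")
  100 * mean(per_class_recall)
}

#' Build an evaluation report
#'
#' Bundles overall accuracy, the confusion matrix (counts and row-
#' normalized), per-class recall and balanced accuracy; optionally attaches
#' a repeated-run (mean, STD, best) accuracy summary.
#'
#' @inheritParams confusion_and_recall
#' @param repeats optional named list or vector with elements `mean`, `sd`,
#'   `best` from a repeated-run experiment.
#' @return an object of class `"eval_report"`.
#' @export
eval_report <- function(predictions, truths,
                        class_order = breathing_conditions(),
                        repeats = NULL) {
  cr <- confusion_and_recall(predictions, truths, class_order)
  rep <- structure(list(n_test = length(truths),
                        accuracy = accuracy_pct(predictions, truths),
                        per_class_recall = cr$recall,
                        balanced_accuracy = if (anyNA(cr$recall)) NA_real_
                        else balanced_accuracy_pct(cr$recall),
                        confusion = cr$confusion,
                        confusion_normalized = cr$normalized,
                        repeats = repeats),
                   class = "eval_report")
  rep
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("Evaluation on %d windows\n", x$n_test))
  cat(sprintf("  accuracy:          %.*f%%\n", digits, x$accuracy))
  if (is.na(x$balanced_accuracy)) {
    cat("  balanced accuracy: undefined (a class is empty in the test set)\n")
  } else {
    cat(sprintf("  balanced accuracy: %.*f%%\n", digits,
                x$balanced_accuracy))
  }
  cat("  per-class recall:\n")
  for (cl in names(x$per_class_recall)) {
    r <- x$per_class_recall[[cl]]
    cat(sprintf("    %-14s %s\n", cl,
                if (is.na(r)) "undefined" else sprintf("%.*f", digits, r)))
  }
  cat("  confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  if (!is.null(x$repeats))
    cat(sprintf("  repeated runs: mean %.*f%%, STD %.*f, best %.*f%%\n",
                digits, x$repeats$mean, 3, x$repeats$sd, digits,
                x$repeats$best))
  invisible(x)
}

# plain-list view for JSON serialisation
report_to_list <- function(x) {
  list(n_test = x$n_test,
       accuracy = x$accuracy,
       balanced_accuracy = x$balanced_accuracy,
       per_class_recall = as.list(x$per_class_recall),
       confusion = apply(x$confusion, 1L, as.list, simplify = FALSE),
       confusion_normalized = apply(x$confusion_normalized, 1L, as.list,
                                    simplify = FALSE),
       repeats = x$repeats)
}

#' Write an evaluation report as JSON
#'
#' @param report an [eval_report()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
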
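# Multiclass evaluation: confusion matrices, precision/recall/F, accuracy,
# balanced accuracy, support-weighted averages, and reconstruction of
# integer confusion counts from rounded published metrics.

# half-up rounding to 2 decimals, as used for report display
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Confusion matrix
#'
#' Rows are true labels, columns predicted labels, in the order given by
#' `label_order`. Any label outside `label_order` is an error.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param label_order Class order (default [mas_levels()]).
#' @param normalize If `TRUE`, rows are normalised to sum to 1 (empty rows
#'   stay zero).
#' @return Integer (or row-normalised numeric) matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, label_order = mas_levels(),
                             normalize = FALSE) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  bad <- setdiff(unique(c(y_true, y_pred)), label_order)
  if (length(bad)) {
    stop("label(s) outside label_order: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(y_true, levels = label_order),
             factor(y_pred, levels = label_order))
  m <- matrix(as.integer(m), nrow = length(label_order),
              dimnames = list(true = label_order, predicted = label_order))
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  m
}

#' Per-class precision, recall and F-measure
#'
#' For each class: precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F = the harmonic mean of the two. Zero-division cases are reported as 0
#' with the `zero_division` flag set.
#'
#' @param confusion Confusion matrix (rows true, columns predicted).
#' @return data.frame with columns `label`, `precision`, `recall`, `f`,
#'   `support`, `zero_division`.
#' @export
precision_recall_f <- function(confusion) {
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  supp <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(supp > 0, tp / supp, 0)
  pr <- precision + recall
  f <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  data.frame(label = rownames(confusion), precision = as.numeric(precision),
             recall = as.numeric(recall), f = as.numeric(f),
             support = as.integer(supp),
             zero_division = pred_n == 0 | supp == 0 | pr == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classification accuracy
#'
#' Fraction of correct classifications: the confusion-matrix trace over its
#' total.
#'
#' @param confusion Confusion matrix.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' Balanced accuracy
#'
#' The (sample-weighted) mean of per-class recall, averaged over the
#' classes present in `y_true`. Equals plain accuracy when class sizes are
#' equal.
#'
#' @param y_true,y_pred Label vectors.
#' @param sample_weights Optional non-negative per-sample weights.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred, sample_weights = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  w <- if (is.null(sample_weights)) rep(1, length(y_true)) else sample_weights
  recalls <- vapply(unique(y_true), function(cl) {
    in_cl <- y_true == cl
    sum(w[in_cl & y_pred == cl]) / sum(w[in_cl])
  }, numeric(1))
  mean(recalls)
}

#' Support-weighted average of per-class metrics
#'
#' Weighted means of the (unrounded) per-class precision, recall and F,
#' with the class supports as weights. Note the algebraic identity:
#' support-weighted recall equals plain accuracy.
#'
#' @param per_class data.frame from [precision_recall_f()] (or any frame
#'   with `precision`, `recall`, `f` columns).
#' @param supports Per-class supports; defaults to `per_class$support`.
#' @return Named numeric vector `precision`, `recall`, `f`.
#' @export
weighted_average <- function(per_class, supports = per_class$support) {
  if (length(supports) != nrow(per_class)) {
    stop("supports length does not match the number of classes")
  }
  w <- supports / sum(supports)
  c(precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f = sum(w * per_class$f))
}

#' Reconstruct integer confusion counts from rounded metrics
#'
#' Given a class's precision and recall rounded to two decimals and its
#' integer support, searches exhaustively for the unique pair of integers
#' (true positives, predicted count) consistent with the rounding. Used to
#' verify published metric tables where only rounded values are printed.
#'
#' @param precision,recall Rounded (2 dp) per-class values.
#' @param support Class support (true count).
#' @param max_predicted Upper bound for the predicted count (e.g. the test
#'   set size).
#' @return List with integer `tp` and `predicted`.
#' @export
#' @examples
#' reconstruct_counts(0.50, 0.43, support = 7, max_predicted = 27)
reconstruct_counts <- function(precision, recall, support, max_predicted) {
  sols <- list()
  for (tp in 0:support) {
    if (.round2(ifelse(support > 0, tp / support, 0)) != .round2(recall)) next
    lo <- max(tp, 1L)
    for (pp in lo:max_predicted) {
      if (.round2(tp / pp) == .round2(precision)) {
        sols[[length(sols) + 1L]] <- list(tp = tp, predicted = pp)
      }
    }
    if (tp == 0 && .round2(precision) == 0) {
      # tp = 0 makes precision 0 for every predicted count: ambiguous unless
      # no other tp matched
      sols[[length(sols) + 1L]] <- list(tp = 0L, predicted = NA_integer_)
    }
  }
  tps <- unique(vapply(sols, `[[`, numeric(1), "tp"))
  if (length(sols) == 0L) {
    stop("no integer counts consistent with precision ", precision,
         " and recall ", recall, " at support ", support)
  }
  if (length(tps) > 1L || (length(sols) > 1L && length(tps) == 1L)) {
    cand <- vapply(sols, function(s) paste0("tp=", s$tp, ",pred=", s$predicted),
                   character(1))
    stop("ambiguous reconstruction; candidates: ", paste(cand, collapse = "; "))
  }
  list(tp = as.integer(sols[[1]]$tp), predicted = as.integer(sols[[1]]$predicted))
}

#' Full evaluation report for a prediction batch
#'
#' @param y_true,y_pred Label vectors.
#' @param label_order Class order (default [mas_levels()]).
#' @return Object of class `evaluation_report`: `labels`, `confusion`,
#'   `per_class`, `accuracy`, `balanced_accuracy`, `weighted`.
#' @export
evaluation_report <- function(y_true, y_pred, label_order = mas_levels()) {
  cm <- confusion_matrix(y_true, y_pred, label_order)
  present <- rowSums(cm) > 0
  pc <- precision_recall_f(cm)[present, , drop = FALSE]
  rownames(pc) <- NULL
  structure(list(labels = label_order, confusion = cm, per_class = pc,
                 accuracy = accuracy(cm),
                 balanced_accuracy = balanced_accuracy(y_true, y_pred),
                 weighted = weighted_average(pc)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("MAS classification report\n")
  cat(sprintf("  accuracy: %.2f  balanced accuracy: %.2f\n",
              .round2(x$accuracy), .round2(x$balanced_accuracy)))
  pc <- x$per_class
  pc[c("precision", "recall", "f")] <- lapply(pc[c("precision", "recall", "f")],
                                              .round2)
  print(pc[c("label", "precision", "recall", "f", "support")], row.names = FALSE)
  cat(sprintf("  weighted avg: P %.2f  R %.2f  F %.2f\n",
              .round2(x$weighted["precision"]), .round2(x$weighted["recall"]),
              .round2(x$weighted["f"])))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(list(
    labels = report$labels,
    confusion = unname(apply(report$confusion, 1L, as.integer, simplify = FALSE)),
    per_class = report$per_class,
    accuracy = report$accuracy,
    balanced_accuracy = report$balanced_accuracy,
    weighted = as.list(report$weighted)),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
}

#' Reference per-class validation metrics of the clinical study
#'
#' Per-class precision, recall and support of the five baseline classifiers
#' and the Logical-SVM-RF cascade, as reported (rounded to two decimals) in
#' the clinical validation of the method this package implements. Bundled
#' so that the metric arithmetic — count reconstruction, F-measures,
#' support-weighted averages — can be recomputed and verified.
#'
#' @return data.frame with columns `classifier`, `mas_level`, `precision`,
#'   `recall`, `support`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv",
                      package = "spastimas", mustWork = TRUE)
  read.csv(path, check.names = FALSE, colClasses = c(
    classifier = "character", mas_level = "character",
    precision = "numeric", recall = "numeric", support = "integer"))
}
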
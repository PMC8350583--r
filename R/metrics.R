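#' Classification metrics from gold and predicted labels
#'
#' Builds the `c x c` confusion matrix (rows = true class, columns =
#' predicted) and derives per-class precision, recall and F1, their
#' support-weighted averages, and the row-normalized confusion matrix
#' (each true-class row divided by its support). A class never predicted
#' has precision 0; a class with zero support has recall 0 and its
#' normalized row is left as zeros.
#'
#' @param gold integer vector of 0-based true classes.
#' @param pred integer vector of 0-based predicted classes.
#' @param n_classes number of classes.
#' @param labels optional class names.
#' @return object of class `trnn_metrics`: list with `confusion`,
#'   `confusion_normalized`, `per_class` (data.frame of precision, recall,
#'   f1, support) and `weighted` (named vector precision/recall/f1).
#' @export
compute_metrics <- function(gold, pred, n_classes = 3, labels = NULL) {
  stopifnot(length(gold) == length(pred), length(gold) > 0,
            all(gold >= 0), all(gold < n_classes),
            all(pred >= 0), all(pred < n_classes))
  if (is.null(labels)) labels <- paste0("class_", seq_len(n_classes) - 1)
  cm <- matrix(0, n_classes, n_classes, dimnames = list(labels, labels))
  for (i in seq_along(gold)) {
    cm[gold[i] + 1L, pred[i] + 1L] <- cm[gold[i] + 1L, pred[i] + 1L] + 1
  }
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  weighted <- c(precision = sum(w * precision), recall = sum(w * recall),
                f1 = sum(w * f1))
  cmn <- cm
  nz <- support > 0
  cmn[nz, ] <- cm[nz, , drop = FALSE] / support[nz]
  structure(list(confusion = cm, confusion_normalized = cmn,
                 per_class = data.frame(class = labels, precision = precision,
                                        recall = recall, f1 = f1,
                                        support = support,
                                        row.names = NULL),
                 weighted = weighted),
            class = "trnn_metrics")
}

#' @export
print.trnn_metrics <- function(x, digits = 3, ...) {
  cat("Classification metrics\n")
  pc <- x$per_class
  cat(sprintf("  %-16s %9s %9s %9s %9s\n", "class", "P", "R", "F1", "support"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-16s %9.*f %9.*f %9.*f %9d\n", pc$class[i],
                digits, pc$precision[i], digits, pc$recall[i],
                digits, pc$f1[i], as.integer(pc$support[i])))
  }
  cat(sprintf("  %-16s %9.*f %9.*f %9.*f %9d\n", "weighted avg",
              digits, x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"], as.integer(sum(pc$support))))
  invisible(x)
}

#' Write metrics as JSON and the confusion matrix as CSV
#'
#' @param metrics a `trnn_metrics`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
write_metrics <- function(metrics, json_path = NULL, csv_path = NULL) {
  out <- list(per_class = metrics$per_class,
              weighted = as.list(metrics$weighted),
              confusion = unname(apply(metrics$confusion, 1, as.numeric,
                                       simplify = FALSE)),
              confusion_normalized = unname(apply(metrics$confusion_normalized,
                                                  1, as.numeric,
                                                  simplify = FALSE)))
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(metrics$confusion), csv_path)
  }
  invisible(out)
}

#' Evaluate a fitted model on a labeled corpus
#'
#' Deterministic (dropout off) forward pass over the corpus, argmax
#' prediction with lowest-index tie-break, and full metric computation.
#'
#' @param object a fitted `trnn` model.
#' @param corpus a non-empty `labeled_corpus`.
#' @param ... unused.
#' @return a `trnn_metrics` object.
#' @export
evaluate <- function(object, corpus, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.trnn <- function(object, corpus, ...) {
  stopifnot(inherits(corpus, "labeled_corpus"), length(corpus) > 0)
  evaluate_params(object$params, corpus, object$vocab, object$config,
                  object$label_set, batch_size = object$control$batch_size)
}
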
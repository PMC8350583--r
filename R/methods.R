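#' @export
print.trnn <- function(x, ...) {
  cat("TransformerRNN text classifier\n")
  cat("  classes:", paste(x$label_set, collapse = ", "), "\n")
  cat("  vocabulary:", x$vocab$size, "ids |",
      format(trnn_param_count(x$config, x$vocab$size), big.mark = ","),
      "parameters\n")
  cat(sprintf("  trained %d epoch(s); best epoch %d", nrow(x$history),
              x$best_epoch))
  f1 <- x$history$val_f1[x$best_epoch]
  if (length(f1) == 1 && !is.na(f1)) cat(sprintf(" (val weighted F1 %.3f)", f1))
  cat("\n")
  invisible(x)
}

#' @export
summary.trnn <- function(object, ...) {
  print(object)
  print(object$config)
  h <- object$history
  cat(sprintf("  final train loss %.4f | train accuracy %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!is.null(object$embedding_coverage)) {
    cat(sprintf("  pretrained embedding coverage: %.1f%%\n",
                100 * object$embedding_coverage))
  }
  invisible(object)
}

#' Extract model weights
#' @param object a fitted `trnn`.
#' @param ... unused.
#' @return flat named list of weight arrays (embedding, encoder, BiLSTM,
#'   classifier).
#' @export
coef.trnn <- function(object, ...) flatten_params(object$params)

#' Plot the training history
#' @param x a fitted `trnn`.
#' @param ... passed to [plot()].
#' @return invisibly, the history data.frame.
#' @export
plot.trnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = "Cross-entropy", ...)
  if (any(!is.na(h$val_f1))) {
    plot(h$epoch, h$val_f1, type = "b", xlab = "epoch",
         ylab = "validation weighted F1", main = "Validation F1", ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  } else {
    plot(h$epoch, h$train_acc, type = "b", xlab = "epoch",
         ylab = "training accuracy", main = "Training accuracy", ...)
  }
  invisible(h)
}

#' Predict classes for new texts
#'
#' Tokenizes and encodes the inputs with the model's vocabulary (unknown
#' tokens map to OOV, documents longer than `max_len` are truncated) and
#' runs a deterministic forward pass. Padding is fully masked, so batch
#' composition does not affect any prediction. Records with empty text get
#' `NA` predictions and a warning rather than failing the whole call.
#'
#' @param object a fitted `trnn`.
#' @param newdata character vector of texts, or a `labeled_corpus`.
#' @param type `"class"` for labels, `"prob"` for the probability matrix,
#'   `"both"` for a list of the two.
#' @param ... unused.
#' @return per `type`: a character vector of labels, a numeric matrix
#'   (rows summing to 1), or both.
#' @export
predict.trnn <- function(object, newdata, type = c("class", "prob", "both"),
                         ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_corpus")) {
    docs <- newdata$documents
  } else {
    stopifnot(is.character(newdata))
    docs <- lapply(newdata, function(tx) list(text = tx, tokens = tokenize(tx)))
  }
  n <- length(docs)
  empty <- vapply(docs, function(d) length(d$tokens) == 0, logical(1))
  if (any(empty)) {
    warning(sum(empty), " empty record(s); returning NA for them")
  }
  probs <- matrix(NA_real_, n, object$config$n_classes,
                  dimnames = list(NULL, object$label_set))
  keep <- which(!empty)
  if (length(keep) > 0) {
    lens <- vapply(docs[keep], function(d) length(d$tokens), integer(1))
    ord <- keep[order(lens, method = "radix")]
    bs <- object$control$batch_size
    for (s in seq(1, length(ord), by = bs)) {
      bi <- ord[s:min(s + bs - 1, length(ord))]
      bmax <- min(object$config$max_len,
                  max(vapply(docs[bi], function(d) length(d$tokens), integer(1))))
      batch <- encode_batch(docs[bi], object$vocab, max_len = bmax)
      fwd <- trnn_forward(object$params, batch, object$config,
                          train_mode = FALSE)
      probs[bi, ] <- fwd$probs
    }
  }
  cls <- rep(NA_character_, n)
  if (length(keep) > 0) {
    cls[keep] <- object$label_set[max.col(probs[keep, , drop = FALSE],
                                          ties.method = "first")]
  }
  switch(type, class = cls, prob = probs, both = list(class = cls, prob = probs))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the configuration, the
#' vocabulary, every weight array and a format version, written with R's
#' native serialization.
#'
#' @param object a fitted `trnn`.
#' @param path checkpoint file path.
#' @return `save_trnn`: `path` invisibly. `load_trnn`: the restored `trnn`.
#' @export
save_trnn <- function(object, path) {
  stopifnot(inherits(object, "trnn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_trnn
#' @export
load_trnn <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "trnn")) stop(path, " is not a trnn checkpoint")
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported checkpoint version: ", obj$version)
  }
  obj
}
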
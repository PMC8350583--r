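# Adaptive moment estimation, operating on flat named parameter lists.
adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Training control parameters
#'
#' Defaults follow the published training setup where one is stated
#' (learning rate 0.0005, mini-batch size 64); the optimizer (adaptive
#' moment estimation), epoch budget and early-stopping rule are this
#' package's choices.
#'
#' @param lr initial learning rate (> 0).
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping;
#'   `patience = 0` stops after the first non-improving epoch; capped at
#'   `max_epochs`. Ignored when no validation corpus is given.
#' @param seed master seed for initialization, shuffling and dropout.
#' @param min_freq minimum token frequency for the vocabulary.
#' @param target_train_acc optional early exit: stop once training accuracy
#'   reaches this value (useful for capacity checks).
#' @param stop_at_val_f1 optional early exit: stop once validation weighted
#'   F1 reaches this value (e.g. 1.0 — no further improvement is possible,
#'   so waiting out the patience window only costs time). The best-epoch
#'   weights are restored as usual.
#' @param verbose print a line per epoch.
#' @return object of class `trnn_control`.
#' @export
trnn_control <- function(lr = 5e-4, batch_size = 64, max_epochs = 100,
                         patience = 10, seed = 1, min_freq = 1,
                         target_train_acc = NULL, stop_at_val_f1 = NULL,
                         verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 0)
  patience <- min(patience, max_epochs)
  structure(list(lr = lr, batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seed = seed, min_freq = min_freq,
                 target_train_acc = target_train_acc,
                 stop_at_val_f1 = stop_at_val_f1, verbose = verbose),
            class = "trnn_control")
}

#' Fit the TransformerRNN classifier
#'
#' Trains the hybrid transformer-encoder/BiLSTM network on a labeled
#' corpus: tokens are embedded (optionally from pretrained GloVe-format
#' vectors), contextualized by a multi-head self-attention encoder,
#' concatenated with the raw embeddings, passed through a BiLSTM, reduced
#' by masked temporal max-pooling, and classified by a softmax layer.
#' Optimization is adaptive-moment gradient descent on the mean
#' cross-entropy, with seeded shuffling and dropout, early stopping on
#' validation weighted F1, and restoration of the best-epoch weights.
#'
#' The vocabulary is built from the training corpus only. Batches are
#' formed by grouping documents of similar length after a seeded shuffle
#' (padding is masked everywhere, so grouping affects speed, not results).
#'
#' @param train a `labeled_corpus` used for fitting (and the vocabulary).
#' @param val optional validation `labeled_corpus` for early stopping.
#' @param config a [trnn_config()].
#' @param control a [trnn_control()].
#' @param embeddings optional `embedding_table` of pretrained vectors.
#' @return object of class `trnn`: list with `params`, `config`, `control`,
#'   `vocab`, `label_set`, `history` (data.frame of per-epoch train loss,
#'   train accuracy and validation weighted F1), `best_epoch`, and
#'   `embedding_coverage`.
#' @seealso [predict.trnn()], [evaluate()], [run_ablation()]
#' @export
trnn <- function(train, val = NULL, config = trnn_config(),
                 control = trnn_control(), embeddings = NULL) {
  stopifnot(inherits(train, "labeled_corpus"))
  vocab <- build_vocab(train, min_freq = control$min_freq)
  E0 <- build_embedding_matrix(vocab, table = embeddings,
                               dim = config$embed_dim, seed = control$seed)
  params <- trnn_init_params(config, vocab$size, embedding = E0,
                             seed = control$seed)
  fitted <- with_seed(control$seed + 1L, {
    train_loop(params, train, val, vocab, config, control)
  })
  structure(list(params = fitted$params, config = config, control = control,
                 vocab = vocab, label_set = train$label_set,
                 history = fitted$history, best_epoch = fitted$best_epoch,
                 embedding_coverage = attr(E0, "coverage"),
                 version = 1L),
            class = "trnn")
}

train_loop <- function(params, train, val, vocab, config, control) {
  n <- length(train)
  lens <- vapply(train$documents, function(d) length(d$tokens), integer(1))
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_f1 = numeric(0))
  best_f1 <- -Inf; best_epoch <- 0L; best_flat <- flat
  for (epoch in seq_len(control$max_epochs)) {
    # seeded shuffle, then group similar lengths into batches and shuffle
    # the batch order, so padding inside each batch stays small
    perm <- sample.int(n)
    perm <- perm[order(lens[perm], method = "radix")]
    starts <- seq(1, n, by = control$batch_size)
    batches <- lapply(starts, function(s) perm[s:min(s + control$batch_size - 1, n)])
    batches <- batches[sample.int(length(batches))]
    ep_loss <- 0; ep_correct <- 0
    for (bi in batches) {
      bmax <- min(config$max_len, max(lens[bi]))
      batch <- encode_batch(train[bi], vocab, max_len = bmax)
      fwd <- trnn_forward(params, batch, config, train_mode = TRUE,
                          keep_cache = TRUE)
      if (!is.finite(fwd$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch of ", length(bi), "); last loss = ", fwd$loss)
      }
      grads <- trnn_backward(params, batch, config, fwd)
      flat <- flatten_params(params)
      upd <- adam_step(flat, grads, opt, lr = control$lr)
      opt <- upd$state
      params <- unflatten_params(upd$flat, params)
      ep_loss <- ep_loss + fwd$loss * length(bi)
      pred <- max.col(fwd$probs, ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == batch$labels)
    }
    ep_loss <- ep_loss / n
    ep_acc <- ep_correct / n
    val_f1 <- NA_real_
    if (!is.null(val)) {
      vm <- evaluate_params(params, val, vocab, config, train$label_set)
      val_f1 <- vm$weighted["f1"]
      if (val_f1 > best_f1) {  # strict: earliest epoch wins ties
        best_f1 <- val_f1; best_epoch <- epoch
        best_flat <- flatten_params(params)
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         train_acc = ep_acc, val_f1 = val_f1))
    if (control$verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val F1 %s",
                      epoch, ep_loss, ep_acc,
                      ifelse(is.na(val_f1), "-", sprintf("%.3f", val_f1))))
    }
    if (!is.null(control$target_train_acc) &&
        ep_acc >= control$target_train_acc) {
      # confirm with a deterministic (dropout-off) pass over the train set
      tm <- evaluate_params(params, train, vocab, config, train$label_set,
                            batch_size = control$batch_size)
      det_acc <- sum(diag(tm$confusion)) / n
      history$train_acc[nrow(history)] <- det_acc
      if (det_acc >= control$target_train_acc) {
        if (is.null(val)) best_epoch <- epoch
        break
      }
    }
    if (!is.null(val) && !is.null(control$stop_at_val_f1) &&
        best_f1 >= control$stop_at_val_f1) break
    if (!is.null(val) && epoch - best_epoch > control$patience) break
  }
  if (!is.null(val) && best_epoch > 0) {
    params <- unflatten_params(best_flat, params)
  } else if (is.null(val)) {
    best_epoch <- nrow(history)
  }
  list(params = params, history = history, best_epoch = best_epoch)
}

# Forward-only evaluation against raw params (used inside the loop, before
# a trnn object exists).
evaluate_params <- function(params, corpus, vocab, config, label_set,
                            batch_size = 64) {
  lens <- vapply(corpus$documents, function(d) length(d$tokens), integer(1))
  n <- length(corpus)
  ord <- order(lens, method = "radix")
  gold <- corpus_label_ids(corpus)
  pred <- integer(n)
  for (s in seq(1, n, by = batch_size)) {
    bi <- ord[s:min(s + batch_size - 1, n)]
    bmax <- min(config$max_len, max(lens[bi]))
    batch <- encode_batch(corpus[bi], vocab, max_len = bmax)
    fwd <- trnn_forward(params, batch, config, train_mode = FALSE)
    pred[bi] <- max.col(fwd$probs, ties.method = "first") - 1L
  }
  compute_metrics(gold, pred, n_classes = config$n_classes,
                  labels = label_set)
}
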
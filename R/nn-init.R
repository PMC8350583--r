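#' Model configuration
#'
#' Collects every architectural choice of the network. Defaults follow the
#' published configuration: 200-dimensional embeddings (tied to the model
#' width, since no input projection exists), 4 attention heads, a
#' 128-unit-per-direction BiLSTM, dropout 0.5. The encoder depth and
#' feed-forward width are this package's choices: one post-norm block and
#' `d_ff = 4 * embed_dim`.
#'
#' @param embed_dim word-embedding / model width `d_model`.
#' @param heads number of attention heads; must divide `embed_dim`.
#' @param lstm_hidden BiLSTM width. Interpreted per direction by default
#'   (output width `2 * lstm_hidden`); set `hidden_is_total = TRUE` to read
#'   it as the total bidirectional width.
#' @param dropout dropout rate in `[0, 1)`, applied to the concatenated
#'   representation and to the pooled vector during training only.
#' @param n_layers encoder block count (>= 0).
#' @param d_ff feed-forward inner width.
#' @param max_len maximum tokens per document; longer documents are
#'   truncated.
#' @param n_classes number of output classes.
#' @param no_max_pool,no_bilstm,no_concat_embedding ablation switches:
#'   replace max-pooling by the final-position state, bypass the BiLSTM,
#'   or drop the word embeddings from the concatenated representation.
#' @param freeze_embeddings keep the embedding matrix fixed during
#'   training (default FALSE: embeddings are trainable).
#' @param hidden_is_total see `lstm_hidden`.
#' @return object of class `trnn_config`.
#' @export
trnn_config <- function(embed_dim = 200, heads = 4, lstm_hidden = 128,
                        dropout = 0.5, n_layers = 1, d_ff = 4 * embed_dim,
                        max_len = 256, n_classes = 3,
                        no_max_pool = FALSE, no_bilstm = FALSE,
                        no_concat_embedding = FALSE,
                        freeze_embeddings = FALSE,
                        hidden_is_total = FALSE) {
  stopifnot(embed_dim %% 2 == 0, embed_dim %% heads == 0,
            dropout >= 0, dropout < 1, n_layers >= 0, d_ff >= 1,
            max_len >= 1, n_classes >= 2)
  m <- if (hidden_is_total) {
    stopifnot(lstm_hidden %% 2 == 0)
    lstm_hidden %/% 2
  } else lstm_hidden
  structure(list(embed_dim = embed_dim, heads = heads, lstm_hidden = m,
                 dropout = dropout, n_layers = n_layers, d_ff = d_ff,
                 max_len = max_len, n_classes = n_classes,
                 no_max_pool = no_max_pool, no_bilstm = no_bilstm,
                 no_concat_embedding = no_concat_embedding,
                 freeze_embeddings = freeze_embeddings),
            class = "trnn_config")
}

#' @export
print.trnn_config <- function(x, ...) {
  cat("TransformerRNN configuration\n")
  cat(sprintf("  d_model %d | heads %d | encoder layers %d | d_ff %d\n",
              x$embed_dim, x$heads, x$n_layers, x$d_ff))
  cat(sprintf("  BiLSTM hidden %d/direction | dropout %.2f | max_len %d | classes %d\n",
              x$lstm_hidden, x$dropout, x$max_len, x$n_classes))
  abl <- c("no_max_pool", "no_bilstm", "no_concat_embedding")
  on <- abl[vapply(abl, function(a) isTRUE(x[[a]]), logical(1))]
  if (length(on)) cat("  ablation:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

# Width of the BiLSTM input: embeddings concatenated with encoder output
# (2 * d_model), or encoder output alone under no_concat_embedding.
lstm_input_dim <- function(config) {
  if (config$no_concat_embedding) config$embed_dim else 2L * config$embed_dim
}

# Width of the vector fed to the classifier.
pooled_dim <- function(config) {
  if (config$no_bilstm) lstm_input_dim(config) else 2L * config$lstm_hidden
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Initialize all model parameters
#'
#' Weight matrices use Glorot-uniform initialization; biases start at zero
#' except the LSTM forget gate (initialized to 1, the usual stabilizer);
#' layer-norm gains start at 1. The embedding matrix is supplied (from
#' [build_embedding_matrix()]) or drawn uniform; its `PAD` row is zeroed
#' and stays zero throughout training.
#'
#' @param config a `trnn_config`.
#' @param vocab_size total id count (including PAD and OOV).
#' @param embedding optional pre-built `vocab_size x embed_dim` matrix.
#' @param seed integer seed.
#' @return nested list of parameter arrays (`E`, `enc$layers`, `lstm$fwd`,
#'   `lstm$bwd`, `cls`).
#' @export
trnn_init_params <- function(config, vocab_size, embedding = NULL, seed = 1) {
  d <- config$embed_dim; dff <- config$d_ff; m <- config$lstm_hidden
  din <- lstm_input_dim(config); pdim <- pooled_dim(config)
  with_seed(seed, {
    E <- if (is.null(embedding)) {
      matrix(stats::runif(vocab_size * d, -0.05, 0.05), vocab_size, d)
    } else {
      stopifnot(nrow(embedding) == vocab_size, ncol(embedding) == d)
      embedding
    }
    E[1, ] <- 0  # PAD row pinned to zero
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
           Wo = glorot(d, d),
           W1 = glorot(d, dff), b1 = numeric(dff),
           W2 = glorot(dff, d), b2 = numeric(d),
           g1 = rep(1, d), be1 = numeric(d),
           g2 = rep(1, d), be2 = numeric(d))
    })
    lstm_dir <- function() {
      b <- numeric(4 * m)
      b[(m + 1):(2 * m)] <- 1  # forget gate bias
      list(Wx = glorot(din, 4 * m), Wh = glorot(m, 4 * m), b = b)
    }
    params <- list(
      E = E,
      enc = list(h = config$heads, n_layers = config$n_layers, layers = layers),
      lstm = if (config$no_bilstm) NULL else list(fwd = lstm_dir(), bwd = lstm_dir()),
      cls = list(W3 = glorot(pdim, config$n_classes),
                 b3 = numeric(config$n_classes)))
    params
  })
}

#' Model parameter count
#'
#' Closed-form count of learnable scalars for a configuration and
#' vocabulary size:
#' embeddings `V * d`; per encoder layer `4 d^2` (Q/K/V/O projections)
#' `+ d * d_ff + d_ff + d_ff * d + d` (feed-forward) `+ 4 d` (two
#' layer-norm gain/bias pairs); BiLSTM `2 * (d_in * 4m + m * 4m + 4m)`
#' with `d_in = 2d` (or `d` without the embedding concatenation); classifier
#' `p * c + c` with `p = 2m` (or `d_in` without the BiLSTM).
#'
#' @param config a `trnn_config`.
#' @param vocab_size total id count.
#' @return integer scalar.
#' @export
trnn_param_count <- function(config, vocab_size) {
  d <- config$embed_dim; dff <- config$d_ff; m <- config$lstm_hidden
  din <- lstm_input_dim(config); pdim <- pooled_dim(config)
  n <- vocab_size * d
  n <- n + config$n_layers * (4 * d * d + d * dff + dff + dff * d + d + 4 * d)
  if (!config$no_bilstm) n <- n + 2 * (din * 4 * m + m * 4 * m + 4 * m)
  n + pdim * config$n_classes + config$n_classes
}

# Flatten/unflatten parameter lists for the optimizer and for
# finite-difference testing. Returns a list of numeric arrays keyed by
# path-like names; embedding excluded when requested (it has its own
# sparse-update handling but is included by default).
flatten_params <- function(params) {
  out <- list()
  out[["E"]] <- params$E
  for (l in seq_along(params$enc$layers)) {
    for (nm in names(params$enc$layers[[l]])) {
      out[[paste0("enc.", l, ".", nm)]] <- params$enc$layers[[l]][[nm]]
    }
  }
  if (!is.null(params$lstm)) {
    for (dir in c("fwd", "bwd")) {
      for (nm in names(params$lstm[[dir]])) {
        out[[paste0("lstm.", dir, ".", nm)]] <- params$lstm[[dir]][[nm]]
      }
    }
  }
  out[["cls.W3"]] <- params$cls$W3
  out[["cls.b3"]] <- params$cls$b3
  out
}

unflatten_params <- function(flat, skeleton) {
  p <- skeleton
  p$E <- flat[["E"]]
  for (l in seq_along(p$enc$layers)) {
    for (nm in names(p$enc$layers[[l]])) {
      p$enc$layers[[l]][[nm]] <- flat[[paste0("enc.", l, ".", nm)]]
    }
  }
  if (!is.null(p$lstm)) {
    for (dir in c("fwd", "bwd")) {
      for (nm in names(p$lstm[[dir]])) {
        p$lstm[[dir]][[nm]] <- flat[[paste0("lstm.", dir, ".", nm)]]
      }
    }
  }
  p$cls$W3 <- flat[["cls.W3"]]
  p$cls$b3 <- flat[["cls.b3"]]
  p
}
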
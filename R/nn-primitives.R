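# Numerically stable row-wise softmax. Rows that are entirely -Inf are not
# permitted (caller must guarantee at least one finite entry per row).
softmax_rows <- function(X) {
  m <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  Z <- exp(X - m)
  Z / rowSums(Z)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sinusoidal positional encoding
#'
#' Deterministic position features added to the input embeddings so the
#' encoder can use word order: even columns carry
#' `sin(pos / 10000^(2i/d_model))` and odd columns the matching cosine,
#' with `pos` starting at 0 for the first token.
#'
#' @param L sequence length (>= 1).
#' @param d_model model width; must be even.
#' @return numeric matrix `L x d_model`.
#' @examples
#' positional_encoding(2, 4)[1, ]  # position 0: c(0, 1, 0, 1)
#' @export
positional_encoding <- function(L, d_model) {
  stopifnot(L >= 1, d_model >= 2)
  if (d_model %% 2 != 0) stop("d_model must be even, got ", d_model)
  pos <- 0:(L - 1)
  i <- 0:(d_model / 2 - 1)
  freq <- 1 / 10000^(2 * i / d_model)
  ang <- outer(pos, freq)              # L x d/2
  PE <- matrix(0, L, d_model)
  PE[, 2 * i + 1] <- sin(ang)
  PE[, 2 * i + 2] <- cos(ang)
  PE
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with masked key positions excluded from
#' the softmax (set to -Inf before normalization). Each output row is a
#' convex combination of the valid rows of `V`.
#'
#' @param Q query matrix `m x d_k`.
#' @param K key matrix `n x d_k`.
#' @param V value matrix `n x d_v`.
#' @param key_mask optional 0/1 vector of length `n`; 0 marks padding keys.
#'   At least one key must be valid.
#' @return numeric matrix `m x d_v`.
#' @export
scaled_dot_attention <- function(Q, K, V, key_mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(key_mask)) {
    stopifnot(length(key_mask) == nrow(K))
    if (sum(key_mask) == 0) stop("all keys are masked")
    S[, key_mask == 0] <- -Inf
  }
  softmax_rows(S) %*% V
}

#' Multi-head self-attention
#'
#' `h` parallel scaled dot-product attentions in projected subspaces of
#' width `d_k = d_model / h`, concatenated and mixed by the output
#' projection `W^O`:
#' `MultiHead(X) = Concat(head_1, ..., head_h) W^O` with
#' `head_i = Attention(X W_i^Q, X W_i^K, X W_i^V)`.
#'
#' @param X input matrix `L x d_model`.
#' @param params list with `Wq`, `Wk`, `Wv` (each `d_model x d_model`,
#'   heads stacked column-wise), `Wo` (`d_model x d_model`) and `h` (head
#'   count dividing `d_model`).
#' @param key_mask optional 0/1 vector of length `L`.
#' @return numeric matrix `L x d_model`.
#' @export
multi_head_attention <- function(X, params, key_mask = NULL) {
  d <- ncol(X)
  h <- params$h
  stopifnot(d %% h == 0, ncol(params$Wq) == d, ncol(params$Wo) == d)
  dk <- d %/% h
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  H <- matrix(0, nrow(X), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    H[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE], key_mask)
  }
  H %*% params$Wo
}

#' Position-wise feed-forward network
#'
#' Two linear transformations with a ReLU in between, applied to each row:
#' `FFN(x) = ReLU(x W1 + b1) W2 + b2`.
#'
#' @param X input matrix `L x d_model`.
#' @param params list with `W1` (`d_model x d_ff`), `b1`, `W2`
#'   (`d_ff x d_model`), `b2`.
#' @return numeric matrix `L x d_model`.
#' @export
feed_forward <- function(X, params) {
  H <- pmax(sweep_add(X %*% params$W1, params$b1), 0)
  sweep_add(H %*% params$W2, params$b2)
}

# Add a bias vector to every row of a matrix (cheap sweep).
sweep_add <- function(X, b) X + rep(b, each = nrow(X))

#' Layer normalization
#'
#' Standardizes each row over its features (population variance), then
#' applies an elementwise affine transform: `g * (x - mean) / sqrt(var +
#' eps) + b`.
#'
#' @param X input matrix.
#' @param gain,bias numeric vectors of length `ncol(X)`.
#' @param eps variance floor (> 0).
#' @return matrix of the same shape.
#' @export
layer_norm <- function(X, gain, bias, eps = 1e-6) {
  stopifnot(eps > 0)
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  Xhat <- Xc / sqrt(v + eps)
  sweep_add(Xhat * rep(gain, each = nrow(X)), bias)
}

#' Masked temporal max-pooling
#'
#' Componentwise maximum over the valid (unmasked) time positions of a
#' sequence of feature vectors, yielding a fixed-length vector.
#'
#' @param H matrix `L x d` of per-position features.
#' @param mask 0/1 vector of length `L`; at least one position valid.
#' @return numeric vector of length `d`.
#' @examples
#' max_pool_time(rbind(c(1, 5), c(3, 2)), c(1, 1))  # c(3, 5)
#' @export
max_pool_time <- function(H, mask) {
  stopifnot(length(mask) == nrow(H))
  valid <- which(mask == 1)
  if (length(valid) == 0) stop("all positions are masked; nothing to pool")
  apply(H[valid, , drop = FALSE], 2, max)
}

#' Mean categorical cross-entropy
#'
#' Mean over the batch of `-log p(true class)`, with the probability
#' clamped at `eps` to keep the log finite.
#'
#' @param probs matrix `batch x c`; each row a probability distribution.
#' @param labels integer vector of 0-based true classes.
#' @param eps clamp for the log.
#' @return scalar loss.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  stopifnot(nrow(probs) == length(labels), all(labels >= 0),
            all(labels < ncol(probs)))
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p, eps)))
}

#' Transformer encoder stack
#'
#' Adds the sinusoidal positional encoding to the input once, then applies
#' `n_layers` post-norm encoder blocks: `X <- LayerNorm(X + MultiHead(X))`
#' followed by `X <- LayerNorm(X + FFN(X))`. Masked (padding) key positions
#' are excluded from every attention softmax.
#'
#' @param E input embedding matrix `L x d_model`.
#' @param key_mask optional 0/1 vector of length `L`.
#' @param params list with `h`, `n_layers`, and per-layer weights `layers`
#'   (each a list with `Wq`, `Wk`, `Wv`, `Wo`, `W1`, `b1`, `W2`, `b2`,
#'   `g1`, `be1`, `g2`, `be2`), as built by [trnn_init_params()].
#' @param use_pe add positional encodings (default TRUE; disabling makes
#'   the encoder permutation-equivariant, used in tests).
#' @return matrix `L x d_model` of contextual representations.
#' @export
transformer_encoder <- function(E, key_mask = NULL, params, use_pe = TRUE) {
  X <- if (use_pe) E + positional_encoding(nrow(E), ncol(E)) else E
  if (params$n_layers == 0) return(X)
  for (l in seq_len(params$n_layers)) {
    p <- params$layers[[l]]
    A <- multi_head_attention(X, list(Wq = p$Wq, Wk = p$Wk, Wv = p$Wv,
                                      Wo = p$Wo, h = params$h), key_mask)
    X <- layer_norm(X + A, p$g1, p$be1)
    F1 <- feed_forward(X, p)
    X <- layer_norm(X + F1, p$g2, p$be2)
  }
  X
}
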
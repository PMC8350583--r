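# Independent explicit-loop reference implementations. These deliberately
# avoid matrix algebra and any code path shared with the package: every
# quantity is accumulated scalar by scalar.

oracle_positional_encoding <- function(L, d) {
  PE <- matrix(0, L, d)
  for (pos in 0:(L - 1)) {
    for (i in 0:(d / 2 - 1)) {
      PE[pos + 1, 2 * i + 1] <- sin(pos / 10000^(2 * i / d))
      PE[pos + 1, 2 * i + 2] <- cos(pos / 10000^(2 * i / d))
    }
  }
  PE
}

oracle_attention <- function(Q, K, V, key_mask = NULL) {
  m <- nrow(Q); n <- nrow(K); dk <- ncol(Q); dv <- ncol(V)
  if (is.null(key_mask)) key_mask <- rep(1, n)
  out <- matrix(0, m, dv)
  for (r in 1:m) {
    scores <- rep(NA_real_, n)
    for (j in 1:n) {
      if (key_mask[j] == 1) {
        s <- 0
        for (t in 1:dk) s <- s + Q[r, t] * K[j, t]
        scores[j] <- s / sqrt(dk)
      }
    }
    mx <- max(scores, na.rm = TRUE)
    w <- rep(0, n); tot <- 0
    for (j in 1:n) {
      if (!is.na(scores[j])) { w[j] <- exp(scores[j] - mx); tot <- tot + w[j] }
    }
    for (j in 1:n) w[j] <- w[j] / tot
    for (cc in 1:dv) {
      acc <- 0
      for (j in 1:n) acc <- acc + w[j] * V[j, cc]
      out[r, cc] <- acc
    }
  }
  out
}

oracle_multi_head <- function(X, Wq, Wk, Wv, Wo, h, key_mask = NULL) {
  d <- ncol(X); dk <- d / h
  Hc <- matrix(0, nrow(X), d)
  for (i in 1:h) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    Hc[, cols] <- oracle_attention(X %*% Wq[, cols, drop = FALSE],
                                   X %*% Wk[, cols, drop = FALSE],
                                   X %*% Wv[, cols, drop = FALSE], key_mask)
  }
  Hc %*% Wo
}

oracle_feed_forward <- function(X, W1, b1, W2, b2) {
  L <- nrow(X); dff <- length(b1); d <- length(b2)
  out <- matrix(0, L, d)
  for (r in 1:L) {
    hrow <- rep(0, dff)
    for (j in 1:dff) {
      a <- b1[j]
      for (t in 1:ncol(X)) a <- a + X[r, t] * W1[t, j]
      hrow[j] <- max(a, 0)
    }
    for (cc in 1:d) {
      a <- b2[cc]
      for (j in 1:dff) a <- a + hrow[j] * W2[j, cc]
      out[r, cc] <- a
    }
  }
  out
}

oracle_layer_norm <- function(X, gain, bias, eps = 1e-6) {
  out <- X
  for (r in 1:nrow(X)) {
    mu <- 0
    for (j in 1:ncol(X)) mu <- mu + X[r, j]
    mu <- mu / ncol(X)
    v <- 0
    for (j in 1:ncol(X)) v <- v + (X[r, j] - mu)^2
    v <- v / ncol(X)
    for (j in 1:ncol(X)) {
      out[r, j] <- gain[j] * (X[r, j] - mu) / sqrt(v + eps) + bias[j]
    }
  }
  out
}

oracle_max_pool <- function(H, mask) {
  out <- rep(-Inf, ncol(H))
  for (j in 1:ncol(H)) {
    for (t in 1:nrow(H)) {
      if (mask[t] == 1 && H[t, j] > out[j]) out[j] <- H[t, j]
    }
  }
  out
}

oracle_cross_entropy <- function(probs, labels) {
  acc <- 0
  for (i in 1:nrow(probs)) acc <- acc - log(probs[i, labels[i] + 1])
  acc / nrow(probs)
}

# Metrics from first principles: counts from the contingency table.
oracle_metrics <- function(gold, pred, n_classes) {
  P <- R <- F1 <- S <- numeric(n_classes)
  for (c0 in 0:(n_classes - 1)) {
    tp <- fp <- fn <- 0
    for (i in seq_along(gold)) {
      if (gold[i] == c0 && pred[i] == c0) tp <- tp + 1
      if (gold[i] != c0 && pred[i] == c0) fp <- fp + 1
      if (gold[i] == c0 && pred[i] != c0) fn <- fn + 1
    }
    S[c0 + 1] <- tp + fn
    P[c0 + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[c0 + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[c0 + 1] <- if (P[c0 + 1] + R[c0 + 1] > 0) {
      2 * P[c0 + 1] * R[c0 + 1] / (P[c0 + 1] + R[c0 + 1])
    } else 0
  }
  w <- S / sum(S)
  list(precision = P, recall = R, f1 = F1, support = S,
       weighted = c(precision = sum(w * P), recall = sum(w * R),
                    f1 = sum(w * F1)))
}

oracle_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- 0; for (v in x) mx <- mx + v; mx <- mx / nx
  my <- 0; for (v in y) my <- my + v; my <- my / ny
  sx2 <- 0; for (v in x) sx2 <- sx2 + (v - mx)^2; sx2 <- sx2 / (nx - 1)
  sy2 <- 0; for (v in y) sy2 <- sy2 + (v - my)^2; sy2 <- sy2 / (ny - 1)
  sp <- sqrt(((nx - 1) * sx2 + (ny - 1) * sy2) / (nx + ny - 2))
  (mx - my) / sp
}
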
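# Batched forward pass.
#
# Internal layout: a batch of B documents padded to L tokens is stacked as a
# (B*L) x d matrix in time-major order — row (t-1)*B + b holds token t of
# document b (the column-major vectorization of the B x L id matrix). This
# makes each LSTM time step a contiguous row block and keeps every large
# multiplication a single BLAS call; attention scores are the only per-
# document loop.
#
# Masking guarantees padding invariance: PAD keys are excluded from every
# attention softmax, the LSTM state is updated only at valid steps (carried
# unchanged through padding), and pooling ranges over valid positions only.

#' Full model forward pass
#'
#' Runs the pipeline embed -> transformer encoder -> concatenate
#' [embedding, encoder output] -> BiLSTM -> masked temporal max-pooling ->
#' linear + softmax, honoring the ablation switches in `config`
#' (`no_concat_embedding` feeds the encoder output alone to the BiLSTM;
#' `no_bilstm` pools the concatenated representation directly;
#' `no_max_pool` uses the final-position state instead of the maximum).
#' Dropout is active only with `train_mode = TRUE` and draws its masks from
#' the current RNG stream.
#'
#' @param params parameter list from [trnn_init_params()].
#' @param batch a `padded_batch` from [encode_batch()].
#' @param config a `trnn_config`.
#' @param train_mode logical; enables dropout.
#' @param keep_cache logical; retain intermediates for the backward pass.
#' @param use_pe logical; add positional encodings (TRUE except in
#'   equivariance tests).
#' @return list with `probs` (`B x c`, rows summing to 1), `pooled`
#'   (document vectors), `loss` (mean cross-entropy when the batch has
#'   labels, else `NA`), and `cache` when requested.
#' @export
trnn_forward <- function(params, batch, config, train_mode = FALSE,
                         keep_cache = FALSE, use_pe = TRUE) {
  B <- nrow(batch$ids); L <- ncol(batch$ids)
  d <- config$embed_dim; h <- config$heads; dk <- d %/% h
  idvec <- as.vector(batch$ids) + 1L       # time-major row index into E
  maskvec <- as.vector(batch$mask)
  X0 <- params$E[idvec, , drop = FALSE]
  PEx <- if (use_pe) {
    positional_encoding(L, d)[rep(seq_len(L), each = B), , drop = FALSE]
  } else NULL
  X <- if (use_pe) X0 + PEx else X0

  enc_cache <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- params$enc$layers[[l]]
    Qm <- X %*% p$Wq; Km <- X %*% p$Wk; Vm <- X %*% p$Wv
    Hc <- matrix(0, B * L, d)
    Plist <- if (keep_cache) vector("list", B) else NULL
    for (b in seq_len(B)) {
      rows_b <- seq(b, by = B, length.out = L)
      km <- maskvec[rows_b]
      pad <- which(km == 0)
      Qb <- Qm[rows_b, , drop = FALSE]
      Kb <- Km[rows_b, , drop = FALSE]
      Vb <- Vm[rows_b, , drop = FALSE]
      Hb <- matrix(0, L, d)
      Pb <- if (keep_cache) vector("list", h) else NULL
      for (i in seq_len(h)) {
        cols <- ((i - 1) * dk + 1):(i * dk)
        S <- tcrossprod(Qb[, cols, drop = FALSE],
                        Kb[, cols, drop = FALSE]) / sqrt(dk)
        if (length(pad)) S[, pad] <- -Inf
        P <- softmax_rows(S)
        Hb[, cols] <- P %*% Vb[, cols, drop = FALSE]
        if (keep_cache) Pb[[i]] <- P
      }
      Hc[rows_b, ] <- Hb
      if (keep_cache) Plist[[b]] <- Pb
    }
    A <- Hc %*% p$Wo
    ln1 <- layer_norm_cached(X + A, p$g1, p$be1)
    X1 <- ln1$Y
    H1 <- sweep_add(X1 %*% p$W1, p$b1)
    Hr <- pmax(H1, 0)
    F1 <- sweep_add(Hr %*% p$W2, p$b2)
    ln2 <- layer_norm_cached(X1 + F1, p$g2, p$be2)
    if (keep_cache) {
      enc_cache[[l]] <- list(X = X, Qm = Qm, Km = Km, Vm = Vm, Hc = Hc,
                             P = Plist, xhat1 = ln1$xhat, inv_sd1 = ln1$inv_sd,
                             X1 = X1, relu_on = (H1 > 0), Hr = Hr,
                             xhat2 = ln2$xhat, inv_sd2 = ln2$inv_sd)
    }
    X <- ln2$Y
  }
  TT <- X

  Cmat <- if (config$no_concat_embedding) TT else cbind(X0, TT)
  keep <- 1 - config$dropout
  M1 <- NULL
  if (train_mode && config$dropout > 0) {
    M1 <- matrix((stats::runif(length(Cmat)) < keep) / keep, nrow(Cmat))
    Cd <- Cmat * M1
  } else Cd <- Cmat

  if (config$no_bilstm) {
    Hl <- Cd
    lstm_f <- lstm_b <- NULL
  } else {
    m <- config$lstm_hidden
    lstm_f <- lstm_pass(Cd, maskvec, B, L, params$lstm$fwd, reverse = FALSE,
                        keep_cache = keep_cache)
    lstm_b <- lstm_pass(Cd, maskvec, B, L, params$lstm$bwd, reverse = TRUE,
                        keep_cache = keep_cache)
    Hl <- cbind(lstm_f$H, lstm_b$H)
  }

  pdim <- ncol(Hl)
  pooled <- matrix(0, B, pdim)
  argmax <- if (keep_cache && !config$no_max_pool) matrix(0L, B, pdim) else NULL
  for (b in seq_len(B)) {
    rows_b <- seq(b, by = B, length.out = L)
    if (config$no_max_pool) {
      if (config$no_bilstm) {
        pooled[b, ] <- Hl[rows_b[batch$lengths[b]], ]
      } else {
        m <- config$lstm_hidden
        pooled[b, ] <- c(Hl[rows_b[L], 1:m], Hl[rows_b[1], (m + 1):(2 * m)])
      }
    } else {
      valid <- rows_b[batch$mask[b, ] == 1]
      Mb <- Hl[valid, , drop = FALSE]
      am <- max.col(t(Mb), ties.method = "first")
      pooled[b, ] <- Mb[cbind(am, seq_len(pdim))]
      if (keep_cache) argmax[b, ] <- valid[am]
    }
  }

  M2 <- NULL
  if (train_mode && config$dropout > 0) {
    M2 <- matrix((stats::runif(length(pooled)) < keep) / keep, B)
    pooled_d <- pooled * M2
  } else pooled_d <- pooled

  logits <- sweep_add(pooled_d %*% params$cls$W3, params$cls$b3)
  probs <- softmax_rows(logits)
  loss <- if (!anyNA(batch$labels)) cross_entropy(probs, batch$labels) else NA_real_

  out <- list(probs = probs, pooled = pooled, loss = loss)
  if (keep_cache) {
    out$cache <- list(B = B, L = L, idvec = idvec, maskvec = maskvec,
                      X0 = X0, enc = enc_cache, TT = TT, Cmat = Cmat,
                      Cd = Cd, M1 = M1, lstm_f = lstm_f, lstm_b = lstm_b,
                      Hl = Hl, argmax = argmax, pooled_d = pooled_d,
                      M2 = M2, probs = probs, use_pe = use_pe)
  }
  out
}

# Layer norm returning the pieces the backward pass needs.
layer_norm_cached <- function(X, gain, bias, eps = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- Xc * inv_sd
  list(Y = sweep_add(xhat * rep(gain, each = nrow(X)), bias),
       xhat = xhat, inv_sd = inv_sd)
}

# One LSTM direction over the stacked time-major input. State updates are
# gated by the per-step validity mask, so padding never alters the state:
# the stored state at any masked step equals the previous state (zero for
# the trailing pads seen first by the reverse direction).
lstm_pass <- function(C, maskvec, B, L, w, reverse = FALSE, keep_cache = FALSE) {
  m <- nrow(w$Wh)
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- matrix(0, B, m); cs <- matrix(0, B, m)
  H <- matrix(0, B * L, m)
  cache <- if (keep_cache) {
    list(i = array(0, c(B, m, L)), f = array(0, c(B, m, L)),
         g = array(0, c(B, m, L)), o = array(0, c(B, m, L)),
         craw = array(0, c(B, m, L)), cst = array(0, c(B, m, L)))
  } else NULL
  bias <- rep(w$b, each = B)
  for (t in ord) {
    rows_t <- ((t - 1) * B + 1):(t * B)
    x <- C[rows_t, , drop = FALSE]
    mt <- maskvec[rows_t]
    z <- x %*% w$Wx + h %*% w$Wh + bias
    ii <- sigmoid(z[, 1:m, drop = FALSE])
    ff <- sigmoid(z[, (m + 1):(2 * m), drop = FALSE])
    gg <- tanh(z[, (2 * m + 1):(3 * m), drop = FALSE])
    oo <- sigmoid(z[, (3 * m + 1):(4 * m), drop = FALSE])
    craw <- ff * cs + ii * gg
    hraw <- oo * tanh(craw)
    cs <- mt * craw + (1 - mt) * cs
    h <- mt * hraw + (1 - mt) * h
    H[rows_t, ] <- h
    if (keep_cache) {
      cache$i[, , t] <- ii; cache$f[, , t] <- ff; cache$g[, , t] <- gg
      cache$o[, , t] <- oo; cache$craw[, , t] <- craw; cache$cst[, , t] <- cs
    }
  }
  list(H = H, cache = cache, ord = ord)
}
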
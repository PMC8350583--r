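# Backward pass through the full network. Returns gradients as a flat
# named list matching flatten_params(), averaged over the batch (the loss
# is the batch-mean cross-entropy). PAD's embedding row gradient is zeroed
# so the row stays exactly zero under any optimizer.

trnn_backward <- function(params, batch, config, fwd) {
  cache <- fwd$cache
  B <- cache$B; L <- cache$L
  d <- config$embed_dim; h <- config$heads; dk <- d %/% h
  keep <- 1 - config$dropout
  grads <- list()

  # classifier
  Y <- matrix(0, B, config$n_classes)
  Y[cbind(seq_len(B), batch$labels + 1L)] <- 1
  dlogits <- (cache$probs - Y) / B
  grads[["cls.W3"]] <- crossprod(cache$pooled_d, dlogits)
  grads[["cls.b3"]] <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, params$cls$W3)
  if (!is.null(cache$M2)) dpooled <- dpooled * cache$M2

  # un-pool into the per-position representation
  pdim <- ncol(cache$Hl)
  dHl <- matrix(0, B * L, pdim)
  for (b in seq_len(B)) {
    rows_b <- seq(b, by = B, length.out = L)
    if (config$no_max_pool) {
      if (config$no_bilstm) {
        r <- rows_b[batch$lengths[b]]
        dHl[r, ] <- dHl[r, ] + dpooled[b, ]
      } else {
        m <- config$lstm_hidden
        dHl[rows_b[L], 1:m] <- dHl[rows_b[L], 1:m] + dpooled[b, 1:m]
        dHl[rows_b[1], (m + 1):(2 * m)] <-
          dHl[rows_b[1], (m + 1):(2 * m)] + dpooled[b, (m + 1):(2 * m)]
      }
    } else {
      idx <- cbind(cache$argmax[b, ], seq_len(pdim))
      dHl[idx] <- dHl[idx] + dpooled[b, ]
    }
  }

  # BiLSTM (or pass-through without it)
  if (config$no_bilstm) {
    dCd <- dHl
  } else {
    m <- config$lstm_hidden
    gf <- lstm_backward(cache$Cd, cache$maskvec, B, L, params$lstm$fwd,
                        cache$lstm_f, dHl[, 1:m, drop = FALSE])
    gb <- lstm_backward(cache$Cd, cache$maskvec, B, L, params$lstm$bwd,
                        cache$lstm_b, dHl[, (m + 1):(2 * m), drop = FALSE])
    grads[["lstm.fwd.Wx"]] <- gf$dWx; grads[["lstm.fwd.Wh"]] <- gf$dWh
    grads[["lstm.fwd.b"]] <- gf$db
    grads[["lstm.bwd.Wx"]] <- gb$dWx; grads[["lstm.bwd.Wh"]] <- gb$dWh
    grads[["lstm.bwd.b"]] <- gb$db
    dCd <- gf$dC + gb$dC
  }
  dC <- if (is.null(cache$M1)) dCd else dCd * cache$M1

  # split the concatenation
  if (config$no_concat_embedding) {
    dX0_direct <- matrix(0, B * L, d)
    dT <- dC
  } else {
    dX0_direct <- dC[, 1:d, drop = FALSE]
    dT <- dC[, (d + 1):(2 * d), drop = FALSE]
  }

  # encoder layers, in reverse
  dX <- dT
  for (l in rev(seq_len(config$n_layers))) {
    p <- params$enc$layers[[l]]
    cc <- cache$enc[[l]]
    ln2 <- layer_norm_backward(dX, p$g2, cc$xhat2, cc$inv_sd2)
    grads[[paste0("enc.", l, ".g2")]] <- ln2$dgain
    grads[[paste0("enc.", l, ".be2")]] <- ln2$dbias
    dX1 <- ln2$dX
    dF <- ln2$dX
    grads[[paste0("enc.", l, ".W2")]] <- crossprod(cc$Hr, dF)
    grads[[paste0("enc.", l, ".b2")]] <- colSums(dF)
    dH1 <- tcrossprod(dF, p$W2) * cc$relu_on
    grads[[paste0("enc.", l, ".W1")]] <- crossprod(cc$X1, dH1)
    grads[[paste0("enc.", l, ".b1")]] <- colSums(dH1)
    dX1 <- dX1 + tcrossprod(dH1, p$W1)
    ln1 <- layer_norm_backward(dX1, p$g1, cc$xhat1, cc$inv_sd1)
    grads[[paste0("enc.", l, ".g1")]] <- ln1$dgain
    grads[[paste0("enc.", l, ".be1")]] <- ln1$dbias
    dXin <- ln1$dX
    dA <- ln1$dX
    grads[[paste0("enc.", l, ".Wo")]] <- crossprod(cc$Hc, dA)
    dHc <- tcrossprod(dA, p$Wo)
    dQm <- matrix(0, B * L, d); dKm <- matrix(0, B * L, d)
    dVm <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows_b <- seq(b, by = B, length.out = L)
      dHb <- dHc[rows_b, , drop = FALSE]
      Qb <- cc$Qm[rows_b, , drop = FALSE]
      Kb <- cc$Km[rows_b, , drop = FALSE]
      Vb <- cc$Vm[rows_b, , drop = FALSE]
      dQb <- matrix(0, L, d); dKb <- matrix(0, L, d); dVb <- matrix(0, L, d)
      for (i in seq_len(h)) {
        cols <- ((i - 1) * dk + 1):(i * dk)
        P <- cc$P[[b]][[i]]
        dH <- dHb[, cols, drop = FALSE]
        dP <- tcrossprod(dH, Vb[, cols, drop = FALSE])
        dVb[, cols] <- crossprod(P, dH)
        dS <- P * (dP - rowSums(dP * P))
        dQb[, cols] <- dS %*% Kb[, cols, drop = FALSE] / sqrt(dk)
        dKb[, cols] <- crossprod(dS, Qb[, cols, drop = FALSE]) / sqrt(dk)
      }
      dQm[rows_b, ] <- dQb; dKm[rows_b, ] <- dKb; dVm[rows_b, ] <- dVb
    }
    grads[[paste0("enc.", l, ".Wq")]] <- crossprod(cc$X, dQm)
    grads[[paste0("enc.", l, ".Wk")]] <- crossprod(cc$X, dKm)
    grads[[paste0("enc.", l, ".Wv")]] <- crossprod(cc$X, dVm)
    dXin <- dXin + tcrossprod(dQm, p$Wq) + tcrossprod(dKm, p$Wk) +
      tcrossprod(dVm, p$Wv)
    dX <- dXin
  }
  dX0 <- dX0_direct + dX  # positional encoding is a constant shift

  # scatter into the embedding matrix
  dE <- matrix(0, nrow(params$E), d)
  if (!isTRUE(config$freeze_embeddings)) {
    agg <- rowsum(dX0, group = cache$idvec)
    dE[as.integer(rownames(agg)), ] <- agg
    dE[1, ] <- 0  # PAD row stays zero
  }
  grads[["E"]] <- dE
  grads
}

# Backward of layer_norm_cached: y = gain * xhat + bias, xhat = (x - mu) * inv_sd.
layer_norm_backward <- function(dY, gain, xhat, inv_sd) {
  dxhat <- dY * rep(gain, each = nrow(dY))
  dX <- inv_sd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dgain = colSums(dY * xhat), dbias = colSums(dY))
}

# Backward through one masked LSTM direction (BPTT). `dH` is the gradient
# on the stored (post-mask) hidden states.
lstm_backward <- function(C, maskvec, B, L, w, pass, dH) {
  m <- nrow(w$Wh)
  cc <- pass$cache
  ord <- pass$ord
  dWx <- matrix(0, nrow(w$Wx), 4 * m)
  dWh <- matrix(0, m, 4 * m)
  db <- numeric(4 * m)
  dC <- matrix(0, B * L, nrow(w$Wx))
  dh <- matrix(0, B, m); dc <- matrix(0, B, m)
  for (k in rev(seq_along(ord))) {
    t <- ord[k]
    rows_t <- ((t - 1) * B + 1):(t * B)
    mt <- maskvec[rows_t]
    dht <- dH[rows_t, , drop = FALSE] + dh
    ii <- cc$i[, , t]; ff <- cc$f[, , t]; gg <- cc$g[, , t]; oo <- cc$o[, , t]
    craw <- cc$craw[, , t]
    if (B == 1) { # drop=TRUE collapses [1, m, 1] slices to vectors
      ii <- matrix(ii, 1); ff <- matrix(ff, 1); gg <- matrix(gg, 1)
      oo <- matrix(oo, 1); craw <- matrix(craw, 1)
    }
    tc <- tanh(craw)
    dhraw <- mt * dht
    dcraw <- mt * dc + dhraw * oo * (1 - tc^2)
    doo <- dhraw * tc
    c_prev <- if (k == 1) matrix(0, B, m) else {
      cp <- cc$cst[, , ord[k - 1]]
      if (B == 1) matrix(cp, 1) else cp
    }
    dii <- dcraw * gg
    dgg <- dcraw * ii
    dff <- dcraw * c_prev
    dz <- cbind(dii * ii * (1 - ii), dff * ff * (1 - ff),
                dgg * (1 - gg^2), doo * oo * (1 - oo))
    x_t <- C[rows_t, , drop = FALSE]
    h_prev <- if (k == 1) matrix(0, B, m) else {
      pr <- ((ord[k - 1] - 1) * B + 1):(ord[k - 1] * B)
      pass$H[pr, , drop = FALSE]
    }
    dWx <- dWx + crossprod(x_t, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dC[rows_t, ] <- tcrossprod(dz, w$Wx)
    dh <- tcrossprod(dz, w$Wh) + (1 - mt) * dht
    dc <- dcraw * ff + (1 - mt) * dc
  }
  list(dWx = dWx, dWh = dWh, db = db, dC = dC)
}
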
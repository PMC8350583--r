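make_forward_fixture <- function(seed = 5, n_layers = 1, ...) {
  cfg <- tiny_config(n_layers = n_layers, ...)
  vocab <- tiny_vocab()
  params <- trnn_init_params(cfg, vocab$size, seed = seed)
  list(cfg = cfg, vocab = vocab, params = params)
}

test_that("encoder with no layers returns input plus positional encoding", {
  fx <- make_forward_fixture(n_layers = 0)
  E <- matrix(rnorm(5 * 8), 5)
  out <- transformer_encoder(E, params = fx$params$enc)
  expect_equal(out, E + positional_encoding(5, 8), tolerance = 1e-12)
})

test_that("encoder is permutation-equivariant without positional encoding and not with it", {
  set.seed(6)
  fx <- make_forward_fixture()
  E <- matrix(rnorm(6 * 8), 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  out_plain <- transformer_encoder(E, params = fx$params$enc, use_pe = FALSE)
  out_perm <- transformer_encoder(E[perm, ], params = fx$params$enc,
                                  use_pe = FALSE)
  expect_equal(out_perm, out_plain[perm, ], tolerance = 1e-8)
  with_pe <- transformer_encoder(E, params = fx$params$enc, use_pe = TRUE)
  with_pe_perm <- transformer_encoder(E[perm, ], params = fx$params$enc,
                                      use_pe = TRUE)
  expect_gt(max(abs(with_pe_perm - with_pe[perm, ])), 1e-3)
})

test_that("appending masked padding rows leaves valid encoder outputs unchanged", {
  set.seed(7)
  fx <- make_forward_fixture()
  E <- matrix(rnorm(4 * 8), 4)
  out <- transformer_encoder(E, key_mask = rep(1, 4), params = fx$params$enc)
  Epad <- rbind(E, matrix(rnorm(3 * 8), 3))
  out_pad <- transformer_encoder(Epad, key_mask = c(rep(1, 4), rep(0, 3)),
                                 params = fx$params$enc)
  expect_equal(out_pad[1:4, ], out, tolerance = 1e-6)
})

test_that("class probabilities are a proper distribution and uniform under zero classifier", {
  fx <- make_forward_fixture()
  docs <- tiny_docs(list(c("a", "b", "c"), letters[2:9]))
  batch <- encode_batch(docs, fx$vocab, max_len = 10)
  fwd <- trnn_forward(fx$params, batch, fx$cfg)
  expect_equal(rowSums(fwd$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(fwd$probs > 0))
  p0 <- fx$params
  p0$cls$W3[] <- 0; p0$cls$b3[] <- 0
  fwd0 <- trnn_forward(p0, batch, fx$cfg)
  expect_equal(fwd0$probs, matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("class probabilities are invariant to padding amount and batch composition", {
  fx <- make_forward_fixture()
  doc <- tiny_docs(list(c("a", "c", "e", "g")))
  others <- tiny_docs(list(letters[1:9], c("b", "d")))
  p_alone <- trnn_forward(fx$params, encode_batch(doc, fx$vocab, 4),
                          fx$cfg)$probs[1, ]
  p_padded <- trnn_forward(fx$params, encode_batch(doc, fx$vocab, 12),
                           fx$cfg)$probs[1, ]
  p_batched <- trnn_forward(fx$params,
                            encode_batch(c(others, doc), fx$vocab, 11),
                            fx$cfg)$probs[3, ]
  expect_equal(p_alone, p_padded, tolerance = 1e-6)
  expect_equal(p_alone, p_batched, tolerance = 1e-6)
})

test_that("padding invariance holds for every ablation variant", {
  for (abl in c("no_max_pool", "no_bilstm", "no_concat_embedding")) {
    args <- list(n_layers = 1)
    args[[abl]] <- TRUE
    fx <- do.call(make_forward_fixture, args)
    doc <- tiny_docs(list(c("a", "c", "e")))
    p1 <- trnn_forward(fx$params, encode_batch(doc, fx$vocab, 3),
                       fx$cfg)$probs[1, ]
    p2 <- trnn_forward(fx$params, encode_batch(doc, fx$vocab, 11),
                       fx$cfg)$probs[1, ]
    expect_equal(p1, p2, tolerance = 1e-6, label = abl)
  }
})

pooled_width_for_test <- function(...) {
  fx <- make_forward_fixture(...)
  docs <- tiny_docs(list(c("a", "b", "c")))
  batch <- encode_batch(docs, fx$vocab, max_len = 5)
  ncol(trnn_forward(fx$params, batch, fx$cfg)$pooled)
}

test_that("ablation variants change the classifier input width as the architecture implies", {
  expect_equal(pooled_width_for_test(no_bilstm = TRUE), 2 * 8)   # 2 * d_model
  expect_equal(pooled_width_for_test(), 2 * 4)                   # 2 * h_lstm
  expect_equal(pooled_width_for_test(no_concat_embedding = TRUE,
                                     no_bilstm = TRUE), 8)       # d_model only
})

test_that("analytic gradients match finite differences for every parameter group", {
  set.seed(11)
  cfg <- trnn_config(embed_dim = 6, heads = 2, lstm_hidden = 3, dropout = 0,
                     n_layers = 1, d_ff = 10, max_len = 6, n_classes = 3)
  vocab <- tiny_vocab()
  params <- trnn_init_params(cfg, vocab$size, seed = 13)
  docs <- list(list(tokens = c("a", "b", "c"), label = "suicide_note"),
               list(tokens = c("d", "e", "f", "g", "h"), label = "neutral"))
  batch <- encode_batch(docs, vocab, max_len = 6)
  fwd <- trnn_forward(params, batch, cfg, keep_cache = TRUE)
  grads <- trnn_backward(params, batch, cfg, fwd)
  flat <- flatten_params(params)
  eps <- 1e-5
  for (nm in names(flat)) {
    idx <- sample(length(flat[[nm]]), min(4, length(flat[[nm]])))
    for (i in idx) {
      f2 <- flat
      f2[[nm]][i] <- f2[[nm]][i] + eps
      lp <- trnn_forward(unflatten_params(f2, params), batch, cfg)$loss
      f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
      lm <- trnn_forward(unflatten_params(f2, params), batch, cfg)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("published parameter-count formula matches the instantiated model", {
  cfg <- trnn_config(embed_dim = 200, heads = 4, lstm_hidden = 128,
                     n_layers = 1)
  vs <- 500L
  params <- trnn_init_params(cfg, vs, seed = 1)
  n_actual <- sum(vapply(flatten_params(params), length, integer(1)))
  expect_equal(trnn_param_count(cfg, vs), n_actual)
  for (abl in c("no_bilstm", "no_concat_embedding")) {
    args <- list(embed_dim = 16, heads = 2, lstm_hidden = 5, n_layers = 2,
                 d_ff = 24)
    args[[abl]] <- TRUE
    cfg2 <- do.call(trnn_config, args)
    p2 <- trnn_init_params(cfg2, 40L, seed = 2)
    expect_equal(trnn_param_count(cfg2, 40L),
                 sum(vapply(flatten_params(p2), length, integer(1))))
  }
})
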
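# Training tests use a deliberately small architecture; the full published
# configuration is exercised in the acceptance suite.
small_cfg <- function(...) {
  trnn_config(embed_dim = 16, heads = 2, lstm_hidden = 8, dropout = 0.2,
              n_layers = 1, d_ff = 32, max_len = 40, ...)
}

test_that("metrics match the hand-computed contingency-table example", {
  gold <- c(0, 0, 1, 1, 2, 2, 2, 2, 2, 2)
  pred <- c(0, 1, 1, 1, 2, 2, 2, 2, 2, 0)
  m <- compute_metrics(gold, pred, n_classes = 3)
  # class 0: tp=1 fp=1 fn=1 -> P=R=F1=0.5
  expect_equal(m$per_class$precision[1], 0.5)
  expect_equal(m$per_class$recall[1], 0.5)
  # class 1: tp=2 fp=1 fn=0 -> P=2/3, R=1, F1=0.8
  expect_equal(m$per_class$precision[2], 2 / 3)
  expect_equal(m$per_class$recall[2], 1)
  expect_equal(m$per_class$f1[2], 0.8)
  # class 2: tp=5 fp=0 fn=1 -> P=1, R=5/6
  expect_equal(m$per_class$recall[3], 5 / 6)
  orc <- oracle_metrics(gold, pred, 3)
  expect_equal(m$weighted, orc$weighted, tolerance = 1e-15)
  expect_equal(sum(diag(m$confusion)), 8)
  expect_equal(rowSums(m$confusion), m$per_class$support,
               ignore_attr = TRUE)
})

test_that("metrics agree with an independent loop reference on random vectors", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    gold <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    m <- compute_metrics(gold, pred, 3)
    orc <- oracle_metrics(gold, pred, 3)
    expect_equal(m$per_class$precision, orc$precision, tolerance = 1e-12)
    expect_equal(m$per_class$recall, orc$recall, tolerance = 1e-12)
    expect_equal(m$per_class$f1, orc$f1, tolerance = 1e-12)
    expect_equal(m$weighted, orc$weighted, tolerance = 1e-12)
    # row-normalized confusion rows sum to 1 where the class occurs
    nz <- m$per_class$support > 0
    expect_equal(unname(rowSums(m$confusion_normalized)[nz]),
                 rep(1, sum(nz)), tolerance = 1e-12)
    # weighted F1 lies between the extreme per-class F1 values
    expect_gte(m$weighted[["f1"]], min(m$per_class$f1[nz]) - 1e-12)
    expect_lte(m$weighted[["f1"]], max(m$per_class$f1[nz]) + 1e-12)
  }
})

test_that("perfect and single-class predictions give the expected degenerate metrics", {
  m <- compute_metrics(c(0, 1, 2, 2), c(0, 1, 2, 2), 3)
  expect_equal(m$per_class$f1, rep(1, 3))
  expect_true(all(m$confusion[upper.tri(m$confusion)] == 0))
  ms <- compute_metrics(rep(1, 6), c(1, 1, 1, 1, 1, 0), 3)
  expect_equal(unname(ms$weighted["recall"]), ms$per_class$recall[2])
})

test_that("a small model overfits a tiny separable corpus", {
  corp <- small_separable_corpus(n_per_class = 6, seed = 31, doc_len = 15)
  fit <- trnn(corp, config = small_cfg(),
              control = trnn_control(max_epochs = 200, seed = 1,
                                     target_train_acc = 1))
  expect_equal(fit$history$train_acc[nrow(fit$history)], 1)
  m <- evaluate(fit, corp)
  expect_equal(unname(m$weighted["f1"]), 1)
})

test_that("training is deterministic: identical seeds give identical fits", {
  corp <- small_separable_corpus(n_per_class = 8, seed = 41, doc_len = 12)
  sp <- split_corpus(corp, seed = 41)
  ctl <- trnn_control(max_epochs = 3, patience = 3, seed = 9, batch_size = 8)
  f1 <- trnn(sp$train, sp$val, config = small_cfg(), control = ctl)
  f2 <- trnn(sp$train, sp$val, config = small_cfg(), control = ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- trnn(sp$train, sp$val, config = small_cfg(),
             control = trnn_control(max_epochs = 3, patience = 3, seed = 10,
                                    batch_size = 8))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("patience = 0 stops after the first non-improving epoch", {
  corp <- small_separable_corpus(n_per_class = 8, seed = 51, doc_len = 10)
  sp <- split_corpus(corp, seed = 51)
  fit <- trnn(sp$train, sp$val, config = small_cfg(),
              control = trnn_control(max_epochs = 50, patience = 0, seed = 2,
                                     batch_size = 8))
  h <- fit$history
  expect_lt(nrow(h), 50)
  expect_equal(nrow(h), fit$best_epoch + 1L)
  # best epoch is the argmax of validation F1, earliest on ties
  expect_equal(fit$best_epoch,
               which(h$val_f1 == max(h$val_f1))[1])
})

test_that("prediction is deterministic and identical batched or one-by-one", {
  corp <- small_separable_corpus(n_per_class = 4, seed = 61, doc_len = 10)
  fit <- trnn(corp, config = small_cfg(),
              control = trnn_control(max_epochs = 2, seed = 3, batch_size = 4))
  texts <- vapply(corp$documents[c(1, 5, 9, 12)], `[[`, character(1), "text")
  pb <- predict(fit, texts, type = "prob")
  expect_equal(rowSums(pb), rep(1, 4), tolerance = 1e-6)
  expect_identical(pb, predict(fit, texts, type = "prob"))
  one <- t(vapply(texts, function(tx) predict(fit, tx, type = "prob")[1, ],
                  numeric(3)))
  expect_equal(unname(one), unname(pb), tolerance = 1e-6)
  expect_warning(p_empty <- predict(fit, c("", texts[1]), type = "both"),
                 "empty")
  expect_true(is.na(p_empty$class[1]))
  expect_false(is.na(p_empty$class[2]))
})

test_that("checkpoints round-trip through save and load", {
  corp <- small_separable_corpus(n_per_class = 4, seed = 71, doc_len = 8)
  fit <- trnn(corp, config = small_cfg(),
              control = trnn_control(max_epochs = 1, seed = 4, batch_size = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_trnn(fit, path)
  back <- load_trnn(path)
  expect_identical(coef(back), coef(fit))
  texts <- corp$documents[[1]]$text
  expect_identical(predict(back, texts, type = "prob"),
                   predict(fit, texts, type = "prob"))
})

test_that("ablation runner validates variants and reports all four", {
  corp <- small_separable_corpus(n_per_class = 8, seed = 81, doc_len = 10)
  sp <- split_corpus(corp, seed = 81)
  expect_error(run_ablation("no_dropout", sp$train, sp$val, sp$test),
               "unknown variant")
  ctl <- trnn_control(max_epochs = 2, patience = 2, seed = 5, batch_size = 8)
  tab <- ablation_report(sp$train, sp$val, sp$test, config = small_cfg(),
                         control = ctl)
  expect_equal(tab$variant, c("full", "no_max_pool", "no_bilstm",
                              "no_concat_embedding"))
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
  runs <- attr(tab, "runs")
  # no_bilstm pools the concatenated representation: classifier input 2*d_model
  expect_equal(nrow(runs[[3]]$model$params$cls$W3), 2 * 16)
  expect_equal(nrow(runs[[1]]$model$params$cls$W3), 2 * 8)
})

test_that("frozen embeddings stay fixed while the rest of the model trains", {
  corp <- small_separable_corpus(n_per_class = 4, seed = 95, doc_len = 8)
  cfg <- small_cfg(freeze_embeddings = TRUE)
  ctl <- trnn_control(max_epochs = 2, seed = 7, batch_size = 4)
  fit <- trnn(corp, config = cfg, control = ctl)
  init_E <- build_embedding_matrix(build_vocab(corp), NULL,
                                   dim = cfg$embed_dim, seed = ctl$seed)
  expect_equal(fit$params$E, init_E, ignore_attr = TRUE)
  # classifier weights did move
  fit2 <- trnn(corp, config = small_cfg(), control = ctl)
  expect_false(identical(fit2$params$E, init_E))
})

test_that("non-finite losses abort with diagnostics", {
  corp <- small_separable_corpus(n_per_class = 4, seed = 91, doc_len = 8)
  # overflow-scale pretrained vectors drive the first forward pass to NaN
  vocab <- build_vocab(corp)
  bad <- matrix(1e308, length(vocab$tokens), 16,
                dimnames = list(vocab$tokens, NULL))
  tab <- structure(list(dim = 16, vectors = bad), class = "embedding_table")
  expect_error(
    trnn(corp, config = small_cfg(),
         control = trnn_control(max_epochs = 2, seed = 6, batch_size = 4),
         embeddings = tab),
    "non-finite")
})
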
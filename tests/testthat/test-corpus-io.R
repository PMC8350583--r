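test_that("tokenizer lower-cases, detaches punctuation and keeps contractions", {
  expect_equal(tokenize("I am sad. Goodbye world."),
               c("i", "am", "sad", ".", "goodbye", "world", "."))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("   "), character(0))
  # documented contraction rule: apostrophe between alphanumerics stays in
  expect_equal(tokenize("Don't!"), c("don't", "!"))
  expect_equal(tokenize("'quoted'"), c("'", "quoted", "'"))
})

test_that("tokenizer is idempotent on its own joined output", {
  texts <- c("I am sad. Goodbye world.", "Don't stop-me now!!",
             "Numbers 123 and e-mail a@b.c", "A! B? C.")
  for (tx in texts) {
    tk <- tokenize(tx)
    expect_equal(tokenize(paste(tk, collapse = " ")), tk)
  }
})

test_that("sentence splitting honors ./!/? followed by whitespace or end", {
  expect_length(split_sentences("I am sad. Goodbye world."), 2)
  expect_equal(split_sentences("no terminator"), "no terminator")
  expect_equal(split_sentences("A! B? C."), c("A!", "B?", "C."))
  expect_equal(split_sentences("Wait... really"), c("Wait...", "really"))
  expect_equal(split_sentences("Wait...really"), "Wait...really")
  expect_length(split_sentences(""), 0)
})

test_that("label variants are canonicalized and unknown labels rejected with line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"text":"a b","label":"Suicide Note"}',
               '{"text":"c d","label":"last_statement"}',
               '{"text":"e f","label":"NEUTRAL"}'), path)
  corp <- read_corpus(path)
  expect_equal(corpus_labels(corp),
               c("suicide_note", "last_statement", "neutral"))
  writeLines(c('{"text":"a","label":"neutral"}',
               '{"text":"b","label":"poem"}'), path)
  expect_error(read_corpus(path), "line 2")
})

test_that("empty-text records are rejected with a warning and counted", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"text":"a b","label":"neutral"}',
               '{"text":"  ","label":"neutral"}'), path)
  expect_warning(corp <- read_corpus(path), "empty text")
  expect_length(corp, 1)
  expect_equal(attr(corp, "n_rejected"), 1L)
})

test_that("corpora round-trip through JSONL and CSV", {
  corp <- labeled_corpus(
    c("I am sad. Goodbye world.", "He said \"hi, there\"", "Don't, ok?"),
    c("suicide_note", "last_statement", "neutral"))
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_corpus(corp, path, format = fmt)
    back <- read_corpus(path, format = fmt)
    expect_equal(corpus_labels(back), corpus_labels(corp))
    for (i in seq_along(corp$documents)) {
      expect_equal(back$documents[[i]]$tokens, corp$documents[[i]]$tokens)
    }
  }
})

test_that("vocabulary applies the frequency threshold and deterministic id order", {
  corp <- labeled_corpus(c("a a a b", "x y x y"),
                         c("neutral", "neutral"))
  v2 <- build_vocab(corp, min_freq = 2)
  expect_true("a" %in% v2$tokens)
  expect_false("b" %in% v2$tokens)
  v1 <- build_vocab(corp, min_freq = 1)
  expect_setequal(v1$tokens, c("a", "b", "x", "y"))
  # frequency desc then lexicographic: a(3), x(2), y(2), b(1)
  expect_equal(v1$tokens, c("a", "x", "y", "b"))
  expect_equal(vocab_ids(v1, c("a", "x", "zzz")), c(2L, 3L, 1L))
  expect_error(build_vocab(corp[0]), "empty")
})

test_that("stratified split follows the floor rule and partitions the corpus", {
  corp <- small_separable_corpus(n_per_class = 10, seed = 3, doc_len = 8)
  sp <- split_corpus(corp, seed = 5)
  # 10 per class: floor(1.5) = 1 to val and test, 8 to train
  expect_equal(length(sp$train), 24)
  expect_equal(length(sp$val), 3)
  expect_equal(length(sp$test), 3)
  for (part in c("train", "val", "test")) {
    counts <- table(corpus_labels(sp[[part]]))[TRNN_LABELS_for_test()]
    expect_equal(as.integer(counts),
                 rep(c(train = 8L, val = 1L, test = 1L)[[part]], 3))
  }
  # partition: disjoint by document identity, union = corpus
  expect_equal(sort(sp$manifest$doc_index), 1:30)
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), 30)
  # determinism
  sp2 <- split_corpus(corp, seed = 5)
  expect_identical(sp$manifest, sp2$manifest)
  sp3 <- split_corpus(corp, seed = 6)
  expect_false(identical(sp$manifest$partition, sp3$manifest$partition))
})

test_that("split errors when a class has fewer than 3 documents", {
  corp <- labeled_corpus(
    c("a b", "c d", "e f", "g h", "i j", "k l", "m n"),
    c(rep("suicide_note", 3), rep("last_statement", 3), "neutral"))
  expect_error(split_corpus(corp), "neutral")
})

test_that("encode_batch pads, truncates and maps unknown tokens to OOV", {
  vocab <- tiny_vocab(c("a", "b", "c"))
  docs <- tiny_docs(list(c("a", "b", "c"), c("a", "zzz")))
  batch <- encode_batch(docs, vocab, max_len = 5)
  expect_equal(dim(batch$ids), c(2, 5))
  expect_equal(batch$mask[1, ], c(1, 1, 1, 0, 0))
  expect_equal(batch$ids[1, 4:5], c(0L, 0L))          # PAD
  expect_equal(batch$ids[2, 2], 1L)                   # OOV
  long <- tiny_docs(list(letters[1:7]))
  bt <- encode_batch(long, vocab, max_len = 5)
  expect_equal(bt$lengths, 5L)
  expect_error(encode_batch(list(), vocab, 5), "empty")
})

test_that("encode_batch mask/id invariants hold on generated corpora", {
  corp <- small_separable_corpus(n_per_class = 5, seed = 9, doc_len = 15)
  vocab <- build_vocab(corp)
  batch <- encode_batch(corp, vocab, max_len = 12)
  lens <- vapply(corp$documents, function(d) length(d$tokens), integer(1))
  expect_equal(rowSums(batch$mask), pmin(lens, 12))
  expect_true(all(batch$ids[batch$mask == 0] == 0))
  expect_true(all(batch$ids[batch$mask == 1] >= 1))
})
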
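# Small shared fixtures built in code.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 8, heads = 2, lstm_hidden = 4, dropout = 0,
         n_layers = 1, d_ff = 16, max_len = 12),
    list(...))
  do.call(trnn_config, args)
}

tiny_vocab <- function(tokens = letters[1:10]) {
  corp <- labeled_corpus(paste(tokens, collapse = " "), "neutral")
  build_vocab(corp)
}

tiny_docs <- function(token_sets) {
  lapply(token_sets, function(tk) list(tokens = tk, label = NULL))
}

# A small, clearly separable generated corpus for training tests.
small_separable_corpus <- function(n_per_class = 10, seed = 7,
                                   doc_len = 25) {
  generate_corpus(generator_config(
    class_counts = c(suicide_note = n_per_class,
                     last_statement = n_per_class, neutral = n_per_class),
    doc_length_mean = rep(doc_len, 3), sentence_length_mean = rep(8, 3),
    shared_vocab = 100, class_vocab = 30, seed = seed))
}

# canonical label order without touching package internals
TRNN_LABELS_for_test <- function() c("suicide_note", "last_statement", "neutral")

random_probs <- function(n, c) {
  P <- matrix(stats::rexp(n * c), n)
  P / rowSums(P)
}
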
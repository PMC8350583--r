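#' Built-in demonstration category lexicon
#'
#' A small lexicon in the spirit of psycholinguistic word-count categories
#' (personal pronouns, positive and negative emotion, social processes,
#' death), used by the synthetic generator and the examples. It is a
#' demonstration artifact, not a reproduction of any proprietary
#' dictionary.
#'
#' @return a `category_lexicon`.
#' @export
demo_lexicon <- function() {
  as_lexicon(list(
    pronoun = c("i", "me", "my", "mine", "myself", "you", "your", "we",
                "us", "our"),
    posemo = c("love", "happy", "hope", "good", "nice", "great", "joy",
               "peace", "grateful"),
    negemo = c("sad", "pain", "hurt", "cry", "fear", "sorry", "alone",
               "hate", "guilt"),
    social = c("friend*", "family", "mother", "father", "brother",
               "sister", "talk*", "together"),
    death = c("death", "die*", "dead", "grave", "funeral", "goodbye")))
}

#' Synthetic corpus generator configuration
#'
#' The generator emulates the structure of the study corpus: three classes
#' with the published imbalance (659:431:2000, scaled down by default),
#' per-class document lengths around the published means (143.3, 111.0 and
#' 130.9 words), per-class sentence lengths (about 15.1, 10.5 and 16.3
#' words), distinct class-specific vocabularies mixed into a shared Zipf
#' background, and lexicon-category tokens injected at rates that realize
#' configured between-class effect sizes (in pooled-SD units). Documents
#' are streams of synthetic symbols, not natural language.
#'
#' @param class_counts named integer vector of documents per class
#'   (suicide_note, last_statement, neutral).
#' @param class_token_boost probability in `[0, 1]` that a background
#'   token is drawn from the class-specific vocabulary rather than the
#'   shared one; 0 means no class signal.
#' @param doc_length_mean per-class mean words per document.
#' @param doc_length_dispersion negative-binomial size parameter (larger =
#'   less length spread).
#' @param sentence_length_mean per-class mean words per sentence.
#' @param shared_vocab,class_vocab sizes of the shared and per-class
#'   symbol vocabularies.
#' @param lexicon a `category_lexicon` whose words are injected.
#' @param category_base_rate baseline per-token injection probability per
#'   category.
#' @param category_shifts named list: per category, a length-3 numeric
#'   vector of per-class offsets in pooled-SD units; the realized Cohen's
#'   d between classes a and b is approximately `shift[a] - shift[b]`.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return object of class `trnn_gen_config`.
#' @export
generator_config <- function(class_counts = c(suicide_note = 132,
                                              last_statement = 86,
                                              neutral = 400),
                             class_token_boost = 0.5,
                             doc_length_mean = c(143.3, 111.0, 130.9),
                             doc_length_dispersion = 20,
                             sentence_length_mean = c(15.1, 10.5, 16.3),
                             shared_vocab = 800, class_vocab = 120,
                             lexicon = demo_lexicon(),
                             category_base_rate = 0.02,
                             category_shifts = list(
                               pronoun = c(0.5, 0.8, 0),
                               posemo = c(0.2, 0.8, 0),
                               negemo = c(0.8, 0.2, 0),
                               social = c(0, 0.8, 0.2),
                               death = c(0.8, 0.5, 0)),
                             seed = 1) {
  stopifnot(length(class_counts) == 3, all(class_counts >= 1),
            class_token_boost >= 0, class_token_boost <= 1,
            all(doc_length_mean >= 1), doc_length_dispersion > 0,
            all(sentence_length_mean >= 1),
            shared_vocab >= 1, class_vocab >= 1,
            category_base_rate > 0, category_base_rate < 0.5,
            all(names(category_shifts) %in% names(lexicon)))
  if (is.null(names(class_counts))) names(class_counts) <- TRNN_LABELS
  structure(list(class_counts = class_counts,
                 class_token_boost = class_token_boost,
                 doc_length_mean = doc_length_mean,
                 doc_length_dispersion = doc_length_dispersion,
                 sentence_length_mean = sentence_length_mean,
                 shared_vocab = shared_vocab, class_vocab = class_vocab,
                 lexicon = lexicon,
                 category_base_rate = category_base_rate,
                 category_shifts = category_shifts, seed = seed),
            class = "trnn_gen_config")
}

# E[1/N] for the truncated (>= 5) negative-binomial document length,
# computed numerically; used to convert pooled-SD shift targets into
# injection-rate offsets.
expected_inv_length <- function(mu, size) {
  hi <- max(stats::qnbinom(0.99999, mu = mu, size = size), 10)
  n <- 5:hi
  p <- stats::dnbinom(n, mu = mu, size = size)
  p <- p + c(sum(stats::dnbinom(0:4, mu = mu, size = size)),
             rep(0, length(n) - 1))  # mass below 5 clamps to 5
  sum(p / n) / sum(p)
}

# Per-class injection probability for one category. A document's category
# rate is Binomial(n, p)/n, with variance v(p) = p(1-p) E[1/n], so the
# Cohen's d of class c against the base rate p0 is
# (p - p0) / sqrt((v(p) + v(p0)) / 2). Each class's p is solved from its
# shift target against that pairwise pooled SD (variance grows with p, so
# solving at the base rate alone would bias realized effects low).
# Between two classes that are both shifted, the realized d is
# shift_a - shift_b only approximately.
category_probs <- function(config) {
  einv <- mean(vapply(config$doc_length_mean, expected_inv_length,
                      numeric(1), size = config$doc_length_dispersion))
  p0 <- config$category_base_rate
  v <- function(p) p * (1 - p) * einv
  solve_p <- function(shift) {
    if (shift == 0) return(p0)
    g <- function(p) (p - p0) / sqrt((v(p) + v(p0)) / 2) - shift
    stats::uniroot(g, lower = 1e-4, upper = 0.45, tol = 1e-10)$root
  }
  probs <- matrix(p0, length(config$lexicon), 3,
                  dimnames = list(names(config$lexicon), NULL))
  for (cat_name in names(config$category_shifts)) {
    probs[cat_name, ] <- vapply(config$category_shifts[[cat_name]], solve_p,
                                numeric(1))
  }
  probs
}

#' Generate a synthetic labeled corpus
#'
#' Samples documents class by class from fixed unigram mixtures: with the
#' per-category injection probabilities from the configured effect-size
#' shifts, a token is a (lower-cased, de-wildcarded) lexicon word;
#' otherwise with probability `class_token_boost` a class-specific symbol
#' and else a shared symbol, both Zipf-distributed. The word stream is cut
#' into period-terminated sentences around the configured sentence length.
#' Deterministic given the config seed; the caller's RNG is untouched.
#'
#' @param config a [generator_config()].
#' @return a `labeled_corpus`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "trnn_gen_config"))
  zipf <- function(V) { w <- 1 / seq_len(V); w / sum(w) }
  shared_tokens <- sprintf("w%04d", seq_len(config$shared_vocab))
  class_tokens <- lapply(c("ka", "kb", "kc"), function(pfx)
    sprintf("%s%04d", pfx, seq_len(config$class_vocab)))
  cat_words <- lapply(config$lexicon, function(p) sub("\\*$", "", p))
  cat_probs <- category_probs(config)

  with_seed(config$seed, {
    texts <- character(0); labels <- character(0)
    for (ci in 1:3) {
      lab <- names(config$class_counts)[ci]
      # class unigram distribution over [category words, class vocab, shared]
      p_cat <- cat_probs[, ci]
      cat_tok <- unlist(lapply(names(cat_words), function(cn)
        cat_words[[cn]]), use.names = FALSE)
      cat_p <- unlist(lapply(names(cat_words), function(cn)
        rep(p_cat[cn] / length(cat_words[[cn]]), length(cat_words[[cn]]))),
        use.names = FALSE)
      rest <- 1 - sum(p_cat)
      toks <- c(cat_tok,
                class_tokens[[ci]],
                shared_tokens)
      prb <- c(cat_p,
               rest * config$class_token_boost * zipf(config$class_vocab),
               rest * (1 - config$class_token_boost) * zipf(config$shared_vocab))
      n_docs <- config$class_counts[ci]
      lens <- pmax(stats::rnbinom(n_docs, mu = config$doc_length_mean[ci],
                                  size = config$doc_length_dispersion), 5)
      for (k in seq_len(n_docs)) {
        words <- sample(toks, lens[k], replace = TRUE, prob = prb)
        texts <- c(texts, assemble_sentences(words,
                                             config$sentence_length_mean[ci]))
        labels <- c(labels, lab)
      }
    }
    labeled_corpus(texts, labels)
  })
}

# Cut a word stream into period-terminated sentences with Poisson-spread
# lengths around the target mean.
assemble_sentences <- function(words, mean_len) {
  n <- length(words)
  out <- character(0)
  pos <- 1
  while (pos <= n) {
    s <- max(1, stats::rpois(1, lambda = mean_len - 1) + 1)
    end <- min(pos + s - 1, n)
    out <- c(out, paste0(paste(words[pos:end], collapse = " "), "."))
    pos <- end + 1
  }
  paste(out, collapse = " ")
}

#' Generate a GloVe-format embedding file
#'
#' Writes deterministic unit-norm random vectors, one `token v1 ... vd`
#' line per token, valid for [load_vectors()].
#'
#' @param tokens character vector of tokens.
#' @param dim vector dimension (>= 2).
#' @param seed integer seed.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
generate_embedding_file <- function(tokens, dim, seed = 1, path) {
  stopifnot(dim >= 2, length(tokens) >= 1)
  V <- with_seed(seed, matrix(stats::rnorm(length(tokens) * dim),
                              length(tokens)))
  V <- V / sqrt(rowSums(V^2))
  lines <- vapply(seq_along(tokens), function(i) {
    paste(tokens[i], paste(sprintf("%.8f", V[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a self-contained fixture directory
#'
#' Emits a synthetic corpus as JSONL, its stratified split manifest, the
#' lexicon (text format) and a matching embedding file.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if missing).
#' @param embed_dim embedding dimension for the generated vector file.
#' @return invisibly, a list with the corpus, the split and the paths.
#' @export
generate_fixture_dir <- function(config = generator_config(), dir,
                                 embed_dim = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config)
  write_corpus(corpus, file.path(dir, "corpus.jsonl"))
  sp <- split_corpus(corpus, seed = config$seed)
  write_split_manifest(sp$manifest, file.path(dir, "split.jsonl"))
  lex_lines <- vapply(names(config$lexicon), function(cn) {
    paste0(cn, ": ", paste(config$lexicon[[cn]], collapse = " "))
  }, character(1))
  writeLines(lex_lines, file.path(dir, "lexicon.txt"), useBytes = TRUE)
  vocab <- build_vocab(corpus)
  generate_embedding_file(vocab$tokens, embed_dim, seed = config$seed,
                          path = file.path(dir, "vectors.txt"))
  invisible(list(corpus = corpus, split = sp,
                 paths = file.path(dir, c("corpus.jsonl", "split.jsonl",
                                          "lexicon.txt", "vectors.txt"))))
}
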
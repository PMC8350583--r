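# Word tokens are tokens containing at least one alphanumeric character;
# pure punctuation tokens are excluded from all counts in this module.
word_tokens <- function(tokens) tokens[grepl("[[:alnum:]]", tokens)]

#' Per-class corpus summary statistics
#'
#' For every class present in the corpus: the number of documents, the
#' average number of words per document, and the average number of words
#' per sentence (total words divided by total sentences). Words are
#' non-punctuation tokens; sentences come from [split_sentences()]. A
#' class in the label set with no documents is omitted with a warning.
#'
#' @param corpus a non-empty `labeled_corpus`.
#' @return data.frame of class `corpus_summary` with columns `class`,
#'   `n_notes`, `avg_words_per_note`, `avg_words_per_sentence`.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"), length(corpus) > 0)
  labs <- corpus_labels(corpus)
  rows <- list()
  for (l in corpus$label_set) {
    idx <- which(labs == l)
    if (length(idx) == 0) {
      warning("class '", l, "' absent from corpus; row omitted")
      next
    }
    words <- vapply(corpus$documents[idx],
                    function(d) length(word_tokens(d$tokens)), integer(1))
    sents <- vapply(corpus$documents[idx],
                    function(d) length(split_sentences(d$text)), integer(1))
    rows[[l]] <- data.frame(class = l, n_notes = length(idx),
                            avg_words_per_note = mean(words),
                            avg_words_per_sentence = sum(words) / max(sum(sents), 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("corpus_summary", "data.frame")
  out
}

#' Read a category lexicon
#'
#' Two formats: plain text with one `category: word1 word2 friend*` line
#' per category, or a JSON object mapping category names to arrays of
#' patterns. A trailing `*` in a pattern matches any suffix (prefix
#' match); all matching is on lower-cased word tokens.
#'
#' @param path lexicon file path.
#' @return object of class `category_lexicon`: named list of character
#'   pattern vectors.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lx <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    lx <- lapply(lx, as.character)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lx <- list()
    for (i in seq_along(lines)) {
      parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
      if (length(parts) < 2) stop("malformed lexicon line ", i, ": ", lines[i])
      cat_name <- trimws(parts[1])
      words <- strsplit(trimws(paste(parts[-1], collapse = ":")),
                        "[ \t]+")[[1]]
      lx[[cat_name]] <- words
    }
  }
  as_lexicon(lx)
}

#' Construct a category lexicon from a named list
#' @param x named list of character pattern vectors.
#' @return a `category_lexicon`.
#' @export
as_lexicon <- function(x) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)), all(nzchar(names(x))))
  x <- lapply(x, function(w) tolower(as.character(w)))
  if (any(vapply(x, length, integer(1)) == 0)) stop("empty category in lexicon")
  structure(x, class = "category_lexicon")
}

# Match word tokens against one category's patterns: exact matches plus
# prefix matches for patterns with a trailing '*'.
match_category <- function(words, patterns) {
  exact <- patterns[!endsWith(patterns, "*")]
  pref <- sub("\\*$", "", patterns[endsWith(patterns, "*")])
  hit <- words %in% exact
  for (p in pref) hit <- hit | startsWith(words, p)
  hit
}

#' Lexicon category rates for one document
#'
#' For each category, the percentage of the document's word tokens that
#' match the category's patterns (a token may count toward several
#' categories). Punctuation-only tokens are excluded from both numerator
#' and denominator.
#'
#' @param doc a document (list with `tokens`), or a character scalar of
#'   raw text.
#' @param lexicon a `category_lexicon`.
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
category_rates <- function(doc, lexicon) {
  if (is.character(doc)) doc <- list(tokens = tokenize(doc))
  words <- word_tokens(doc$tokens)
  if (length(words) == 0) stop("document has no word tokens")
  if (length(lexicon) == 0) return(stats::setNames(numeric(0), character(0)))
  vapply(lexicon, function(p) 100 * sum(match_category(words, p)) / length(words),
         numeric(1))
}

# Per-document rate matrix for a corpus (documents x categories). Documents
# without word tokens are dropped with a warning.
corpus_category_rates <- function(corpus, lexicon) {
  ok <- vapply(corpus$documents,
               function(d) length(word_tokens(d$tokens)) > 0, logical(1))
  if (any(!ok)) warning(sum(!ok), " document(s) without word tokens skipped")
  docs <- corpus$documents[ok]
  out <- t(vapply(docs, function(d) category_rates(d, lexicon),
                  numeric(length(lexicon))))
  colnames(out) <- names(lexicon)
  out
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' `d = (mean(x) - mean(y)) / s_p` with the classic pooled SD
#' `s_p^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)` using
#' sample (n-1) variances. By convention here |d| of 0.2, 0.5 and 0.8 mark
#' small, medium and large effects.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return signed scalar d.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("degenerate samples: pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Magnitude label from |d|: below 0.5 small, [0.5, 0.8) medium, >= 0.8 large.
d_magnitude <- function(d) {
  ad <- abs(d)
  ifelse(ad >= 0.8, "large", ifelse(ad >= 0.5, "medium", "small"))
}

#' Effect-size screening between two corpora
#'
#' Computes per-document category rates in both corpora and, per category,
#' the signed Cohen's d of corpus A minus corpus B, the group means/SDs and
#' a magnitude label. Rows are sorted by |d| descending; rows at or above
#' `threshold` are flagged. Categories with zero pooled SD are reported
#' with `d = NA` and `degenerate = TRUE` rather than dropped.
#'
#' @param corpus_a,corpus_b non-empty labeled corpora.
#' @param lexicon a `category_lexicon`.
#' @param threshold |d| flagging threshold (default 0.5, a medium effect).
#' @return data.frame of class `effect_size_table` with columns `feature`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `d`, `magnitude`,
#'   `flagged`, `degenerate`.
#' @export
effect_size_table <- function(corpus_a, corpus_b, lexicon, threshold = 0.5) {
  stopifnot(length(corpus_a) > 0, length(corpus_b) > 0)
  ra <- corpus_category_rates(corpus_a, lexicon)
  rb <- corpus_category_rates(corpus_b, lexicon)
  rows <- lapply(names(lexicon), function(cat_name) {
    x <- ra[, cat_name]; y <- rb[, cat_name]
    d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
    data.frame(feature = cat_name,
               mean_a = mean(x), sd_a = stats::sd(x), n_a = length(x),
               mean_b = mean(y), sd_b = stats::sd(y), n_b = length(y),
               d = d,
               magnitude = if (is.na(d)) NA_character_ else d_magnitude(d),
               flagged = !is.na(d) && abs(d) >= threshold,
               degenerate = is.na(d))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$d), method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("effect_size_table", "data.frame")
  out
}

#' Top terms by frequency
#'
#' Case-folded n-gram counts (orders 1 to `ngram_max`) over word tokens,
#' with optional stopword removal, ranked by frequency descending. Ties
#' are broken by n-gram order (longer first), then lexicographically.
#' N-grams do not cross document boundaries.
#'
#' @param corpus a `labeled_corpus`.
#' @param k number of terms to return (>= 1).
#' @param ngram_max maximum n-gram order.
#' @param stopwords character vector of tokens to drop before counting.
#' @return data.frame with columns `term` and `frequency`, at most `k`
#'   rows.
#' @export
top_terms <- function(corpus, k = 20, ngram_max = 1, stopwords = character()) {
  stopifnot(k >= 1, ngram_max >= 1)
  counts <- new.env(parent = emptyenv())
  tally <- list()
  for (d in corpus$documents) {
    w <- word_tokens(d$tokens)
    w <- w[!w %in% stopwords]
    if (length(w) == 0) next
    for (n in seq_len(min(ngram_max, length(w)))) {
      if (n == 1) {
        grams <- w
      } else {
        m <- length(w) - n + 1
        grams <- vapply(seq_len(m), function(s) paste(w[s:(s + n - 1)],
                                                      collapse = " "),
                        character(1))
      }
      tally[[length(tally) + 1L]] <- grams
    }
  }
  if (length(tally) == 0) {
    return(data.frame(term = character(0), frequency = integer(0)))
  }
  tab <- table(unlist(tally, use.names = FALSE))
  term <- names(tab)
  freq <- as.integer(tab)
  order_n <- lengths(strsplit(term, " ", fixed = TRUE))
  ord <- order(-freq, -order_n, term, method = "radix")
  out <- data.frame(term = term[ord], frequency = freq[ord])
  utils::head(out, k)
}

#' Write a corpus summary or effect-size table as CSV
#' @param x a `corpus_summary` or `effect_size_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
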
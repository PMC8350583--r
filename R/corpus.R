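#' @keywords internal
"_PACKAGE"

# Canonical label set; order fixes the integer class coding used everywhere:
# suicide_note = 0, last_statement = 1, neutral = 2.
TRNN_LABELS <- c("suicide_note", "last_statement", "neutral")

#' Construct a labeled corpus
#'
#' A labeled corpus is the unit of input for fitting and profiling: a set of
#' free-text documents, each carrying one of the three closed-set class
#' labels (`suicide_note`, `last_statement`, `neutral`). Tokenization is
#' applied once, deterministically, at construction.
#'
#' @param text character vector of document texts.
#' @param label character vector of labels, recycled against `text`; each is
#'   canonicalized (lower-case, spaces to underscores) and must then be one
#'   of the closed label set.
#' @param label_set ordered character vector of admissible labels. The
#'   default order fixes the integer class coding.
#' @return An object of class `labeled_corpus`: a list with elements
#'   `documents` (list of documents, each with `text`, `tokens`, `label`)
#'   and `label_set`.
#' @examples
#' corp <- labeled_corpus(c("I am sad. Goodbye.", "Nice weather today."),
#'                        c("suicide_note", "neutral"))
#' length(corp)
#' @export
labeled_corpus <- function(text, label, label_set = TRNN_LABELS) {
  stopifnot(is.character(text), length(text) >= 1)
  label <- canonicalize_label(rep_len(as.character(label), length(text)))
  bad <- which(!label %in% label_set)
  if (length(bad) > 0) {
    stop("unknown label '", label[bad[1]], "' at document ", bad[1],
         "; expected one of: ", paste(label_set, collapse = ", "))
  }
  docs <- vector("list", length(text))
  for (i in seq_along(text)) {
    docs[[i]] <- list(text = text[i], tokens = tokenize(text[i]), label = label[i])
  }
  structure(list(documents = docs, label_set = label_set),
            class = "labeled_corpus")
}

canonicalize_label <- function(x) {
  gsub("[ ]+", "_", trimws(tolower(x)))
}

#' @export
length.labeled_corpus <- function(x) length(x$documents)

#' @export
`[.labeled_corpus` <- function(x, i) {
  structure(list(documents = x$documents[i], label_set = x$label_set),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  labs <- corpus_labels(x)
  cat("Labeled corpus:", length(x), "documents\n")
  tab <- table(factor(labs, levels = x$label_set))
  for (l in names(tab)) cat(sprintf("  %-15s %d\n", l, tab[[l]]))
  invisible(x)
}

#' Extract the label vector of a corpus
#' @param corpus a `labeled_corpus`.
#' @return character vector of document labels, in document order.
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$documents, `[[`, character(1), "label")
}

#' Integer class codes (0-based) for a corpus
#' @inheritParams corpus_labels
#' @return integer vector; position of each label in `label_set`, minus one.
#' @export
corpus_label_ids <- function(corpus) {
  match(corpus_labels(corpus), corpus$label_set) - 1L
}

#' Tokenize text
#'
#' Deterministic, language-light tokenization: lower-case, then split into
#' maximal alphanumeric runs (apostrophes between alphanumerics are kept
#' inside the word, so "don't" stays one token) and single-character
#' punctuation tokens. Whitespace never yields tokens.
#'
#' The tokenizer is idempotent on its own output: tokenizing the
#' space-joined token sequence reproduces the sequence.
#'
#' @param text a character scalar (any unicode string).
#' @return character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize("I am sad. Goodbye world.")
#' tokenize("Don't!")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  x <- tolower(text)
  m <- gregexpr("[[:alnum:]]+(?:'[[:alnum:]]+)*|[^[:space:][:alnum:]]",
                x, perl = TRUE)
  regmatches(x, m)[[1]]
}

#' Split text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace or end of text.
#' Runs of terminators stay attached to their sentence; empty sentences are
#' never returned. Text without a terminator is a single sentence.
#'
#' @param text a character scalar.
#' @return character vector of sentence strings (trimmed).
#' @examples
#' split_sentences("I am sad. Goodbye world.")
#' split_sentences("A! B? C.")
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Read a labeled corpus from JSONL or CSV
#'
#' JSONL: one object per line with keys `text` and `label`. CSV: header
#' `text,label` with RFC-4180 quoting. Labels are canonicalized (lower-case,
#' spaces to underscores) before the closed-set check; a record with an
#' unknown label aborts with its line number. Records with empty text are
#' rejected with a warning and counted in the `n_rejected` attribute.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @param label_set ordered admissible labels.
#' @return a `labeled_corpus`, with attribute `n_rejected`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        label_set = TRNN_LABELS) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines_keep <- which(nzchar(trimws(lines)))
    text <- character(length(lines_keep))
    label <- character(length(lines_keep))
    for (k in seq_along(lines_keep)) {
      i <- lines_keep[k]
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSON at line ", i,
                                               ": ", conditionMessage(e)))
      if (is.null(rec$text) || is.null(rec$label)) {
        stop("record at line ", i, " lacks 'text' or 'label'")
      }
      text[k] <- as.character(rec$text)
      label[k] <- as.character(rec$label)
      src_line <- i
      lab <- canonicalize_label(label[k])
      if (!lab %in% label_set) {
        stop("unknown label '", label[k], "' at line ", src_line,
             "; expected one of: ", paste(label_set, collapse = ", "))
      }
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    if (!all(c("text", "label") %in% names(df))) {
      stop("CSV must have columns 'text' and 'label'")
    }
    text <- df$text
    label <- df$label
    lab <- canonicalize_label(label)
    bad <- which(!lab %in% label_set)
    if (length(bad) > 0) {
      # +1 header line, so data row i is file line i+1
      stop("unknown label '", label[bad[1]], "' at line ", bad[1] + 1L,
           "; expected one of: ", paste(label_set, collapse = ", "))
    }
  }
  empty <- !nzchar(trimws(text))
  n_rejected <- sum(empty)
  if (n_rejected > 0) {
    warning(n_rejected, " record(s) with empty text rejected")
    text <- text[!empty]
    label <- label[!empty]
  }
  if (length(text) == 0) stop("no usable records in ", path)
  corp <- labeled_corpus(text, label, label_set = label_set)
  attr(corp, "n_rejected") <- n_rejected
  corp
}

#' Write a labeled corpus to JSONL or CSV
#'
#' Inverse of [read_corpus()]: a written corpus reads back with identical
#' texts, token sequences and labels.
#'
#' @param corpus a `labeled_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  text <- vapply(corpus$documents, `[[`, character(1), "text")
  label <- corpus_labels(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_along(text), function(i) {
      jsonlite::toJSON(list(text = text[i], label = label[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(data.frame(text = text, label = label,
                                stringsAsFactors = FALSE),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Build a vocabulary from a corpus
#'
#' Tokens with corpus frequency at least `min_freq` receive contiguous ids
#' starting at 2; id order is frequency descending, ties broken
#' lexicographically. Ids 0 and 1 are reserved: `PAD = 0` (padding; its
#' embedding row is pinned to zero) and `OOV = 1` (out-of-vocabulary).
#'
#' @param corpus a `labeled_corpus`.
#' @param min_freq minimum corpus frequency (>= 1) for inclusion.
#' @return an object of class `trnn_vocab`: list with `tokens` (character
#'   vector indexed by id - 1, starting at the first real token), `pad_id`
#'   (0), `oov_id` (1), and `size` (total id count including PAD/OOV).
#' @export
build_vocab <- function(corpus, min_freq = 1) {
  stopifnot(min_freq >= 1)
  if (length(corpus) == 0) stop("cannot build a vocabulary from an empty corpus")
  all_tokens <- unlist(lapply(corpus$documents, `[[`, "tokens"), use.names = FALSE)
  if (length(all_tokens) == 0) stop("corpus contains no tokens")
  freq <- table(all_tokens)
  freq <- freq[freq >= min_freq]
  if (length(freq) == 0) stop("no token reaches min_freq = ", min_freq)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  toks <- names(freq)[ord]
  structure(list(tokens = toks, pad_id = 0L, oov_id = 1L,
                 size = length(toks) + 2L),
            class = "trnn_vocab")
}

#' @export
print.trnn_vocab <- function(x, ...) {
  cat("Vocabulary:", x$size, "ids (PAD=0, OOV=1,", length(x$tokens),
      "tokens)\n")
  invisible(x)
}

#' Map tokens to integer ids
#' @param vocab a `trnn_vocab`.
#' @param tokens character vector.
#' @return integer ids; unknown tokens map to `OOV = 1`.
#' @export
vocab_ids <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  ifelse(is.na(idx), vocab$oov_id, idx + 1L)
}

#' Stratified 70/15/15 corpus split
#'
#' Splits a corpus into train/validation/test partitions, stratified by
#' class. Within each class of size n, the validation and test partitions
#' get `floor(ratio * n)` documents each and the remainder goes to train.
#' The per-class shuffle is seeded, so the split is reproducible; the global
#' RNG state is left untouched.
#'
#' @param corpus a `labeled_corpus`; every label in its label set must have
#'   at least 3 documents.
#' @param ratios numeric length-3 (train, val, test), summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train`, `val`, `test` (each a
#'   `labeled_corpus`) and `manifest` (data.frame of `doc_index`,
#'   `partition`).
#' @export
split_corpus <- function(corpus, ratios = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  labs <- corpus_labels(corpus)
  for (l in corpus$label_set) {
    if (sum(labs == l) < 3) {
      stop("class '", l, "' has fewer than 3 documents; cannot split")
    }
  }
  part <- character(length(labs))
  with_seed(seed, {
    for (l in corpus$label_set) {
      idx <- which(labs == l)
      idx <- sample(idx)
      n <- length(idx)
      n_val <- floor(ratios[2] * n)
      n_test <- floor(ratios[3] * n)
      n_train <- n - n_val - n_test
      part[idx[seq_len(n_train)]] <- "train"
      part[idx[n_train + seq_len(n_val)]] <- "val"
      part[idx[n_train + n_val + seq_len(n_test)]] <- "test"
    }
  })
  manifest <- data.frame(doc_index = seq_along(labs), partition = part,
                         stringsAsFactors = FALSE)
  list(train = corpus[part == "train"],
       val = corpus[part == "val"],
       test = corpus[part == "test"],
       manifest = manifest)
}

#' Write a split manifest as JSONL
#' @param manifest data.frame from [split_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(manifest, path) {
  lines <- vapply(seq_len(nrow(manifest)), function(i) {
    jsonlite::toJSON(list(doc_index = manifest$doc_index[i],
                          partition = manifest$partition[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Encode documents as a padded integer batch
#'
#' Maps each document's tokens to vocabulary ids, truncates at `max_len`,
#' and right-pads with `PAD = 0` into a rectangular `batch x max_len`
#' matrix. The mask marks real tokens with 1, left-aligned.
#'
#' @param docs list of documents (each with a `tokens` field), or a
#'   `labeled_corpus`.
#' @param vocab a `trnn_vocab`.
#' @param max_len number of columns (>= 1); longer documents are truncated.
#' @return list of class `padded_batch`: `ids` (integer matrix), `mask`
#'   (0/1 matrix), `lengths` (integer vector), `labels` (0-based integer
#'   vector, NA where a document carries no label).
#' @export
encode_batch <- function(docs, vocab, max_len) {
  stopifnot(max_len >= 1)
  if (inherits(docs, "labeled_corpus")) {
    label_set <- docs$label_set
    docs <- docs$documents
  } else {
    label_set <- TRNN_LABELS
  }
  if (length(docs) == 0) stop("cannot encode an empty document set")
  B <- length(docs)
  ids <- matrix(0L, B, max_len)
  mask <- matrix(0, B, max_len)
  lengths <- integer(B)
  labels <- rep(NA_integer_, B)
  for (b in seq_len(B)) {
    toks <- docs[[b]]$tokens
    if (length(toks) == 0) stop("document ", b, " has no tokens")
    n <- min(length(toks), max_len)
    ids[b, seq_len(n)] <- vocab_ids(vocab, toks[seq_len(n)])
    mask[b, seq_len(n)] <- 1
    lengths[b] <- n
    if (!is.null(docs[[b]]$label)) {
      labels[b] <- match(docs[[b]]$label, label_set) - 1L
    }
  }
  structure(list(ids = ids, mask = mask, lengths = lengths, labels = labels),
            class = "padded_batch")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
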
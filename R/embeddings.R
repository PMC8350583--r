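#' Load word vectors in GloVe plain-text format
#'
#' Each line is a token followed by `d` space-separated floats. The
#' dimension is inferred from the first line unless `expect_dim` is given,
#' in which case any mismatch is an error. Duplicate tokens keep their first
#' occurrence (with a warning). Files ending in `.gz` are read through a
#' gzip connection.
#'
#' @param path file path (plain text or gzip).
#' @param expect_dim expected vector dimension, or `NULL` to infer.
#' @return object of class `embedding_table`: list with `dim` and `vectors`
#'   (numeric matrix, one row per token, rownames = tokens).
#' @export
load_vectors <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty vector file: ", path)
  parts <- strsplit(lines, "[ \t]+")
  d <- length(parts[[1]]) - 1L
  if (d < 1) stop("line 1 of ", path, " has no vector components")
  if (!is.null(expect_dim) && d != expect_dim) {
    stop("vector file has dimension ", d, " but expected ", expect_dim)
  }
  toks <- character(length(parts))
  mat <- matrix(NA_real_, length(parts), d)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != d + 1L) {
      stop("line ", i, " of ", path, " has ", length(p) - 1L,
           " vector components; expected ", d)
    }
    toks[i] <- p[1]
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric vector component at line ", i, " of ", path)
    mat[i, ] <- v
  }
  dup <- duplicated(toks)
  if (any(dup)) {
    warning(sum(dup), " duplicate token(s) in ", path,
            "; first occurrence kept")
    mat <- mat[!dup, , drop = FALSE]
    toks <- toks[!dup]
  }
  rownames(mat) <- toks
  structure(list(dim = d, vectors = mat), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("Embedding table:", nrow(x$vectors), "tokens, dim", x$dim, "\n")
  invisible(x)
}

#' Build the model's embedding matrix for a vocabulary
#'
#' Row layout follows vocabulary ids (row `id + 1`): the `PAD` row is all
#' zeros; rows for tokens found in `table` copy the pretrained vectors
#' bit-for-bit; every remaining row (including `OOV`) is sampled uniformly
#' from `(-oov_scale, +oov_scale)` under `seed`. With `table = NULL` all
#' non-PAD rows are random, so the package trains with no download.
#'
#' @param vocab a `trnn_vocab`.
#' @param table an `embedding_table`, or `NULL` for fully random init.
#' @param dim embedding dimension; must equal `table$dim` when a table is
#'   given.
#' @param oov_scale half-width of the uniform init for unmatched rows.
#' @param seed integer seed for the random rows.
#' @return numeric matrix `vocab$size x dim` with attribute `coverage`
#'   (matched fraction of real tokens) and `n_matched`.
#' @export
build_embedding_matrix <- function(vocab, table = NULL, dim = 200,
                                   oov_scale = 0.05, seed = 1) {
  if (!is.null(table) && table$dim != dim) {
    stop("embedding table dimension ", table$dim, " != requested dim ", dim)
  }
  V <- vocab$size
  E <- with_seed(seed, matrix(stats::runif(V * dim, -oov_scale, oov_scale),
                              V, dim))
  E[vocab$pad_id + 1L, ] <- 0
  n_matched <- 0L
  if (!is.null(table)) {
    hit <- match(vocab$tokens, rownames(table$vectors))
    found <- which(!is.na(hit))
    if (length(found) > 0) {
      E[found + 2L, ] <- table$vectors[hit[found], , drop = FALSE]
    }
    n_matched <- length(found)
  }
  attr(E, "n_matched") <- n_matched
  attr(E, "coverage") <- if (length(vocab$tokens) > 0) {
    n_matched / length(vocab$tokens)
  } else 0
  E
}
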
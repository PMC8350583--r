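#' Train and evaluate an architecture ablation
#'
#' Refits the model with one component removed — `no_max_pool` replaces the
#' temporal max-pooling by the final-position BiLSTM state, `no_bilstm`
#' feeds the concatenated representation directly into pooling,
#' `no_concat_embedding` drops the word embeddings from the concatenation —
#' under an otherwise identical configuration and seed, and evaluates on
#' the test corpus. `variant = "full"` is the unmodified pipeline.
#'
#' @param variant one of `"full"`, `"no_max_pool"`, `"no_bilstm"`,
#'   `"no_concat_embedding"`.
#' @param train,val,test labeled corpora.
#' @param config a [trnn_config()] (its ablation flags are overridden).
#' @param control a [trnn_control()].
#' @param embeddings optional `embedding_table`.
#' @return list with `variant`, `model` (the fitted `trnn`) and `metrics`
#'   (test-set `trnn_metrics`).
#' @export
run_ablation <- function(variant, train, val, test,
                         config = trnn_config(), control = trnn_control(),
                         embeddings = NULL) {
  variants <- c("full", "no_max_pool", "no_bilstm", "no_concat_embedding")
  if (!variant %in% variants) {
    stop("unknown variant '", variant, "'; expected one of: ",
         paste(variants, collapse = ", "))
  }
  cfg <- config
  cfg$no_max_pool <- variant == "no_max_pool"
  cfg$no_bilstm <- variant == "no_bilstm"
  cfg$no_concat_embedding <- variant == "no_concat_embedding"
  model <- trnn(train, val, config = cfg, control = control,
                embeddings = embeddings)
  list(variant = variant, model = model,
       metrics = evaluate(model, test))
}

#' Run the full ablation comparison
#'
#' Trains all four variants under identical seeds and reports their
#' weighted precision/recall/F1 side by side.
#'
#' @inheritParams run_ablation
#' @param variants which variants to run (default all four).
#' @return object of class `trnn_ablation`: data.frame with one row per
#'   variant (weighted P, R, F1), with the fitted runs in attribute
#'   `"runs"`.
#' @export
ablation_report <- function(train, val, test, config = trnn_config(),
                            control = trnn_control(), embeddings = NULL,
                            variants = c("full", "no_max_pool", "no_bilstm",
                                         "no_concat_embedding")) {
  runs <- lapply(variants, run_ablation, train = train, val = val,
                 test = test, config = config, control = control,
                 embeddings = embeddings)
  tab <- data.frame(
    variant = variants,
    precision = vapply(runs, function(r) unname(r$metrics$weighted["precision"]), 0),
    recall = vapply(runs, function(r) unname(r$metrics$weighted["recall"]), 0),
    f1 = vapply(runs, function(r) unname(r$metrics$weighted["f1"]), 0))
  attr(tab, "runs") <- runs
  class(tab) <- c("trnn_ablation", "data.frame")
  tab
}

#' @export
print.trnn_ablation <- function(x, digits = 3, ...) {
  cat("Ablation comparison (weighted averages)\n")
  cat(sprintf("  %-22s %9s %9s %9s\n", "variant", "P", "R", "F1"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s %9.*f %9.*f %9.*f\n", x$variant[i],
                digits, x$precision[i], digits, x$recall[i],
                digits, x$f1[i]))
  }
  invisible(x)
}
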
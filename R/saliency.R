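#' Per-generated-token saliency gradients (extension point)
#'
#' Backends that support gradient-based attribution implement this generic.
#' For the prompt of one extraction and its generation trace it must return,
#' for each generated token, the gradient of that token's probability score
#' with respect to each input-token embedding, together with the embeddings
#' themselves.
#'
#' @param adapter A differentiable model adapter.
#' @param input_text Preprocessed input text the prediction was made from.
#' @param attribute Schema attribute that was extracted.
#' @param trace The [generation_trace()] produced by [extract_attribute()]
#'   on the same inputs.
#' @return A list with `tokens` (character, the input tokens attribution is
#'   reported over), `norms` (matrix, input tokens x generated tokens, of L2
#'   norms of gradient-times-embedding) and `scores` (the token scores).
#' @export
saliency_grads <- function(adapter, input_text, attribute, trace) {
  UseMethod("saliency_grads")
}

#' @export
saliency_grads.default <- function(adapter, input_text, attribute, trace) {
  stop("adapter is not differentiable (capability error); ",
       "use a finite-difference oracle for black-box adapters", call. = FALSE)
}

#' @export
saliency_grads.gemi_tiny_lm <- function(adapter, input_text, attribute, trace) {
  prompt <- paste0("<BOS> ", input_text, " <SEP> ", attribute, ":")
  prompt_ids <- encode_tokens(adapter$tokenizer, prompt)
  gen_ids <- unname(adapter$tokenizer$index[trace$tokens])
  gen_ids[is.na(gen_ids)] <- adapter$tokenizer$unk_id
  ids <- c(prompt_ids, as.integer(gen_ids))
  n_prompt <- length(prompt_ids)
  input_tokens <- tokenize_words(adapter$tokenizer, input_text)
  # input tokens sit after <BOS> at positions 2..(1 + n_input)
  n_input <- length(input_tokens)
  if (length(gen_ids) == 0L) {
    return(list(tokens = input_tokens,
                norms = matrix(0, n_input, 0), scores = numeric(0)))
  }
  positions <- n_prompt + seq_along(gen_ids)
  res <- tf_input_saliency(adapter$params, ids, positions, n_prompt,
                           adapter$n_heads)
  norms <- res$norms[1L + seq_len(n_input), , drop = FALSE]
  list(tokens = input_tokens, norms = norms, scores = as.numeric(res$scores))
}

#' Input-times-gradient saliency map
#'
#' Attributes a predicted attribute value to the input tokens: for each
#' generated token, the gradient of that token's score with respect to every
#' input-token embedding is multiplied elementwise by the embedding and
#' reduced to a per-input-token L2 norm; norms are summed across the
#' generated tokens and normalized to sum 1. When every norm is zero (an
#' output constant in the input) the uniform map is returned.
#'
#' @inheritParams saliency_grads
#' @param n_bins Number of display-intensity bins (see [bin_scores()]).
#' @return An object of class `saliency_map`: `tokens`, normalized `scores`
#'   (nonnegative, summing to 1) and integer `bins` in `0:(n_bins - 1)`.
#' @export
input_x_grad <- function(adapter, input_text, attribute, trace, n_bins = 5L) {
  assert_attribute(attribute)
  g <- saliency_grads(adapter, input_text, attribute, trace)
  total <- if (ncol(g$norms)) rowSums(g$norms) else rep(0, length(g$tokens))
  s <- sum(total)
  scores <- if (s > 0) total / s else rep(1 / max(length(total), 1L), length(total))
  map <- structure(list(tokens = g$tokens, scores = as.numeric(scores),
                        bins = integer(length(scores))),
                   class = "saliency_map")
  bin_scores(map, n_bins)
}

#' Assign display-intensity bins to a saliency map
#'
#' Scores are partitioned into `n_bins` equal-width intervals of
#' `[0, max(score)]`; the bin index (0 = lightest shade, `n_bins - 1` =
#' darkest) indicates how strongly the model exploited each token.
#'
#' @param map A `saliency_map`.
#' @param n_bins Number of bins (at least 2).
#' @return The map with its `bins` field filled in.
#' @export
bin_scores <- function(map, n_bins = 5L) {
  stopifnot(inherits(map, "saliency_map"), n_bins >= 2L)
  mx <- max(map$scores, 0)
  if (mx <= 0) {
    map$bins <- rep(0L, length(map$scores))
  } else {
    b <- floor(map$scores / mx * n_bins)
    map$bins <- as.integer(pmin(b, n_bins - 1L))
  }
  map
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map>", length(x$tokens), "tokens\n")
  ord <- order(-x$scores)
  top <- utils::head(ord, 5L)
  for (i in top) {
    cat(sprintf("  %-25s %.4f (bin %d)\n", x$tokens[i], x$scores[i], x$bins[i]))
  }
  invisible(x)
}

#' Serialize a saliency map to JSON
#'
#' @param map A `saliency_map`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON text (invisibly when written to a file).
#' @export
saliency_to_json <- function(map, path = NULL) {
  obj <- lapply(seq_along(map$tokens), function(i) {
    list(token = map$tokens[i], score = map$scores[i], bin = map$bins[i])
  })
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
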
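# Central finite-difference oracle for input-times-gradient attributions:
# perturbs each input-token embedding coordinate through the forward pass
# only, independent of the analytic backward pass.

fd_saliency_norms <- function(adapter, input_text, attribute, trace,
                              eps = 1e-4) {
  tok <- adapter$tokenizer
  prompt <- paste0("<BOS> ", input_text, " <SEP> ", attribute, ":")
  prompt_ids <- encode_tokens(tok, prompt)
  gen_ids <- unname(tok$index[trace$tokens])
  ids <- c(prompt_ids, as.integer(gen_ids))
  positions <- length(prompt_ids) + seq_along(gen_ids)
  n_input <- length(tokenize_words(tok, input_text))
  d <- adapter$d_model
  emb <- adapter$params$E[ids, , drop = FALSE]
  norms <- matrix(0, n_input, length(positions))
  for (t in seq_len(n_input)) {
    row <- 1L + t  # input tokens follow <BOS>
    grad <- matrix(0, length(positions), d)
    for (j in seq_len(d)) {
      up <- emb; up[row, j] <- up[row, j] + eps
      dn <- emb; dn[row, j] <- dn[row, j] - eps
      sp <- geomex:::tf_token_scores(adapter$params, ids, positions,
                                     adapter$n_heads, up)
      sm <- geomex:::tf_token_scores(adapter$params, ids, positions,
                                     adapter$n_heads, dn)
      grad[, j] <- (sp - sm) / (2 * eps)
    }
    for (g in seq_along(positions)) {
      norms[t, g] <- sqrt(sum((grad[g, ] * emb[row, ])^2))
    }
  }
  norms
}

saliency_cosine <- function(a, b) {
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
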
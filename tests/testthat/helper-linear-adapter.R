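# A linear toy adapter with a closed-form attribution: its score for the
# single generated token is w . mean(input embeddings), so the gradient with
# respect to embedding e_i is w/n and input-times-gradient reduces to
# |w (*) e_i| / n per token.

linear_lm <- function(w, embeddings) {
  structure(list(w = w, embeddings = embeddings),
            class = c("linear_lm", "gemi_adapter"))
}

saliency_grads_linear_lm <- function(adapter, input_text, attribute, trace) {
  tokens <- strsplit(trimws(input_text), "\\s+")[[1]]
  n <- length(tokens)
  emb <- t(vapply(tokens, function(tk) adapter$embeddings[[tk]],
                  numeric(length(adapter$w))))
  grad <- matrix(rep(adapter$w / n, n), nrow = n, byrow = TRUE)
  norms <- matrix(sqrt(rowSums((grad * emb)^2)), ncol = 1)
  list(tokens = tokens, norms = norms,
       scores = sum(adapter$w * colMeans(emb)))
}

registerS3method("saliency_grads", "linear_lm", saliency_grads_linear_lm,
                 envir = asNamespace("geomex"))
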
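#' Training configuration
#'
#' Optimization settings for [fine_tune()]. Defaults suit fine-tuning a
#' large pretrained backbone: cross-entropy loss, Adam with learning rate `1e-4`,
#' early stopping with patience 2 and min-delta 0, and batch size 12; the
#' effective batch is `batch_size * replicas` (replicas model data-parallel
#' copies and default to 1). When training the small from-scratch backend a
#' larger learning rate (around `2e-3`) is appropriate; see the package
#' vignette.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Sequences per replica per optimizer step.
#' @param replicas Data-parallel replica count; multiplies the batch size.
#' @param patience Early stopping: number of consecutive non-improving
#'   validation epochs tolerated before halting.
#' @param min_delta Minimum improvement of validation loss that resets the
#'   patience counter.
#' @param max_epochs Hard cap on training epochs.
#' @param validation_fraction Fraction of the dataset held out (seeded) for
#'   the early-stopping validation loss. When the split would be empty, no
#'   early stopping is applied.
#' @param loss_mask `"target"` computes the cross-entropy only on the tokens
#'   after the task keyword (the target value and `<EOS>`); `"full"` scores
#'   the whole sequence.
#' @param seed Random seed for shuffling and the validation split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 12L, replicas = 1L,
                         patience = 2L, min_delta = 0, max_epochs = 10L,
                         validation_fraction = 0.1,
                         loss_mask = c("target", "full"), seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, replicas >= 1,
            patience >= 0, min_delta >= 0, max_epochs >= 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 replicas = as.integer(replicas),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 loss_mask = match.arg(loss_mask),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' A generation trace
#'
#' The generated token sequence (up to and excluding `<EOS>`) with the
#' conditional probability the model assigned to each chosen token, and the
#' probability of the terminating `<EOS>` when generation stopped there
#' (`NA` when generation was cut off by the token budget).
#'
#' @param tokens Character vector of generated tokens.
#' @param probs Numeric vector of per-token probabilities, same length.
#' @param eos_prob Probability of the terminating `<EOS>` token, or `NA`.
#' @return An object of class `generation_trace`.
#' @export
generation_trace <- function(tokens, probs, eos_prob = NA_real_) {
  stopifnot(length(tokens) == length(probs),
            all(probs >= 0 & probs <= 1))
  structure(list(tokens = as.character(tokens), probs = as.numeric(probs),
                 eos_prob = eos_prob),
            class = "generation_trace")
}

#' @export
print.generation_trace <- function(x, ...) {
  cat("<generation_trace>", if (length(x$tokens)) paste(x$tokens, collapse = " ")
      else "(empty)", "\n")
  if (length(x$probs)) cat("  probs:", paste(round(x$probs, 4), collapse = " "), "\n")
  invisible(x)
}

#' Capabilities of a model adapter
#'
#' @param adapter A model adapter.
#' @return A list with logical flags `generates`, `trainable`,
#'   `differentiable`.
#' @export
adapter_capabilities <- function(adapter) UseMethod("adapter_capabilities")

#' Greedy generation from a model adapter
#'
#' Decodes greedily (argmax at each step) from the prompt, stopping at
#' `<EOS>` or after `max_new_tokens` tokens. Greedy decoding makes the whole
#' annotation loop deterministic: identical adapter and prompt always yield
#' an identical trace.
#'
#' @param adapter A model adapter with the `generates` capability.
#' @param prompt Prompt text.
#' @param max_new_tokens Maximum number of generated tokens.
#' @return A [generation_trace()].
#' @export
generate <- function(adapter, prompt, max_new_tokens = 8L) UseMethod("generate")

#' Fine-tune a trainable model adapter
#'
#' Optimizes the cross-entropy of the formatted training strings (see
#' [format_training_string()]) with Adam, by default masking the loss to the
#' target-and-`<EOS>` span so optimization aligns with the extraction
#' objective. A seeded fraction of the dataset is held out and training halts
#' when its loss fails to improve by `min_delta` for more than `patience`
#' consecutive epochs, or at `max_epochs`.
#'
#' @param adapter A model adapter with the `trainable` capability.
#' @param dataset A list of [training_example()] objects or a character vector
#'   of formatted training strings.
#' @param config A [train_config()].
#' @return The updated adapter; `$history` holds per-epoch losses.
#' @export
fine_tune <- function(adapter, dataset, config = train_config()) UseMethod("fine_tune")

# ---- fixture adapter --------------------------------------------------------

#' Table-driven fixture adapter
#'
#' An exact, non-trainable adapter for tests and examples: a lookup table
#' maps a prompt (the initial prompt plus any already-generated tokens,
#' space-separated) to the next token and its probability. Prompts absent
#' from the table yield an immediate `<EOS>` with probability 1.
#'
#' @param table Named list; each element is `list(token = , prob = )`.
#' @return An adapter of class `gemi_fixture_lm`.
#' @examples
#' fx <- fixture_lm(list("p" = list(token = "hela", prob = 0.9)))
#' generate(fx, "p")
#' @export
fixture_lm <- function(table = list()) {
  structure(list(table = table), class = c("gemi_fixture_lm", "gemi_adapter"))
}

#' @export
adapter_capabilities.gemi_fixture_lm <- function(adapter) {
  list(generates = TRUE, trainable = FALSE, differentiable = FALSE)
}

#' @export
generate.gemi_fixture_lm <- function(adapter, prompt, max_new_tokens = 8L) {
  cur <- prompt
  tokens <- character(0)
  probs <- numeric(0)
  eos_prob <- NA_real_
  while (length(tokens) < max_new_tokens) {
    step <- adapter$table[[cur]]
    if (is.null(step)) {
      eos_prob <- 1
      break
    }
    if (identical(step$token, "<EOS>")) {
      eos_prob <- step$prob
      break
    }
    tokens <- c(tokens, step$token)
    probs <- c(probs, step$prob)
    cur <- paste(cur, step$token)
  }
  generation_trace(tokens, probs, eos_prob)
}

#' @export
fine_tune.gemi_fixture_lm <- function(adapter, dataset, config = train_config()) {
  stop("adapter is not trainable (capability error)", call. = FALSE)
}

#' @export
print.gemi_fixture_lm <- function(x, ...) {
  cat("<fixture adapter>", length(x$table), "table entries\n")
  invisible(x)
}

# ---- tiny trainable transformer --------------------------------------------

#' Small trainable decoder-only transformer
#'
#' A word-level autoregressive language model small enough to train on one
#' CPU: by default 2 decoder layers, 2 attention heads and embedding size 64,
#' with a feed-forward width of twice the embedding size. The same
#' configuration object can express much larger decoder stacks (e.g. 12
#' layers, 12 heads, embedding 768), but only the small setting is exercised
#' here. The tokenizer is built from the supplied corpus; `<BOS>`, `<SEP>`
#' and `<EOS>` are reserved tokens.
#'
#' @param corpus Character vector of texts the word vocabulary is built from
#'   (typically the formatted training strings), or a ready
#'   [word_tokenizer()].
#' @param d_model Embedding size.
#' @param n_layers Number of decoder layers.
#' @param n_heads Number of attention heads (must divide `d_model`).
#' @param d_ff Feed-forward hidden width.
#' @param max_len Maximum context length in tokens.
#' @param seed Seed for weight initialization.
#' @return An adapter of class `gemi_tiny_lm`.
#' @export
tiny_lm <- function(corpus, d_model = 64L, n_layers = 2L, n_heads = 2L,
                    d_ff = 2L * d_model, max_len = 448L, seed = 1L) {
  stopifnot(d_model %% n_heads == 0L)
  tok <- if (inherits(corpus, "word_tokenizer")) corpus else word_tokenizer(corpus)
  V <- length(tok$vocab)
  params <- with_seed(seed, init_params(V, as.integer(d_model), as.integer(n_layers),
                                        as.integer(d_ff), as.integer(max_len)))
  structure(list(tokenizer = tok, params = params,
                 n_heads = as.integer(n_heads), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 history = NULL),
            class = c("gemi_tiny_lm", "gemi_adapter"))
}

init_params <- function(V, d, n_layers, d_ff, max_len, sd = 0.02) {
  layer <- function() {
    list(ln1g = rep(1, d), ln1b = rep(0, d),
         Wq = matrix(stats::rnorm(d * d, 0, sd), d, d), bq = rep(0, d),
         Wk = matrix(stats::rnorm(d * d, 0, sd), d, d), bk = rep(0, d),
         Wv = matrix(stats::rnorm(d * d, 0, sd), d, d), bv = rep(0, d),
         Wo = matrix(stats::rnorm(d * d, 0, sd), d, d), bo = rep(0, d),
         ln2g = rep(1, d), ln2b = rep(0, d),
         W1 = matrix(stats::rnorm(d * d_ff, 0, sd), d, d_ff), b1 = rep(0, d_ff),
         W2 = matrix(stats::rnorm(d_ff * d, 0, sd), d_ff, d), b2 = rep(0, d))
  }
  list(E = matrix(stats::rnorm(V * d, 0, sd), V, d),
       P = matrix(stats::rnorm(max_len * d, 0, sd), max_len, d),
       layers = lapply(seq_len(n_layers), function(i) layer()),
       lnf_g = rep(1, d), lnf_b = rep(0, d),
       Wout = matrix(stats::rnorm(d * V, 0, sd), d, V), bout = rep(0, V))
}

#' @export
adapter_capabilities.gemi_tiny_lm <- function(adapter) {
  list(generates = TRUE, trainable = TRUE, differentiable = TRUE)
}

#' @export
print.gemi_tiny_lm <- function(x, ...) {
  cat("<tiny transformer LM> ", x$n_layers, " layers, ", x$n_heads, " heads, d=",
      x$d_model, ", vocab ", length(x$tokenizer$vocab), ", context ", x$max_len,
      "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", nrow(x$history), " epochs; final train loss ",
        round(utils::tail(x$history$train_loss, 1), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
generate.gemi_tiny_lm <- function(adapter, prompt, max_new_tokens = 8L) {
  ids <- encode_tokens(adapter$tokenizer, prompt)
  if (length(ids) == 0L) stop("empty prompt", call. = FALSE)
  if (length(ids) >= adapter$max_len) {
    stop("prompt exceeds model context length (", adapter$max_len, " tokens)",
         call. = FALSE)
  }
  res <- tf_generate(adapter$params, ids, as.integer(max_new_tokens),
                     adapter$tokenizer$eos_id, adapter$n_heads)
  generation_trace(adapter$tokenizer$vocab[res$ids], res$probs, res$eos_prob)
}

# encode one training example into (ids, cut) where cut is the 1-based index
# of the first loss-scored token
encode_example <- function(adapter, ex, loss_mask = "target") {
  tok <- adapter$tokenizer
  text <- format_training_string(ex)
  ids <- encode_tokens(tok, text)
  if (loss_mask == "full") {
    cut <- 2L
  } else {
    n_prefix <- 1L + length(tokenize_words(tok, ex$input)) + 1L +
      length(tokenize_words(tok, ex$task))
    cut <- n_prefix + 1L
  }
  list(ids = ids, cut = cut)
}

#' @export
fine_tune.gemi_tiny_lm <- function(adapter, dataset, config = train_config()) {
  if (is.character(dataset)) dataset <- lapply(dataset, parse_training_string)
  if (length(dataset) == 0L) stop("training dataset is empty", call. = FALSE)
  if (config$max_epochs == 0L) return(adapter)
  enc <- lapply(dataset, function(ex) encode_example(adapter, ex, config$loss_mask))
  too_long <- vapply(enc, function(e) length(e$ids) > adapter$max_len, TRUE)
  if (any(too_long)) {
    stop(sum(too_long), " training sequence(s) exceed the model context length",
         call. = FALSE)
  }
  n <- length(enc)
  eff_batch <- config$batch_size * config$replicas
  params <- adapter$params
  opt <- adam_init(params)
  es <- list(best = Inf, wait = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))

  with_seed(config$seed, {
    n_val <- floor(n * config$validation_fraction)
    idx <- sample.int(n)
    val_idx <- if (n_val >= 1L) idx[seq_len(n_val)] else integer(0)
    train_idx <- setdiff(idx, val_idx)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      total_loss <- 0
      total_tok <- 0
      for (start in seq(1L, length(ord), by = eff_batch)) {
        batch <- ord[start:min(start + eff_batch - 1L, length(ord))]
        res <- tf_batch(params,
                        lapply(enc[batch], `[[`, "ids"),
                        vapply(enc[batch], `[[`, 1L, "cut"),
                        adapter$n_heads, TRUE)
        total_loss <- total_loss + res$loss
        total_tok <- total_tok + res$n_tok
        if (res$n_tok > 0) {
          step <- adam_step(params, res$grads, opt, config$learning_rate,
                            scale = 1 / res$n_tok)
          params <- step$params
          opt <- step$state
        }
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        vres <- tf_batch(params, lapply(enc[val_idx], `[[`, "ids"),
                         vapply(enc[val_idx], `[[`, 1L, "cut"),
                         adapter$n_heads, FALSE)
        val_loss <- vres$loss / max(vres$n_tok, 1)
      }
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = total_loss / max(total_tok, 1),
                                     val_loss = val_loss))
      if (!is.na(val_loss)) {
        es <- early_stop_update(es, val_loss, config$patience, config$min_delta)
        if (es$stop) break
      }
    }
  })
  adapter$params <- params
  adapter$history <- hist
  adapter
}

# early-stopping state machine: stop once the count of consecutive epochs
# without an improvement > min_delta exceeds patience
early_stop_update <- function(state, val_loss, patience, min_delta) {
  if (val_loss < state$best - min_delta) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$stop <- state$wait > patience
  state
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, scale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- persistence ------------------------------------------------------------

#' Save or load an adapter
#'
#' The adapter is written to a directory as an RDS of the weights plus a YAML
#' manifest holding the configuration and vocabulary.
#'
#' @param adapter A `gemi_tiny_lm` adapter.
#' @param dir Target directory (created if missing).
#' @return `save_adapter` returns `dir` invisibly; `load_adapter` returns the
#'   adapter.
#' @export
save_adapter <- function(adapter, dir) {
  stopifnot(inherits(adapter, "gemi_tiny_lm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(class = "gemi_tiny_lm", d_model = adapter$d_model,
                   n_layers = adapter$n_layers, n_heads = adapter$n_heads,
                   d_ff = adapter$d_ff, max_len = adapter$max_len,
                   seed = adapter$seed, vocab = adapter$tokenizer$vocab)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  saveRDS(adapter$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_adapter
#' @export
load_adapter <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  tok <- word_tokenizer(character(0))
  tok$vocab <- as.character(manifest$vocab)
  tok$index <- stats::setNames(seq_along(tok$vocab), tok$vocab)
  adapter <- structure(
    list(tokenizer = tok, params = readRDS(file.path(dir, "weights.rds")),
         n_heads = manifest$n_heads, d_model = manifest$d_model,
         n_layers = manifest$n_layers, d_ff = manifest$d_ff,
         max_len = manifest$max_len, seed = manifest$seed, history = NULL),
    class = c("gemi_tiny_lm", "gemi_adapter"))
  adapter
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
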
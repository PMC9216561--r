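test_that("the fixture adapter reads generations off its table", {
  # immediate end-of-sequence: empty trace, the EOS probability is kept
  fx0 <- fixture_lm(list(p = list(token = "<EOS>", prob = 1)))
  tr0 <- generate(fx0, "p")
  expect_length(tr0$tokens, 0L)
  expect_length(tr0$probs, 0L)
  expect_identical(tr0$eos_prob, 1)

  fx <- fixture_lm(list(
    "p" = list(token = "hela", prob = 0.9),
    "p hela" = list(token = "-s3", prob = 0.99),
    "p hela -s3" = list(token = "<EOS>", prob = 1)))
  tr <- generate(fx, "p")
  expect_identical(tr$tokens, c("hela", "-s3"))
  expect_identical(tr$probs, c(0.9, 0.99))

  # a non-stopping chain is cut at the token budget
  chain <- list("p" = list(token = "a", prob = 0.5),
                "p a" = list(token = "a", prob = 0.5))
  # table misses "p a a": missing prompts default to EOS, so build the chain
  keys <- "p"
  steps <- list(list(token = "a", prob = 0.5))
  for (i in 1:12) {
    keys <- c(keys, paste(c("p", rep("a", i)), collapse = " "))
    steps <- c(steps, list(list(token = "a", prob = 0.5)))
  }
  fx_inf <- fixture_lm(stats::setNames(steps, keys[seq_along(steps)]))
  expect_length(generate(fx_inf, "p", max_new_tokens = 1L)$tokens, 1L)
  expect_length(generate(fx_inf, "p", max_new_tokens = 5L)$tokens, 5L)

  expect_error(fine_tune(fx, list()), "not trainable")
  caps <- adapter_capabilities(fx)
  expect_false(caps$trainable)
  expect_true(caps$generates)
})

test_that("next-token distributions are valid and decoding is deterministic", {
  ad <- tiny_lm("a b c d", d_model = 16L, n_layers = 2L, n_heads = 2L,
                d_ff = 32L, max_len = 16L, seed = 3L)
  for (prompt in list("a", "a b", "d c b")) {
    ids <- encode_tokens(ad$tokenizer, prompt)
    p <- geomex:::tf_next_probs(ad$params, ids, ad$n_heads)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  t1 <- generate(ad, "a b", max_new_tokens = 4L)
  t2 <- generate(ad, "a b", max_new_tokens = 4L)
  expect_identical(t1, t2)
})

test_that("early stopping halts after patience is exhausted on a plateau", {
  es <- list(best = Inf, wait = 0L)
  trace <- c(1.0, 0.8, 0.8, 0.8, 0.8)  # improvement, then a plateau
  stopped_at <- NA
  for (i in seq_along(trace)) {
    es <- geomex:::early_stop_update(es, trace[i], patience = 2L, min_delta = 0)
    if (es$stop) { stopped_at <- i; break }
  }
  # patience 2: training runs exactly patience + 1 non-improving epochs
  expect_identical(stopped_at, 5L)
  expect_identical(es$best, 0.8)

  # an improving sequence never stops
  es <- list(best = Inf, wait = 0L)
  for (v in seq(1, 0.1, by = -0.1)) {
    es <- geomex:::early_stop_update(es, v, 2L, 0)
  }
  expect_false(es$stop)

  # min_delta: improvements smaller than min_delta do not reset patience
  es <- list(best = Inf, wait = 0L)
  for (v in c(1.0, 0.999, 0.998, 0.997)) {
    es <- geomex:::early_stop_update(es, v, 2L, min_delta = 0.01)
    if (es$stop) break
  }
  expect_true(es$stop)
})

test_that("zero-epoch fine-tuning leaves the adapter unchanged", {
  ad <- tiny_lm("a b c", d_model = 16L, n_layers = 1L, n_heads = 2L,
                d_ff = 16L, max_len = 16L, seed = 4L)
  before <- generate(ad, "a", max_new_tokens = 3L)
  tuned <- fine_tune(ad, list(training_example("a", "b:", "c")),
                     train_config(max_epochs = 0L))
  expect_identical(generate(tuned, "a", max_new_tokens = 3L), before)
  expect_error(fine_tune(ad, list()), "empty")
})

test_that("a seeded tiny backend memorizes a small training set exactly", {
  examples <- list(
    training_example("cells from liver sample", "tissue:", "liver"),
    training_example("k562 profiled by chip", "cell line:", "k562"),
    training_example("mouse embryo tissue", "species:", "mus musculus"),
    training_example("donor is an adult man", "sex:", "male"),
    training_example("rna was sequenced", "technique:", "rna-seq"))
  texts <- vapply(examples, format_training_string, "")
  ad <- tiny_lm(texts, d_model = 32L, n_layers = 2L, n_heads = 2L,
                d_ff = 64L, max_len = 48L, seed = 11L)
  ad <- fine_tune(ad, examples,
                  train_config(learning_rate = 5e-3, max_epochs = 120L,
                               batch_size = 5L, validation_fraction = 0,
                               seed = 11L))
  for (ex in examples) {
    tr <- generate(ad, paste0("<BOS> ", ex$input, " <SEP> ", ex$task))
    expect_identical(paste(tr$tokens, collapse = " "), ex$target)
  }
})

test_that("fine-tuning is reproducible under a fixed seed", {
  examples <- corpus_to_examples(shared_corpus()[1:10])
  texts <- vapply(examples, format_training_string, "")
  run <- function() {
    ad <- tiny_lm(texts, d_model = 16L, n_layers = 1L, n_heads = 2L,
                  d_ff = 32L, max_len = 96L, seed = 21L)
    fine_tune(ad, examples,
              train_config(learning_rate = 2e-3, max_epochs = 2L, seed = 21L))
  }
  a <- run()
  b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("adapters survive a save/load round trip", {
  ad <- shared_adapter()
  dir <- tempfile("adapter")
  save_adapter(ad, dir)
  back <- load_adapter(dir)
  expect_identical(back$tokenizer$vocab, ad$tokenizer$vocab)
  prompt <- paste0("<BOS> ", preprocess(linearize(shared_corpus()[[1]]$record)),
                   " <SEP> tissue:")
  expect_identical(generate(back, prompt), generate(ad, prompt))
})

test_that("over-long prompts are rejected as context errors", {
  ad <- tiny_lm("a b c", d_model = 16L, n_layers = 1L, n_heads = 2L,
                d_ff = 16L, max_len = 8L, seed = 5L)
  long_prompt <- paste(rep("a", 20), collapse = " ")
  expect_error(generate(ad, long_prompt), "context length")
})
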
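# Shared fixtures: a small synthetic corpus and a briefly trained adapter,
# built once per test run.

.fixture_env <- new.env(parent = emptyenv())

shared_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- generate_corpus(generator_config(
      n_samples = 60, seed = 401, field_dropout_rate = 0.2, synonym_rate = 0.2))
  }
  .fixture_env$corpus
}

# adapter trained just enough to produce meaningful, deterministic outputs
shared_adapter <- function() {
  if (is.null(.fixture_env$adapter)) {
    examples <- corpus_to_examples(shared_corpus())
    texts <- vapply(examples, format_training_string, "")
    adapter <- tiny_lm(texts, seed = 402)
    .fixture_env$adapter <- fine_tune(
      adapter, examples,
      train_config(learning_rate = 2e-3, max_epochs = 3, seed = 402))
  }
  .fixture_env$adapter
}

# a random geo_sample for round-trip properties (names avoid the SOFT
# underscore escaping and the reserved characteristics slot)
random_record <- function() {
  rand_word <- function() {
    paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
  }
  rand_words <- function(n) paste(replicate(n, rand_word()), collapse = " ")
  n_fields <- sample(1:5, 1)
  fields <- stats::setNames(
    vapply(seq_len(n_fields), function(i) rand_words(sample(1:4, 1)), ""),
    make.unique(replicate(n_fields, rand_word())))
  n_ch <- sample(0:3, 1)
  ch <- if (n_ch > 0) {
    stats::setNames(vapply(seq_len(n_ch), function(i) rand_words(2), ""),
                    make.unique(replicate(n_ch, rand_word())))
  }
  geo_sample(paste0("GSM", sample(1e5, 1)), fields, characteristics = ch,
             series_id = if (stats::runif(1) < 0.5) paste0("GSE", sample(1e4, 1)))
}

# fixture table generating "hela-s3" then EOS for one specific prompt
hela_fixture <- function(prompt) {
  fixture_lm(stats::setNames(list(
    list(token = "hela-s3", prob = 0.9),
    list(token = "<EOS>", prob = 1)),
    c(prompt, paste(prompt, "hela-s3"))))
}

# an extraction_result whose predictions have the requested traffic lights,
# for queue-manipulation tests that do not need a model
make_result <- function(sample_id, n_low, n_red = 0) {
  attrs <- schema_attributes()
  lights <- rep("green", length(attrs))
  if (n_low > 0) lights[seq_len(n_low)] <- "yellow"
  if (n_red > 0) lights[seq_len(n_red)] <- "red"
  preds <- lapply(seq_along(attrs), function(i) {
    conf <- switch(lights[i], green = 0.95, yellow = 0.7, red = 0.3)
    structure(list(attribute = attrs[i], value = "x",
                   trace = generation_trace("x", conf),
                   confidence = conf, strategy = "first",
                   traffic_light = lights[i], approved = FALSE),
              class = "gemi_prediction")
  })
  names(preds) <- attrs
  structure(list(sample_id = sample_id, series_id = NULL,
                 input_text = "probe", predictions = preds),
            class = "extraction_result")
}
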
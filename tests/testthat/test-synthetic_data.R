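test_that("corpus generation is seeded, validated and sized", {
  expect_length(generate_corpus(generator_config(0)), 0L)
  expect_error(generator_config(-1), "nonnegative")
  expect_error(generator_config(10, field_dropout_rate = 1.5))

  a <- generate_corpus(generator_config(25, seed = 33))
  b <- generate_corpus(generator_config(25, seed = 33))
  expect_identical(a, b)
  c <- generate_corpus(generator_config(25, seed = 34))
  expect_false(identical(a, c))
  expect_length(a, 25L)
})

test_that("dropped attributes survive only through implicit cues", {
  # prostate tissue with everything droppable except the anchor: the donor
  # sex stays in the truth, implied male by the prostate mention
  vocab <- default_vocabulary()
  vocab$p_cell_line <- 0
  vocab$tissues <- "prostate"
  cfg <- generator_config(30, seed = 35, field_dropout_rate = 1,
                          synonym_rate = 0, vocab = vocab)
  for (s in generate_corpus(cfg)) {
    expect_identical(unname(s$truth[["sex"]]), "male")
    expect_identical(unname(s$basis[["sex"]]), "implicit")
    expect_false(grepl("sex:", linearize(s$record), fixed = TRUE))
  }

  # a K562 record with the tissue dropped keeps the haematopoietic and
  # lymphoid tissue of origin and the leukemia disease state via the cue
  vocab2 <- default_vocabulary()
  vocab2$p_cell_line <- 1
  vocab2$cell_lines <- vocab2$cell_lines[vocab2$cell_lines$name == "k562", ]
  cfg2 <- generator_config(20, seed = 36, field_dropout_rate = 1,
                           synonym_rate = 0, vocab = vocab2)
  for (s in generate_corpus(cfg2)) {
    expect_identical(unname(s$truth[["tissue"]]),
                     "haematopoietic and lymphoid tissue")
    expect_identical(unname(s$basis[["tissue"]]), "implicit")
    expect_identical(unname(s$truth[["disease"]]), "leukemia")
    expect_identical(unname(s$truth[["sex"]]), "female")
  }
})

test_that("without dropout or synonyms every truth value is verbatim", {
  cfg <- generator_config(50, seed = 37, field_dropout_rate = 0,
                          synonym_rate = 0)
  for (s in generate_corpus(cfg)) {
    text <- tolower(linearize(s$record))
    for (a in names(s$truth)[!is.na(s$truth)]) {
      expect_true(grepl(s$truth[[a]], text, fixed = TRUE),
                  info = paste(s$record$sample_id, a, s$truth[[a]]))
      expect_identical(unname(s$basis[[a]]), "explicit")
    }
  }
})

test_that("label marginals follow the configured sampling weights", {
  cfg <- generator_config(5000, seed = 38, field_dropout_rate = 0,
                          synonym_rate = 0)
  corpus <- generate_corpus(cfg)
  tech <- vapply(corpus, function(s) unname(s$truth[["technique"]]), "")
  n <- length(tech)
  w <- cfg$vocab$technique_weights
  for (i in seq_along(cfg$vocab$techniques)) {
    observed <- sum(tech == cfg$vocab$techniques[i])
    expected <- n * w[i]
    sigma <- sqrt(n * w[i] * (1 - w[i]))
    expect_lt(abs(observed - expected), 3 * sigma)
  }
  is_cl <- vapply(corpus, function(s) !is.na(s$truth[["cell line"]]), TRUE)
  p <- cfg$vocab$p_cell_line
  expect_lt(abs(sum(is_cl) - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("synonym swaps keep the canonical truth out of the text", {
  cfg <- generator_config(400, seed = 39, field_dropout_rate = 0,
                          synonym_rate = 1)
  corpus <- generate_corpus(cfg)
  human <- Filter(function(s) identical(unname(s$truth[["species"]]),
                                        "homo sapiens"), corpus)
  expect_gt(length(human), 0L)
  for (s in human[1:5]) {
    text <- tolower(linearize(s$record))
    expect_true(grepl("[organism]: human", text, fixed = TRUE))
    expect_identical(unname(s$basis[["species"]]), "explicit")
  }
})

test_that("corpus splits are seeded, disjoint and exhaustive", {
  corpus <- generate_corpus(generator_config(100, seed = 40))
  sp <- split_corpus(corpus, 0.8, seed = 41)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  ids <- function(x) vapply(x, function(s) s$record$sample_id, "")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(corpus))
  expect_identical(split_corpus(corpus, 0.8, seed = 41), sp)
  expect_error(split_corpus(corpus, 1), "between")
})

test_that("labeled corpora round-trip through JSON-lines", {
  corpus <- shared_corpus()[1:6]
  path <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus_jsonl(path)
  expect_length(back, 6L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$truth, corpus[[i]]$truth)
    expect_identical(back[[i]]$record$fields, corpus[[i]]$record$fields)
    expect_identical(back[[i]]$record$characteristics,
                     corpus[[i]]$record$characteristics)
  }
})

test_that("training examples mirror the non-null truth attributes", {
  corpus <- shared_corpus()
  examples <- corpus_to_examples(corpus)
  expect_identical(length(examples),
                   sum(vapply(corpus, function(s) sum(!is.na(s$truth)), 0L)))
  expect_true(all(vapply(examples, function(e)
    sub(":$", "", e$task) %in% schema_attributes(), TRUE)))
  # inputs are preprocessed: lowercase, within the token budget
  inputs <- unique(vapply(examples, `[[`, "", "input"))
  expect_identical(inputs, tolower(inputs))
  expect_true(all(vapply(inputs, token_count, 1L) <= 400L))
})
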
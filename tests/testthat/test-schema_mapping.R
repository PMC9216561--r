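test_that("the unified schema has 15 uniquely named attributes", {
  schema <- attribute_schema()
  expect_identical(nrow(schema), 15L)
  expect_false(anyDuplicated(schema$name) > 0)
  expect_setequal(schema$name, schema_attributes())
})

test_that("Cistrome records map onto cell line, cell type, tissue and target", {
  rec <- source_record("cistrome", c("Cell Line" = "k562",
                                     "Cell Type" = "erythroblast",
                                     "Tissue Type" = "blood",
                                     "Factor Name" = "ctcf"))
  mapped <- map_cistrome(rec)
  expect_identical(unname(mapped["cell line"]), "k562")
  expect_identical(unname(mapped["cell type"]), "erythroblast")
  expect_identical(unname(mapped["tissue"]), "blood")
  expect_identical(unname(mapped["target"]), "ctcf")
  expect_true(all(is.na(mapped[setdiff(schema_attributes(),
                                       c("cell line", "cell type",
                                         "tissue", "target"))])))

  expect_true(all(is.na(map_cistrome(source_record("cistrome")))))

  # per-attribute independence: a missing source column only nulls its target
  partial <- map_cistrome(source_record("cistrome",
                                        c("Cell Line" = "k562",
                                          "Factor Name" = "ctcf")))
  expect_true(is.na(partial["tissue"]))
  expect_identical(unname(partial["cell line"]), "k562")

  expect_error(map_cistrome(source_record("encode")), "schema error")
})

test_that("ENCODE classification routes the biosample term", {
  cl <- map_encode(source_record("encode",
                                 c(Classification = "cell line",
                                   "Biosample term name" = "HeLa-S3")))
  expect_identical(unname(cl["cell line"]), "HeLa-S3")
  expect_true(is.na(cl["tissue"]))
  expect_true(is.na(cl["cell type"]))
  expect_identical(unname(cl["classification"]), "cell line")
  expect_true(all(is.na(cl[setdiff(schema_attributes(),
                                   c("cell line", "classification"))])))

  ti <- map_encode(source_record("encode",
                                 c(Classification = "tissue",
                                   "Biosample term name" = "liver",
                                   Sex = "male",
                                   "Health status" = "healthy")))
  expect_identical(unname(ti["tissue"]), "liver")
  expect_true(is.na(ti["cell line"]))
  expect_true(is.na(ti["cell type"]))
  expect_identical(unname(ti["sex"]), "male")
  expect_identical(unname(ti["disease"]), "healthy")

  expect_true(all(is.na(map_encode(source_record("encode")))))

  expect_warning(
    odd <- map_encode(source_record("encode",
                                    c(Classification = "organoid",
                                      "Biosample term name" = "gut"))),
    "unknown Classification")
  expect_true(is.na(odd["cell line"]) && is.na(odd["tissue"]))
})

test_that("mapping never populates attributes outside the source's columns", {
  # cistrome can only ever reach these four unified attributes
  set.seed(81)
  cistrome_reach <- c("cell line", "cell type", "tissue", "target")
  for (i in 1:20) {
    cols <- sample(source_attribute_names("cistrome"), sample(1:4, 1))
    rec <- source_record("cistrome",
                         stats::setNames(rep("v", length(cols)), cols))
    mapped <- map_cistrome(rec)
    expect_true(all(is.na(mapped[setdiff(schema_attributes(), cistrome_reach)])))
  }
})

test_that("fallback text concatenates the three ENCODE text attributes", {
  rec <- source_record("encode",
                       c(Description = "d", "Biosample summary" = "b",
                         "replicates.library.biosample.description" = "r"))
  fb <- build_fallback_text(rec)
  expect_identical(unname(fb$fields["characteristics"]), "d b r")
  expect_identical(linearize(fb), "[characteristics]: d b r [description]: d b r")

  empty <- build_fallback_text(source_record("encode"))
  expect_identical(unname(empty$fields["description"]), "")

  only_b <- build_fallback_text(source_record("encode",
                                              c("Biosample summary" = "b")))
  expect_identical(unname(only_b$fields["description"]), "b")
})

test_that("samples split into one example per non-null attribute", {
  cist <- map_cistrome(source_record("cistrome",
                                     c("Cell Line" = "K562",
                                       "Cell Type" = "Erythroblast",
                                       "Tissue Type" = "Blood",
                                       "Factor Name" = "CTCF")))
  ex <- split_into_training_examples(cist, "some input")
  expect_length(ex, 4L)
  expect_true(all(vapply(ex, function(e) identical(e$input, "some input"), TRUE)))
  expect_setequal(vapply(ex, `[[`, "", "task"),
                  c("cell line:", "cell type:", "tissue:", "target:"))
  expect_identical(ex[[1]]$target, tolower(ex[[1]]$target))

  expect_length(split_into_training_examples(empty_unified_record(), "x"), 0L)

  enc <- empty_unified_record()
  enc[c("cell line", "technique", "technique type", "target", "species",
        "sex", "disease", "classification", "feature")] <- "v"
  ex9 <- split_into_training_examples(enc, "shared")
  expect_length(ex9, 9L)
  expect_identical(unique(vapply(ex9, `[[`, "", "input")), "shared")
})

test_that("training strings carry the special keywords and invert cleanly", {
  ex <- training_example("s", "cell line:", "hela-s3")
  expect_identical(format_training_string(ex),
                   "<BOS> s <SEP> cell line: hela-s3 <EOS>")
  expect_identical(
    format_training_string(training_example("", "cell line:", "hela-s3")),
    "<BOS>  <SEP> cell line: hela-s3 <EOS>")

  set.seed(82)
  attrs <- schema_attributes()
  for (i in 1:100) {
    words <- function(n) paste(sample(letters, n, replace = TRUE), collapse = "")
    ex <- training_example(
      paste(replicate(sample(1:12, 1), words(4)), collapse = " "),
      paste0(sample(attrs, 1), ":"),
      paste(replicate(sample(1:4, 1), words(5)), collapse = " "))
    back <- parse_training_string(format_training_string(ex))
    expect_identical(back$task, ex$task)
    expect_identical(back$target, ex$target)
    expect_identical(back$input, ex$input)
  }
})

test_that("merged datasets concatenate sources and their task unions", {
  cist <- split_into_training_examples(
    map_cistrome(source_record("cistrome",
                               c("Cell Line" = "k562", "Cell Type" = "e",
                                 "Tissue Type" = "b", "Factor Name" = "ctcf"))),
    "i1")
  enc_rec <- empty_unified_record()
  enc_rec[c("cell line", "technique", "technique type", "target", "species",
            "sex", "disease", "classification", "feature")] <- "v"
  enc <- split_into_training_examples(enc_rec, "i2")
  merged <- merge_datasets(cist, enc)
  expect_length(merged, 13L)
  tasks <- unique(vapply(merged, `[[`, "", "task"))
  expect_setequal(tasks, union(vapply(cist, `[[`, "", "task"),
                               vapply(enc, `[[`, "", "task")))
  expect_true(all(sub(":$", "", tasks) %in% schema_attributes()))
  expect_length(merge_datasets(list(), list()), 0L)
})

test_that("source tables and JSONL example files round-trip", {
  tab <- data.frame("Cell Line" = c("k562", "hepg2"),
                    "Cell Type" = c("erythroblast", NA),
                    "Tissue Type" = c("blood", "liver"),
                    "Factor Name" = c("ctcf", "polr2a"),
                    gsm = c("GSM1", "GSM2"), check.names = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  rows <- read_source_table(path, "cistrome")
  expect_length(rows, 2L)
  expect_identical(rows[[1]]$gsm, "GSM1")
  expect_identical(unname(map_cistrome(rows[[2]])["target"]), "polr2a")
  expect_true(is.na(map_cistrome(rows[[2]])["cell type"]))

  ex <- list(training_example("a b", "sex:", "male"),
             training_example("c", "tissue:", "liver"))
  jl <- tempfile(fileext = ".jsonl")
  write_examples_jsonl(ex, jl)
  back <- read_examples_jsonl(jl)
  expect_identical(lapply(back, unclass), lapply(ex, unclass))
})
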
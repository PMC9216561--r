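test_that("identifiers resolve to samples and duplicates load once", {
  corpus <- shared_corpus()[1:8]
  records <- lapply(corpus, `[[`, "record")
  resolver <- sample_resolver(records)
  gsms <- vapply(records, `[[`, "", "sample_id")
  gse <- records[[1]]$series_id
  members <- sum(vapply(records, function(r) identical(r$series_id, gse), TRUE))

  session <- annotation_session(shared_adapter())
  session <- load_samples(session, gsms[1:3], resolver)
  expect_length(session$queue, 3L)

  session2 <- annotation_session(shared_adapter())
  session2 <- load_samples(session2, gse, resolver)
  expect_length(session2$queue, members)

  # duplicates within the request and against the loaded queue are ignored
  session2 <- load_samples(session2, c(gsms[1], gsms[1]), resolver)
  qids <- vapply(session2$queue, `[[`, "", "sample_id")
  expect_false(anyDuplicated(qids) > 0)

  expect_warning(load_samples(session, "GSM_does_not_exist", resolver),
                 "not resolved")
})

test_that("the queue sorts by low-confidence count, stably", {
  session <- annotation_session(fixture_lm())
  session$queue <- list(make_result("s1", 2), make_result("s2", 0),
                        make_result("s3", 5))
  sorted <- sort_queue(session)
  expect_identical(vapply(sorted$queue, `[[`, "", "sample_id"),
                   c("s3", "s1", "s2"))

  # all green: order unchanged
  session$queue <- list(make_result("a", 0), make_result("b", 0))
  expect_identical(vapply(sort_queue(session)$queue, `[[`, "", "sample_id"),
                   c("a", "b"))

  # ties preserve prior relative order
  session$queue <- list(make_result("t1", 3), make_result("t2", 3),
                        make_result("t3", 4))
  expect_identical(vapply(sort_queue(session)$queue, `[[`, "", "sample_id"),
                   c("t3", "t1", "t2"))

  # sorting is a permutation of the queue
  session$queue <- lapply(1:6, function(i) make_result(paste0("p", i),
                                                       sample(0:5, 1)))
  expect_setequal(vapply(sort_queue(session)$queue, `[[`, "", "sample_id"),
                  paste0("p", 1:6))
})

test_that("edits confirm, blank or replace a field and approve it", {
  session <- annotation_session(fixture_lm())
  session$queue <- list(make_result("s1", 3))

  session <- apply_edit(session, "s1", user_edit("cell line", "confirm"))
  p <- session$queue[[1]]$predictions[["cell line"]]
  expect_identical(p$value, "x")
  expect_true(p$approved)

  session <- apply_edit(session, "s1", user_edit("cell type", "set-unknown"))
  expect_identical(session$queue[[1]]$predictions[["cell type"]]$value,
                   "unknown")

  session <- apply_edit(
    session, "s1",
    user_edit("tissue", "new-value", "haematopoietic and lymphoid tissue"))
  expect_identical(session$queue[[1]]$predictions[["tissue"]]$value,
                   "haematopoietic and lymphoid tissue")

  expect_error(user_edit("tissue", "new-value"), "non-empty")
  expect_error(apply_edit(session, "nope", user_edit("sex", "confirm")),
               "not in the queue")
})

test_that("queue plus annotated store is conserved under sort and edit", {
  session <- annotation_session(fixture_lm())
  session$queue <- lapply(1:5, function(i) make_result(paste0("s", i),
                                                       i %% 3))
  n0 <- length(session$queue) + length(session$annotated_store)
  session <- sort_queue(session)
  expect_identical(length(session$queue) + length(session$annotated_store), n0)
  session <- apply_edit(session, "s2", user_edit("sex", "confirm"))
  expect_identical(length(session$queue) + length(session$annotated_store), n0)
})

test_that("finalize requires approval, augments the store and retrains", {
  corpus <- shared_corpus()[1:3]
  examples <- corpus_to_examples(corpus)
  session <- annotation_session(
    shared_adapter(), base_dataset = examples,
    train_cfg = train_config(learning_rate = 2e-3, max_epochs = 1L, seed = 7L))
  records <- lapply(corpus, `[[`, "record")
  session <- load_samples(session,
                          vapply(records, `[[`, "", "sample_id"),
                          sample_resolver(records))
  sid <- session$queue[[1]]$sample_id

  expect_error(finalize_sample(session, sid), "unapproved")

  for (a in schema_attributes()) {
    session <- apply_edit(session, sid, user_edit(a, "confirm"))
  }
  pos <- match(sid, vapply(session$queue, `[[`, "", "sample_id"))
  n_known <- sum(vapply(session$queue[[pos]]$predictions,
                        function(p) !identical(p$value, "unknown"), TRUE))
  n_before <- length(session$queue)
  session <- finalize_sample(session, sid)

  expect_length(session$annotated_store, 1L)
  expect_length(session$queue, n_before - 1L)
  expect_length(session$augmentation_store, n_known)
  expect_false(is.null(session$adapter$history))  # retraining happened
  expect_error(apply_edit(session, sid, user_edit("sex", "confirm")),
               "already finalized")
})

test_that("the stop condition fires on empty or fully confident queues", {
  session <- annotation_session(fixture_lm())
  expect_true(stop_condition(session))
  session$queue <- list(make_result("a", 0), make_result("b", 0))
  expect_true(stop_condition(session))
  session$queue[[2]] <- make_result("b", 1)  # one yellow field anywhere
  expect_false(stop_condition(session))
})

test_that("sessions export the annotated table plus the queue snapshot", {
  empty <- annotation_session(fixture_lm())
  csv <- tempfile(fileext = ".csv")
  export_session(empty, csv, "csv")
  df <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(nrow(df), 0L)
  expect_identical(names(df), c("gsm", "gse", schema_attributes()))

  session <- annotation_session(fixture_lm())
  session$annotated_store <- list(make_result("s9", 0))
  export_session(session, csv, "csv")
  df2 <- utils::read.csv(csv, check.names = FALSE, colClasses = "character")
  expect_identical(nrow(df2), 1L)
  expect_identical(df2$gsm, "s9")
  expect_identical(df2$`cell line`, "x")

  js <- tempfile(fileext = ".json")
  export_session(session, js, "json")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, 1L)
  expect_identical(parsed[[1]]$sample_id, "s9")
  expect_identical(parsed[[1]]$predictions[["sex"]]$value, "x")
})

test_that("session checkpoints restore the queue, stores and adapter", {
  corpus <- shared_corpus()[1:2]
  records <- lapply(corpus, `[[`, "record")
  session <- annotation_session(shared_adapter())
  session <- load_samples(session, vapply(records, `[[`, "", "sample_id"),
                          sample_resolver(records))
  dir <- tempfile("session")
  save_session(session, dir)
  back <- load_session(dir)
  expect_s3_class(back, "annotation_session")
  expect_length(back$queue, 2L)
  expect_identical(back$queue[[1]]$predictions[["tissue"]]$value,
                   session$queue[[1]]$predictions[["tissue"]]$value)
  expect_identical(back$adapter$tokenizer$vocab,
                   session$adapter$tokenizer$vocab)
})
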
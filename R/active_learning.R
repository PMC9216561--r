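#' Create an annotation session
#'
#' The session drives the four-phase annotation loop: load samples and
#' extract their attribute tables; sort the queue so the sample with the most
#' low-confidence fields comes first; let the user confirm, blank or correct
#' each field; and on finalization retrain the model online with the
#' corrected examples added to an augmentation store, regenerate the
#' remaining queue and re-sort.
#'
#' @param adapter A generating model adapter (trainable for online learning).
#' @param base_dataset List of [training_example()] objects the model was
#'   trained on; retraining uses the union of this dataset and the
#'   augmentation store, which counters forgetting.
#' @param th [thresholds()] for the traffic-light classes.
#' @param train_cfg [train_config()] used for each online retraining round.
#' @param strategy Confidence strategy (see [confidence()]).
#' @param include_unknown Include fields approved as `"unknown"` as literal
#'   training targets (default `FALSE`: they are excluded from augmentation).
#' @param augmentation_weight How many times the augmentation store is
#'   replayed per retraining pass (default 8). Corrections are few compared
#'   to the base dataset; replaying them with higher weight lets the model
#'   absorb a correction within a couple of finalizes while the online
#'   updates themselves stay small.
#' @param preprocess_cfg [preprocess_config()] applied to loaded records.
#' @return An object of class `annotation_session`.
#' @export
annotation_session <- function(adapter, base_dataset = list(),
                               th = thresholds(), train_cfg = train_config(),
                               strategy = "first", include_unknown = FALSE,
                               augmentation_weight = 8L,
                               preprocess_cfg = preprocess_config()) {
  stopifnot(augmentation_weight >= 1L)
  structure(list(adapter = adapter, base_dataset = base_dataset,
                 thresholds = th, train_config = train_cfg,
                 strategy = strategy, include_unknown = include_unknown,
                 augmentation_weight = as.integer(augmentation_weight),
                 preprocess_cfg = preprocess_cfg,
                 queue = list(), annotated_store = list(),
                 augmentation_store = list(), records = list()),
            class = "annotation_session")
}

#' @export
print.annotation_session <- function(x, ...) {
  cat("<annotation_session> queue ", length(x$queue), ", annotated ",
      length(x$annotated_store), ", augmentation store ",
      length(x$augmentation_store), " examples\n", sep = "")
  invisible(x)
}

#' Build a resolver over an in-memory sample store
#'
#' Maps a GSM identifier to its record and a GSE identifier to the records
#' of its member samples.
#'
#' @param records List of [geo_sample()] objects.
#' @return A function `f(id)` returning a list of records (empty when the
#'   identifier is unknown).
#' @export
sample_resolver <- function(records) {
  by_gsm <- stats::setNames(records,
                            vapply(records, `[[`, "", "sample_id"))
  series <- vapply(records, function(r) {
    if (is.null(r$series_id)) "" else r$series_id
  }, "")
  function(id) {
    if (id %in% names(by_gsm)) return(by_gsm[id])
    hit <- which(series == id & nzchar(id))
    unname(by_gsm[hit])
  }
}

#' Load samples into the annotation queue
#'
#' Resolves each GSM/GSE identifier to sample records, extracts their
#' attribute tables and appends them to the queue. Duplicate GSMs (within
#' the id list or against samples already in the session) are loaded once.
#' Unresolvable identifiers are reported as warnings and the remaining ids
#' are still processed.
#'
#' @param session An [annotation_session()].
#' @param ids Character vector of GSM/GSE identifiers.
#' @param resolver A function mapping one identifier to a list of
#'   [geo_sample()] records, e.g. [sample_resolver()].
#' @return The updated session.
#' @export
load_samples <- function(session, ids, resolver) {
  stopifnot(inherits(session, "annotation_session"))
  seen <- c(names(session$records))
  for (id in ids) {
    records <- resolver(id)
    if (!length(records)) {
      warning("identifier not resolved: ", id, call. = FALSE)
      next
    }
    for (rec in records) {
      if (rec$sample_id %in% seen) next
      seen <- c(seen, rec$sample_id)
      session$records[[rec$sample_id]] <- rec
      session$queue[[length(session$queue) + 1L]] <-
        extract_all(session$adapter, rec, strategy = session$strategy,
                    th = session$thresholds, config = session$preprocess_cfg)
    }
  }
  session
}

#' Sort the annotation queue by annotation need
#'
#' Samples are ordered by descending count of low-confidence (non-green)
#' fields, so the sample that needs user editing the most is shown first.
#' Ties keep their prior relative order (stable sort).
#'
#' @param session An [annotation_session()].
#' @return The session with its queue reordered.
#' @export
sort_queue <- function(session) {
  counts <- vapply(session$queue, low_confidence_count, 1L)
  session$queue <- session$queue[order(-counts, seq_along(counts))]
  session
}

#' Describe one user edit
#'
#' @param attribute Schema attribute being edited.
#' @param action `"confirm"` (keep the predicted value), `"set-unknown"`
#'   (the information is not retrievable for this sample) or `"new-value"`
#'   (insert a corrected value).
#' @param value Replacement text, required for `"new-value"`.
#' @return An object of class `user_edit`.
#' @export
user_edit <- function(attribute, action = c("confirm", "set-unknown", "new-value"),
                      value = NULL) {
  assert_attribute(attribute)
  action <- match.arg(action)
  if (action == "new-value" && (is.null(value) || !nzchar(value))) {
    stop("new-value edits require non-empty text", call. = FALSE)
  }
  structure(list(attribute = attribute, action = action, value = value),
            class = "user_edit")
}

find_in_queue <- function(session, sample_id) {
  ids <- vapply(session$queue, `[[`, "", "sample_id")
  pos <- match(sample_id, ids)
  if (is.na(pos)) {
    done <- vapply(session$annotated_store, `[[`, "", "sample_id")
    if (sample_id %in% done) {
      stop("sample ", sample_id, " is already finalized (state error)",
           call. = FALSE)
    }
    stop("sample ", sample_id, " is not in the queue", call. = FALSE)
  }
  pos
}

#' Apply a user edit to a queued sample
#'
#' Confirm keeps the predicted value, set-unknown replaces it with
#' `"unknown"` and new-value replaces it with the supplied text; in every
#' case the field is marked user-approved.
#'
#' @param session An [annotation_session()].
#' @param sample_id GSM identifier of a queued sample.
#' @param edit A [user_edit()].
#' @return The updated session.
#' @export
apply_edit <- function(session, sample_id, edit) {
  stopifnot(inherits(edit, "user_edit"))
  pos <- find_in_queue(session, sample_id)
  pred <- session$queue[[pos]]$predictions[[edit$attribute]]
  if (edit$action == "set-unknown") {
    pred$value <- "unknown"
  } else if (edit$action == "new-value") {
    pred$value <- edit$value
  }
  pred$approved <- TRUE
  session$queue[[pos]]$predictions[[edit$attribute]] <- pred
  session
}

#' Finalize a fully approved sample and retrain online
#'
#' Requires every attribute of the sample to be user-approved. The sample's
#' approved values (excluding `"unknown"` unless the session says otherwise)
#' become training examples appended to the augmentation store; the adapter
#' is fine-tuned on the base dataset plus the store (replayed
#' `augmentation_weight` times); the sample moves to the
#' annotated store; and the remaining queue is re-extracted with the updated
#' model and re-sorted.
#'
#' @param session An [annotation_session()].
#' @param sample_id GSM identifier of a queued, fully approved sample.
#' @return The updated session.
#' @export
finalize_sample <- function(session, sample_id) {
  pos <- find_in_queue(session, sample_id)
  result <- session$queue[[pos]]
  unapproved <- names(Filter(function(p) !p$approved, result$predictions))
  if (length(unapproved)) {
    stop("sample ", sample_id, " has unapproved fields: ",
         paste(unapproved, collapse = ", "), call. = FALSE)
  }
  for (p in result$predictions) {
    if (!session$include_unknown && identical(p$value, "unknown")) next
    if (!nzchar(p$value)) next
    session$augmentation_store[[length(session$augmentation_store) + 1L]] <-
      training_example(result$input_text, paste0(p$attribute, ":"),
                       tolower(p$value))
  }
  train_set <- c(session$base_dataset,
                 rep(session$augmentation_store, session$augmentation_weight))
  session$adapter <- fine_tune(session$adapter, train_set, session$train_config)
  session$annotated_store[[length(session$annotated_store) + 1L]] <- result
  session$queue <- session$queue[-pos]
  # the table is generated again for the samples still awaiting review
  session$queue <- lapply(session$queue, function(r) {
    extract_all(session$adapter, session$records[[r$sample_id]],
                strategy = session$strategy, th = session$thresholds,
                config = session$preprocess_cfg)
  })
  sort_queue(session)
}

#' Has the annotation loop finished?
#'
#' True when the queue is empty or every prediction of every queued sample
#' is highly confident (green).
#'
#' @param session An [annotation_session()].
#' @return Logical flag.
#' @export
stop_condition <- function(session) {
  if (!length(session$queue)) return(TRUE)
  all(vapply(session$queue, function(r) low_confidence_count(r) == 0L, TRUE))
}

#' Export the session table
#'
#' Writes the annotated store followed by a snapshot of the current queue,
#' as CSV (one row per sample: gsm, gse and the 15 attribute columns in
#' schema order) or as JSON mirroring the nested extraction results.
#'
#' @param session An [annotation_session()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @param confidence For CSV, include per-attribute confidence columns.
#' @return `path`, invisibly.
#' @export
export_session <- function(session, path, format = c("csv", "json"),
                           confidence = FALSE) {
  write_results(c(session$annotated_store, session$queue), path,
                format = match.arg(format), confidence = confidence)
}

#' Save or load a session checkpoint
#'
#' The adapter is saved via [save_adapter()]; queue, stores and records are
#' written alongside so an annotation session can be resumed (the annotated
#' store doubles as the listing of previously approved samples).
#'
#' @param session An [annotation_session()].
#' @param dir Checkpoint directory.
#' @return `save_session` returns `dir` invisibly; `load_session` the
#'   restored session.
#' @export
save_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(session$adapter, "gemi_tiny_lm")) {
    save_adapter(session$adapter, file.path(dir, "adapter"))
  }
  rest <- session
  rest$adapter <- NULL
  saveRDS(rest, file.path(dir, "session.rds"))
  invisible(dir)
}

#' @rdname save_session
#' @export
load_session <- function(dir) {
  session <- readRDS(file.path(dir, "session.rds"))
  adapter_dir <- file.path(dir, "adapter")
  if (dir.exists(adapter_dir)) {
    session$adapter <- load_adapter(adapter_dir)
  }
  class(session) <- "annotation_session"
  session
}

#' Replay the annotation loop with an oracle user
#'
#' Simulates a domain expert who always corrects predictions to the ground
#' truth: at each step the queue is sorted, the neediest sample's fields are
#' confirmed (when correct), blanked (when the truth is null) or corrected
#' (when wrong), and the sample is finalized, triggering online retraining.
#' Used for evaluating how quickly user feedback removes low-confidence
#' fields from the queue.
#'
#' @param session An [annotation_session()] with a populated queue.
#' @param truths Named list: sample id to ground-truth attribute vector (as
#'   in a labeled sample's `truth`).
#' @param max_steps Maximum number of finalize iterations.
#' @return List with the final `session` and a `history` data frame with one
#'   row per iteration: queued samples, total red fields and total non-green
#'   fields in the queue before the iteration's finalize.
#' @export
simulate_annotation <- function(session, truths, max_steps = 10L) {
  history <- data.frame(step = integer(0), queue_size = integer(0),
                        red_fields = integer(0), low_confidence = integer(0))
  step <- 0L
  while (step < max_steps && !stop_condition(session)) {
    step <- step + 1L
    session <- sort_queue(session)
    history <- rbind(history, data.frame(
      step = step, queue_size = length(session$queue),
      red_fields = sum(vapply(session$queue, red_count, 1L)),
      low_confidence = sum(vapply(session$queue, low_confidence_count, 1L))))
    target <- session$queue[[1L]]
    truth <- truths[[target$sample_id]]
    for (attr in schema_attributes()) {
      pred <- target$predictions[[attr]]
      tv <- if (!is.null(truth)) truth[[attr]] else NA_character_
      edit <- if (is.na(tv)) {
        user_edit(attr, "set-unknown")
      } else if (identical(tolower(pred$value), tolower(tv))) {
        user_edit(attr, "confirm")
      } else {
        user_edit(attr, "new-value", value = tolower(tv))
      }
      session <- apply_edit(session, target$sample_id, edit)
    }
    session <- finalize_sample(session, target$sample_id)
  }
  list(session = session, history = history)
}
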
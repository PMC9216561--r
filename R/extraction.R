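#' Traffic-light confidence thresholds
#'
#' Predictions with confidence above the green threshold are shown as
#' accurate (green), between the yellow and green thresholds as to-be-
#' verified (yellow), and below the yellow threshold as probably wrong (red).
#'
#' @param green Green threshold (default 0.8).
#' @param yellow Yellow threshold (default 0.6).
#' @return An object of class `gemi_thresholds`.
#' @export
thresholds <- function(green = 0.8, yellow = 0.6) {
  stopifnot(yellow >= 0, yellow < green, green <= 1)
  structure(list(green = green, yellow = yellow), class = "gemi_thresholds")
}

#' Combine per-token probabilities into a prediction confidence
#'
#' Three strategies: `"product"` multiplies the probabilities of all the
#' generated tokens, `"min"` selects the lowest probability among them (the
#' most critical part of the text) and `"first"` selects the probability of
#' the first token (the most informative part). The first-token option is the
#' best calibrated with prediction correctness and is the default throughout
#' the package. For an empty trace (immediate `<EOS>`), the probability the
#' model assigned to that `<EOS>` is returned when recorded (its commitment
#' to "nothing to extract"), else 0.
#'
#' @param trace A [generation_trace()].
#' @param strategy `"first"`, `"min"` or `"product"`.
#' @return A probability in `[0, 1]`.
#' @examples
#' confidence(generation_trace(c("a", "b"), c(0.9, 0.5)), "product")
#' @export
confidence <- function(trace, strategy = c("first", "min", "product")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(trace, "generation_trace"))
  if (length(trace$probs) == 0L) {
    return(if (!is.na(trace$eos_prob)) trace$eos_prob else 0)
  }
  switch(strategy,
         product = prod(trace$probs),
         min = min(trace$probs),
         first = trace$probs[[1]])
}

#' Classify a confidence value into a traffic-light class
#'
#' Green iff the confidence is strictly above the green threshold; red iff it
#' is strictly below the yellow threshold; yellow otherwise (so values
#' exactly at either threshold are yellow).
#'
#' @param conf Confidence in `[0, 1]`.
#' @param th A [thresholds()] object.
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
classify_confidence <- function(conf, th = thresholds()) {
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) ||
      conf < 0 || conf > 1) {
    stop("confidence must be a probability in [0, 1]", call. = FALSE)
  }
  if (conf > th$green) "green" else if (conf < th$yellow) "red" else "yellow"
}

#' Extract one attribute from preprocessed input text
#'
#' Builds the task-conditioned prompt
#' `"<BOS> " + input_text + " <SEP> " + attribute + ":"`, decodes greedily
#' and scores the generation. An empty generation (immediate `<EOS>`) yields
#' the value `"unknown"`. Each attribute is extracted independently of the
#' others; no state is carried between calls.
#'
#' @param adapter A generating model adapter.
#' @param input_text Preprocessed linearized sample text.
#' @param attribute One of the 15 schema attribute names.
#' @param strategy Confidence strategy (see [confidence()]).
#' @param th A [thresholds()] object.
#' @param max_new_tokens Generation budget per attribute.
#' @return An object of class `gemi_prediction`: attribute, value, trace,
#'   confidence, strategy, traffic light and an `approved` flag used by the
#'   annotation loop.
#' @export
extract_attribute <- function(adapter, input_text, attribute,
                              strategy = "first", th = thresholds(),
                              max_new_tokens = 8L) {
  assert_attribute(attribute)
  prompt <- paste0("<BOS> ", input_text, " <SEP> ", attribute, ":")
  trace <- generate(adapter, prompt, max_new_tokens = max_new_tokens)
  value <- if (length(trace$tokens)) paste(trace$tokens, collapse = " ") else "unknown"
  conf <- confidence(trace, strategy)
  structure(list(attribute = attribute, value = value, trace = trace,
                 confidence = conf, strategy = strategy,
                 traffic_light = classify_confidence(conf, th),
                 approved = FALSE),
            class = "gemi_prediction")
}

#' @export
print.gemi_prediction <- function(x, ...) {
  cat(sprintf("%s = %s  [%s, conf %.3f%s]\n", x$attribute, x$value,
              x$traffic_light, x$confidence,
              if (x$approved) ", approved" else ""))
  invisible(x)
}

#' Extract the full attribute table for one sample
#'
#' Linearizes and preprocesses the record, then extracts each of the 15
#' schema attributes independently. A failure on one attribute is captured
#' as an `"unknown"` red prediction and does not abort the remaining
#' attributes.
#'
#' @param adapter A generating model adapter.
#' @param record A [geo_sample()].
#' @param strategy Confidence strategy.
#' @param th A [thresholds()] object.
#' @param config A [preprocess_config()].
#' @return An object of class `extraction_result` carrying the sample and
#'   series ids, the preprocessed input text and exactly one prediction per
#'   schema attribute.
#' @export
extract_all <- function(adapter, record, strategy = "first", th = thresholds(),
                        config = preprocess_config()) {
  stopifnot(inherits(record, "geo_sample"))
  input_text <- preprocess(linearize(record), config)
  preds <- lapply(schema_attributes(), function(a) {
    tryCatch(
      extract_attribute(adapter, input_text, a, strategy = strategy, th = th),
      error = function(e) {
        structure(list(attribute = a, value = "unknown",
                       trace = generation_trace(character(0), numeric(0)),
                       confidence = 0, strategy = strategy,
                       traffic_light = "red", approved = FALSE,
                       error = conditionMessage(e)),
                  class = "gemi_prediction")
      })
  })
  names(preds) <- schema_attributes()
  structure(list(sample_id = record$sample_id, series_id = record$series_id,
                 input_text = input_text, predictions = preds),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ", x$sample_id,
      if (!is.null(x$series_id)) paste0(" (", x$series_id, ")"), "\n", sep = "")
  for (p in x$predictions) {
    cat("  ")
    print(p)
  }
  invisible(x)
}

# count of non-green fields, the sorting key of the annotation queue
low_confidence_count <- function(result) {
  sum(vapply(result$predictions, function(p) p$traffic_light != "green", TRUE))
}

red_count <- function(result) {
  sum(vapply(result$predictions, function(p) p$traffic_light == "red", TRUE))
}

#' Convert extraction results to a data frame
#'
#' One row per sample: `gsm`, `gse`, then the 15 attribute columns in schema
#' order; optionally a confidence column per attribute.
#'
#' @param results List of `extraction_result` objects.
#' @param confidence Append `<attribute>.confidence` columns.
#' @return A data frame with 17 columns (32 with confidences).
#' @export
results_to_table <- function(results, confidence = FALSE) {
  attrs <- schema_attributes()
  rows <- lapply(results, function(r) {
    vals <- vapply(r$predictions[attrs], `[[`, "", "value")
    row <- c(gsm = r$sample_id,
             gse = if (is.null(r$series_id)) "" else r$series_id, vals)
    if (confidence) {
      confs <- vapply(r$predictions[attrs], function(p) format(p$confidence), "")
      names(confs) <- paste0(attrs, ".confidence")
      row <- c(row, confs)
    }
    row
  })
  header <- c("gsm", "gse", attrs,
              if (confidence) paste0(attrs, ".confidence"))
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (!length(rows)) {
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  }
  names(df) <- header
  rownames(df) <- NULL
  df
}

#' Write extraction results to CSV or JSON
#'
#' CSV holds one row per sample (see [results_to_table()]); JSON mirrors the
#' nested `extraction_result` structure including per-token probabilities.
#'
#' @param results List of `extraction_result` objects.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @param confidence For CSV, include per-attribute confidence columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json"),
                          confidence = FALSE) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(results_to_table(results, confidence = confidence), path,
                     row.names = FALSE)
  } else {
    obj <- lapply(results, result_to_list)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

result_to_list <- function(r) {
  list(sample_id = r$sample_id,
       series_id = if (is.null(r$series_id)) NULL else r$series_id,
       input_text = r$input_text,
       predictions = lapply(r$predictions, function(p) {
         list(attribute = p$attribute, value = p$value,
              confidence = p$confidence, strategy = p$strategy,
              traffic_light = p$traffic_light, approved = p$approved,
              tokens = as.list(p$trace$tokens), probs = as.list(p$trace$probs))
       }))
}
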
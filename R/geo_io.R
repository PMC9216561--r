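#' Construct a GEO sample record
#'
#' A `geo_sample` is one GEO Sample (GSM): an identifier, an optional Series
#' (GSE) identifier, an ordered map of metadata fields and an optional ordered
#' map of characteristic sub-pairs. Characteristics are rendered inline inside
#' a `characteristics` field when the record is linearized; when the supplied
#' `fields` do not already contain a `characteristics` entry, one is inserted
#' before `description` (or appended) so the field order is explicit and
#' preserved through read/serialize round trips.
#'
#' @param sample_id GSM identifier (non-empty string).
#' @param fields Named character vector of metadata fields, in order. Names
#'   must be unique.
#' @param characteristics Optional named character vector of characteristic
#'   sub-pairs (e.g. `c("condition" = "mtb-infected")`).
#' @param series_id Optional GSE identifier.
#' @return An object of class `geo_sample`.
#' @examples
#' geo_sample("GSM1", c(title = "x", organism = "homo sapiens"))
#' @export
geo_sample <- function(sample_id, fields = character(), characteristics = NULL,
                       series_id = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  fields <- coerce_fields(fields)
  if (anyDuplicated(names(fields))) {
    stop("field names must be unique within a record", call. = FALSE)
  }
  characteristics <- coerce_fields(characteristics)
  if (length(characteristics) && !("characteristics" %in% names(fields))) {
    pos <- match("description", names(fields))
    if (is.na(pos)) {
      fields <- c(fields, characteristics = "")
    } else {
      fields <- append(fields, c(characteristics = ""), after = pos - 1L)
    }
  }
  structure(
    list(
      sample_id = sample_id,
      series_id = if (!is.null(series_id) && nzchar(series_id)) series_id else NULL,
      fields = fields,
      characteristics = characteristics
    ),
    class = "geo_sample"
  )
}

# coerce a named vector/list to a named character vector (possibly empty)
coerce_fields <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  out <- vapply(x, function(v) paste(as.character(v), collapse = " "), "")
  names(out) <- names(x)
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("all fields must be named", call. = FALSE)
  }
  out
}

#' @export
print.geo_sample <- function(x, ...) {
  cat("<geo_sample> ", x$sample_id,
      if (!is.null(x$series_id)) paste0(" (", x$series_id, ")"), "\n", sep = "")
  for (nm in names(x$fields)) {
    if (nm == "characteristics" && length(x$characteristics)) {
      cat("  characteristics:\n")
      for (k in names(x$characteristics)) {
        cat("    ", k, ": ", x$characteristics[[k]], "\n", sep = "")
      }
    } else {
      cat("  ", nm, ": ", x$fields[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Parse one GEO-style sample record
#'
#' Two dialects are supported. `"soft"` is a minimal subset of NCBI GEO's SOFT
#' format: a `^SAMPLE = <id>` header, `!Sample_<key> = <value>` attribute
#' lines (underscores in `<key>` map to spaces in the field name), repeated
#' `!Sample_characteristics_ch1 = <sub-key>: <sub-value>` lines populating the
#' characteristics map, and `!Sample_series_id` giving the GSE. `"json"`
#' mirrors the `geo_sample` structure one-to-one
#' (`{"sample_id": ..., "series_id": ..., "fields": {...},
#' "characteristics": {...}}`).
#'
#' @param text Character: the record, either as a single string or a vector of
#'   lines (SOFT), or a JSON string / path handled by [jsonlite::fromJSON()].
#' @param dialect `"soft"` or `"json"`.
#' @return A [geo_sample()].
#' @export
parse_sample <- function(text, dialect = c("soft", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") parse_sample_json(text) else parse_sample_soft(text)
}

parse_sample_soft <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  sample_id <- NULL
  series_id <- NULL
  fields <- character(0)
  fnames <- character(0)
  char_keys <- character(0)
  char_vals <- character(0)
  char_seen <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\^SAMPLE\\s*=", ln)) {
      sample_id <- trimws(sub("^\\^SAMPLE\\s*=", "", ln))
      next
    }
    if (!grepl("^!Sample_", ln) || !grepl("=", ln, fixed = TRUE)) {
      stop("malformed SOFT line ", i, ": ", ln, call. = FALSE)
    }
    key <- trimws(sub("^!Sample_([^=]*)=.*$", "\\1", ln))
    val <- sub("^[^=]*=\\s?", "", ln)
    if (key == "geo_accession") {
      if (is.null(sample_id)) sample_id <- trimws(val)
    } else if (key == "series_id") {
      series_id <- trimws(val)
    } else if (key == "characteristics_ch1") {
      if (!char_seen) {
        # record the position of the characteristics block in field order
        fields <- c(fields, "")
        fnames <- c(fnames, "characteristics")
        char_seen <- TRUE
      }
      m <- regexpr(": ", val, fixed = TRUE)
      if (m > 0) {
        char_keys <- c(char_keys, substr(val, 1L, m - 1L))
        char_vals <- c(char_vals, substr(val, m + 2L, nchar(val)))
      } else {
        char_keys <- c(char_keys, trimws(val))
        char_vals <- c(char_vals, "")
      }
    } else {
      fields <- c(fields, val)
      fnames <- c(fnames, gsub("_", " ", key, fixed = TRUE))
    }
  }
  if (is.null(sample_id) || !nzchar(sample_id)) {
    stop("SOFT record has no sample identifier (^SAMPLE line)", call. = FALSE)
  }
  names(fields) <- fnames
  geo_sample(sample_id, fields,
             characteristics = if (length(char_keys)) stats::setNames(char_vals, char_keys),
             series_id = series_id)
}

parse_sample_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(obj$sample_id)) stop("JSON record has no sample_id", call. = FALSE)
  fields <- if (length(obj$fields)) {
    stats::setNames(vapply(obj$fields, as.character, ""), names(obj$fields))
  } else character(0)
  ch <- if (length(obj$characteristics)) {
    stats::setNames(vapply(obj$characteristics, as.character, ""),
                    names(obj$characteristics))
  } else NULL
  geo_sample(obj$sample_id, fields, characteristics = ch,
             series_id = if (!is.null(obj$series_id)) obj$series_id)
}

#' Serialize a sample record
#'
#' Inverse of [parse_sample()]: writes the record in the SOFT-lite or JSON
#' dialect such that parsing the output reproduces the record.
#'
#' @param record A [geo_sample()].
#' @param dialect `"soft"` or `"json"`.
#' @return A single string.
#' @export
serialize_sample <- function(record, dialect = c("soft", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(record, "geo_sample"))
  if (dialect == "json") {
    obj <- list(sample_id = record$sample_id)
    if (!is.null(record$series_id)) obj$series_id <- record$series_id
    obj$fields <- as.list(record$fields[names(record$fields) != "characteristics"])
    if (length(record$characteristics)) {
      obj$characteristics <- as.list(record$characteristics)
    }
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE)))
  }
  out <- paste0("^SAMPLE = ", record$sample_id)
  for (nm in names(record$fields)) {
    if (nm == "characteristics") {
      for (k in names(record$characteristics)) {
        out <- c(out, paste0("!Sample_characteristics_ch1 = ", k, ": ",
                             record$characteristics[[k]]))
      }
    } else {
      out <- c(out, paste0("!Sample_", gsub(" ", "_", nm, fixed = TRUE), " = ",
                           record$fields[[nm]]))
    }
  }
  if (!is.null(record$series_id)) {
    out <- c(out, paste0("!Sample_series_id = ", record$series_id))
  }
  paste(out, collapse = "\n")
}

#' Linearize a sample record into model input text
#'
#' Converts the ordered field map into the bracketed plain-text form the
#' language model consumes: field keys are enclosed in square brackets and
#' values reported unchanged, `"[name of the field]: metadata-free-text"`,
#' concatenated in field order. Characteristic sub-pairs are rendered inline
#' inside the `characteristics` field value as `"sub-key: sub-value"`
#' sequences. No preprocessing is applied here; see [preprocess()].
#'
#' @param record A [geo_sample()].
#' @return A single string (empty for an empty record).
#' @examples
#' linearize(geo_sample("GSM1", c(a = "x", b = "y")))
#' @export
linearize <- function(record) {
  stopifnot(inherits(record, "geo_sample"))
  if (!length(record$fields)) return("")
  parts <- vapply(names(record$fields), function(nm) {
    val <- record$fields[[nm]]
    if (nm == "characteristics" && length(record$characteristics)) {
      rendered <- paste(sprintf("%s: %s", names(record$characteristics),
                                record$characteristics), collapse = " ")
      val <- trimws(paste(rendered, val))
    }
    sprintf("[%s]: %s", nm, val)
  }, "")
  trimws(paste(parts, collapse = " "))
}

#' Preprocessing configuration
#'
#' Controls the text normalization applied before tokenization: lowercasing,
#' replacement of special characters by spaces, removal of over-long words
#' (which rarely carry usable information, e.g. URLs and serialized arrays)
#' and truncation to a fixed token budget matching the model context.
#'
#' @param lowercase Lowercase the text first (default `TRUE`).
#' @param strip_chars Characters replaced by a single space (default `*`
#'   and `_`, so compound tokens such as `"dc_mtb"` become separable words).
#' @param max_word_chars Words longer than this many characters are removed
#'   (default 30).
#' @param max_tokens Keep only the first `max_tokens` tokens (default 400).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(lowercase = TRUE, strip_chars = c("*", "_"),
                              max_word_chars = 30L, max_tokens = 400L) {
  stopifnot(max_word_chars >= 1L, max_tokens >= 1L)
  structure(list(lowercase = isTRUE(lowercase),
                 strip_chars = as.character(strip_chars),
                 max_word_chars = as.integer(max_word_chars),
                 max_tokens = as.integer(max_tokens)),
            class = "preprocess_config")
}

#' Preprocess linearized metadata text
#'
#' Applies, in order: lowercasing; replacement of each strip character by a
#' single space; whitespace collapsing; removal of every whitespace-delimited
#' word longer than `max_word_chars` characters; truncation to the first
#' `max_tokens` tokens under the active tokenizer. The operation is
#' idempotent. With the default word-level tokenizer a token is a
#' whitespace-delimited word.
#'
#' @param text Input text (single string).
#' @param config A [preprocess_config()].
#' @param tokenizer Optional tokenizer (see [word_tokenizer()]); when `NULL`
#'   tokens are whitespace-delimited words.
#' @return The preprocessed text (single string).
#' @examples
#' preprocess("DC_MTB_H3K9me3*")
#' @export
preprocess <- function(text, config = preprocess_config(), tokenizer = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (config$lowercase) text <- tolower(text)
  for (ch in config$strip_chars) {
    text <- gsub(ch, " ", text, fixed = TRUE)
  }
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  words <- words[nchar(words) <= config$max_word_chars]
  text <- paste(words, collapse = " ")
  toks <- if (is.null(tokenizer)) words else tokenize_words(tokenizer, text)
  if (length(toks) > config$max_tokens) {
    text <- paste(toks[seq_len(config$max_tokens)], collapse = " ")
  }
  text
}

#' Read every sample record from a SOFT-lite file
#'
#' Splits the file at `^SAMPLE` headers and parses each block with
#' [parse_sample()].
#'
#' @param path Path to a SOFT-lite text file.
#' @return List of [geo_sample()] records.
#' @export
read_soft_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\^SAMPLE\\s*=", lines)
  if (!length(starts)) stop("no ^SAMPLE blocks in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_sample(lines[starts[i]:ends[i]], dialect = "soft")
  })
}

#' Count tokens of a text under the default word tokenizer
#'
#' @param text Single string.
#' @return Integer number of whitespace-delimited words.
#' @export
token_count <- function(text) {
  words <- strsplit(trimws(text), "\\s+")[[1]]
  sum(nzchar(words))
}
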
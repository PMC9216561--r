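#' Construct a source annotation record
#'
#' One row of a Cistrome-style or ENCODE-style annotation table. The Cistrome
#' vocabulary carries `Cell Line`, `Cell Type`, `Tissue Type` and
#' `Factor Name`; the ENCODE vocabulary carries the attribute columns of the
#' unified schema plus the free-text attributes `Description`,
#' `Biosample summary` and `replicates.library.biosample.description`.
#'
#' @param source `"cistrome"` or `"encode"`.
#' @param attrs Named character vector of source attributes (missing values
#'   allowed; use `NA` or omit).
#' @param gsm Optional GSM identifier linking the row to a GEO sample.
#' @return An object of class `source_record`.
#' @export
source_record <- function(source = c("cistrome", "encode"), attrs = character(),
                          gsm = NULL) {
  source <- match.arg(source)
  attrs <- attrs[!is.na(attrs)]
  if (length(attrs) && (is.null(names(attrs)) || any(!nzchar(names(attrs))))) {
    stop("source attributes must be named", call. = FALSE)
  }
  declared <- source_attribute_names(source)
  unknown <- setdiff(names(attrs), declared)
  if (length(unknown)) {
    warning("ignoring attributes not in the ", source, " schema: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    attrs <- attrs[setdiff(names(attrs), unknown)]
  }
  structure(list(source = source, attrs = attrs,
                 gsm = if (!is.null(gsm) && !is.na(gsm) && nzchar(gsm)) gsm),
            class = "source_record")
}

#' The tabular ENCODE input schema
#'
#' The 15 attribute columns an ENCODE-style annotation record carries per
#' experiment: the 13 distinct mapped columns plus the free-text
#' `Description` and `Biosample summary`. The nested
#' `replicates.library.biosample.description` path is accepted as an
#' additional input but belongs to the replicate structure rather than the
#' per-record schema; it is only used when building fallback text.
#'
#' @return Character vector of 15 ENCODE attribute names.
#' @export
encode_input_schema <- function() {
  c("Classification", "Biosample term name", "Assay Name", "Assay Type",
    "Target of Assay", "Organism", "Life stage", "Age", "Age units", "Sex",
    "Ethnicity", "Health status", "Investigated as", "Description",
    "Biosample summary")
}

source_attribute_names <- function(source) {
  if (source == "cistrome") {
    c("Cell Line", "Cell Type", "Tissue Type", "Factor Name")
  } else {
    c("Biosample term name", "Assay Name", "Assay Type", "Target of Assay",
      "Organism", "Life stage", "Age", "Age units", "Sex", "Ethnicity",
      "Health status", "Classification", "Investigated as",
      "Description", "Biosample summary",
      "replicates.library.biosample.description")
  }
}

get_attr <- function(record, name) {
  v <- unname(record$attrs[name])
  if (length(v) != 1L || is.na(v) || !nzchar(v)) NA_character_ else v
}

#' Map a Cistrome record into the unified schema
#'
#' `Cell Line` and `Cell Type` are copied, `Tissue Type` maps to `tissue` and
#' `Factor Name` to `target`; all other unified attributes stay null.
#'
#' @param record A [source_record()] with `source == "cistrome"`.
#' @return A named character vector over the 15 schema attributes (`NA` for
#'   null).
#' @export
map_cistrome <- function(record) {
  stopifnot(inherits(record, "source_record"))
  if (record$source != "cistrome") {
    stop("map_cistrome requires a cistrome record (schema error)", call. = FALSE)
  }
  out <- empty_unified_record()
  out["cell line"] <- get_attr(record, "Cell Line")
  out["cell type"] <- get_attr(record, "Cell Type")
  out["tissue"] <- get_attr(record, "Tissue Type")
  out["target"] <- get_attr(record, "Factor Name")
  out
}

#' Map an ENCODE record into the unified schema
#'
#' The `Classification` attribute disambiguates the `Biosample term name`:
#' when it reads `"cell line"` the term becomes the cell line (tissue null),
#' when `"tissue"` it becomes the tissue (cell line null); cell type is set
#' to null in both cases. Any other classification leaves both null with a
#' warning. The remaining attributes map by direct renaming: Assay Name to
#' technique, Assay Type to technique type, Target of Assay to target,
#' Organism to species, Health status to disease, Investigated as to feature,
#' and Life stage, Age, Age units, Sex, Ethnicity, Classification copied.
#'
#' @param record A [source_record()] with `source == "encode"`.
#' @return A named character vector over the 15 schema attributes.
#' @export
map_encode <- function(record) {
  stopifnot(inherits(record, "source_record"))
  if (record$source != "encode") {
    stop("map_encode requires an encode record (schema error)", call. = FALSE)
  }
  out <- empty_unified_record()
  classification <- get_attr(record, "Classification")
  term <- get_attr(record, "Biosample term name")
  cls <- tolower(trimws(ifelse(is.na(classification), "", classification)))
  if (cls == "cell line") {
    out["cell line"] <- term
  } else if (cls == "tissue") {
    out["tissue"] <- term
  } else if (nzchar(cls) && !is.na(term)) {
    warning("unknown Classification value '", classification,
            "'; cell line and tissue left null", call. = FALSE)
  }
  out["cell type"] <- NA_character_
  out["technique"] <- get_attr(record, "Assay Name")
  out["technique type"] <- get_attr(record, "Assay Type")
  out["target"] <- get_attr(record, "Target of Assay")
  out["species"] <- get_attr(record, "Organism")
  out["life stage"] <- get_attr(record, "Life stage")
  out["age"] <- get_attr(record, "Age")
  out["age units"] <- get_attr(record, "Age units")
  out["sex"] <- get_attr(record, "Sex")
  out["ethnicity"] <- get_attr(record, "Ethnicity")
  out["disease"] <- get_attr(record, "Health status")
  out["classification"] <- classification
  out["feature"] <- get_attr(record, "Investigated as")
  out
}

#' Build fallback input text for an ENCODE record without a GSM
#'
#' When no GEO sample is linked, input text is built by concatenating the
#' ENCODE free-text attributes `Description`, `Biosample summary` and
#' `replicates.library.biosample.description` (in that order,
#' space-separated, skipping missing components) into the `characteristics`
#' and `description` fields of a synthetic sample record.
#'
#' @param record A [source_record()] with `source == "encode"` and no GSM.
#' @return A [geo_sample()] whose `characteristics`/`description` fields hold
#'   the concatenated text.
#' @export
build_fallback_text <- function(record) {
  stopifnot(inherits(record, "source_record"))
  if (record$source != "encode") {
    stop("build_fallback_text requires an encode record", call. = FALSE)
  }
  parts <- c(get_attr(record, "Description"),
             get_attr(record, "Biosample summary"),
             get_attr(record, "replicates.library.biosample.description"))
  text <- paste(parts[!is.na(parts)], collapse = " ")
  geo_sample(sample_id = if (!is.null(record$gsm)) record$gsm else "encode-sample",
             fields = c(characteristics = text, description = text))
}

#' Construct a training example
#'
#' The unit of fine-tuning: a preprocessed linearized input text, a task
#' keyword (an attribute name followed by `":"`) and a target value.
#'
#' @param input Preprocessed linearized input text.
#' @param task Task keyword, e.g. `"cell line:"`.
#' @param target Target value text (non-empty).
#' @return An object of class `gemi_training_example`.
#' @export
training_example <- function(input, task, target) {
  stopifnot(is.character(input), length(input) == 1L,
            is.character(task), length(task) == 1L, nzchar(task),
            is.character(target), length(target) == 1L, nzchar(target))
  structure(list(input = input, task = task, target = target),
            class = "gemi_training_example")
}

#' Split a unified record into per-attribute training examples
#'
#' Each annotated sample becomes as many training examples as it has
#' non-null attributes: all examples share the same input text while the task
#' is the attribute name followed by `":"` and the target is the attribute
#' value. Tasks and targets are lowercased, consistently with the text
#' preprocessing.
#'
#' @param unified Named character vector over the schema attributes (`NA` =
#'   null), as returned by [map_cistrome()] / [map_encode()].
#' @param input Preprocessed linearized input text shared by the examples.
#' @return List of [training_example()] objects (possibly empty).
#' @export
split_into_training_examples <- function(unified, input) {
  bad <- setdiff(names(unified), schema_attributes())
  if (length(bad)) {
    stop("attributes outside the schema: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- names(unified)[!is.na(unified) & nzchar(unified)]
  lapply(keep, function(a) {
    training_example(input, paste0(tolower(a), ":"), tolower(unified[[a]]))
  })
}

#' Format a training example as a model training string
#'
#' Produces `"<BOS> " + input + " <SEP> " + task + " " + target + " <EOS>"`
#' with the three literal special keywords (beginning of sentence, separator,
#' end of sentence).
#'
#' @param ex A [training_example()].
#' @return A single string.
#' @examples
#' format_training_string(training_example("s", "cell line:", "hela-s3"))
#' @export
format_training_string <- function(ex) {
  stopifnot(inherits(ex, "gemi_training_example"))
  paste0("<BOS> ", ex$input, " <SEP> ", ex$task, " ", ex$target, " <EOS>")
}

#' Parse a formatted training string back into a training example
#'
#' Inverse of [format_training_string()]: splits on `<SEP>`/`<EOS>`; the task
#' is the first word (ending in `":"`) after the separator unless the
#' following word also carries the task (multi-word attribute names end with
#' a colon only on their last word).
#'
#' @param text A formatted training string.
#' @return A [training_example()].
#' @export
parse_training_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^<BOS>\\s*(.*?)\\s*<SEP>\\s*(.*?)\\s*<EOS>\\s*$", text))[[1]]
  if (length(m) != 3L) stop("not a valid training string: ", text, call. = FALSE)
  input <- m[2]
  tail_words <- strsplit(trimws(m[3]), "\\s+")[[1]]
  colon_at <- which(endsWith(tail_words, ":"))
  if (!length(colon_at)) stop("no task keyword in training string", call. = FALSE)
  k <- colon_at[[1]]
  task <- paste(tail_words[seq_len(k)], collapse = " ")
  target <- paste(tail_words[-seq_len(k)], collapse = " ")
  training_example(input, task, target)
}

#' Merge per-source training example sets
#'
#' Concatenates the example lists obtained from the heterogeneous sources;
#' the resulting set of task names is the union of both sources' attributes.
#' Samples annotated in both sources are kept twice (no deduplication).
#'
#' @param ... Lists of [training_example()] objects.
#' @return A single concatenated list.
#' @export
merge_datasets <- function(...) {
  out <- c(...)
  stopifnot(all(vapply(out, inherits, TRUE, "gemi_training_example")))
  out
}

# ---- tabular readers and JSONL ---------------------------------------------

#' Read a Cistrome- or ENCODE-style annotation table
#'
#' Reads a delimited text table whose header names the source attributes
#' (a `gsm` column, when present, links rows to GEO samples) and returns one
#' [source_record()] per row.
#'
#' @param path Path to a TSV/CSV file.
#' @param source `"cistrome"` or `"encode"`.
#' @param sep Field separator (default tab).
#' @return List of [source_record()] objects.
#' @export
read_source_table <- function(path, source = c("cistrome", "encode"),
                              sep = "\t") {
  source <- match.arg(source)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  gsm_col <- intersect(c("gsm", "GSM"), names(df))[1]
  lapply(seq_len(nrow(df)), function(i) {
    row <- unlist(lapply(df[i, , drop = FALSE], as.character))
    names(row) <- names(df)
    gsm <- if (!is.na(gsm_col)) row[[gsm_col]] else NULL
    source_record(source, row[setdiff(names(row), c("gsm", "GSM"))], gsm = gsm)
  })
}

#' Write or read training examples as JSON-lines
#'
#' One JSON object per line with keys `input`, `task`, `target`.
#'
#' @param examples List of [training_example()] objects.
#' @param path Output (or input) file path.
#' @return `write_examples_jsonl` returns `path` invisibly;
#'   `read_examples_jsonl` returns the list of examples.
#' @export
write_examples_jsonl <- function(examples, path) {
  lines <- vapply(examples, function(ex) {
    as.character(jsonlite::toJSON(list(input = ex$input, task = ex$task,
                                       target = ex$target), auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_examples_jsonl
#' @export
read_examples_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln)
    training_example(o$input, o$task, o$target)
  })
}
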
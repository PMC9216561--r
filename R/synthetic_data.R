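#' Default attribute vocabulary of the synthetic generator
#'
#' Cell lines carry biologically documented donor properties (tissue, cell
#' type, disease, sex, donor age, ethnicity) so that a cell-line mention can
#' imply attributes that are absent from the text, the way K562 implies a
#' haematopoietic and lymphoid tissue of origin and a leukemia disease state,
#' or a prostate biosample implies a male donor.
#'
#' @return A list of vocabularies, sampling weights and synonym tables used
#'   by [generate_corpus()].
#' @export
default_vocabulary <- function() {
  cell_lines <- data.frame(
    name = c("k562", "hela-s3", "gm12878", "hepg2", "a549", "mcf-7",
             "lncap", "imr-90"),
    cell_type = c("erythroblast", "epithelial cell", "lymphoblastoid cell",
                  "hepatocyte", "epithelial cell", "epithelial cell",
                  "epithelial cell", "fibroblast"),
    tissue = c("haematopoietic and lymphoid tissue", "cervix",
               "haematopoietic and lymphoid tissue", "liver", "lung",
               "breast", "prostate", "lung"),
    disease = c("leukemia", "adenocarcinoma", "healthy",
                "hepatocellular carcinoma", "lung carcinoma",
                "breast carcinoma", "prostate carcinoma", "healthy"),
    sex = c("female", "female", "female", "male", "male", "female",
            "male", "female"),
    age = c("53", "31", "27", "15", "58", "69", "50", "16"),
    ethnicity = c("caucasian", "african american", "caucasian", "caucasian",
                  "caucasian", "caucasian", "caucasian", "caucasian"),
    stringsAsFactors = FALSE
  )
  list(
    p_cell_line = 0.6,
    cell_lines = cell_lines,
    tissues = c("liver", "lung", "brain", "heart", "kidney", "spleen",
                "prostate", "breast"),
    techniques = c("chip-seq", "rna-seq", "atac-seq", "wgbs"),
    technique_weights = c(0.4, 0.3, 0.2, 0.1),
    technique_types = c("chip-seq" = "dna binding",
                        "rna-seq" = "transcription profiling",
                        "atac-seq" = "chromatin accessibility",
                        "wgbs" = "dna methylation"),
    targets = c("ctcf", "polr2a", "ep300", "h3k27ac", "h3k4me3", "h3k9me3"),
    target_features = c(ctcf = "transcription factor",
                        polr2a = "transcription factor",
                        ep300 = "transcription factor",
                        h3k27ac = "histone", h3k4me3 = "histone",
                        h3k9me3 = "histone"),
    species = c("homo sapiens", "mus musculus"),
    species_weights = c(0.7, 0.3),
    ethnicities = c("caucasian", "asian", "african american"),
    ethnicity_weights = c(0.5, 0.25, 0.25),
    life_stages = c("adult", "child", "embryonic"),
    life_stage_weights = c(0.7, 0.15, 0.15),
    sexes = c("male", "female"),
    diseases_tissue = c("healthy", "carcinoma"),
    disease_weights = c(0.7, 0.3),
    synonyms = c("homo sapiens" = "human", "mus musculus" = "mouse",
                 "chip-seq" = "chip sequencing", "rna-seq" = "rna sequencing",
                 "atac-seq" = "atac sequencing")
  )
}

#' Default implicit-cue table
#'
#' Maps a cue term that may appear in the text to the attribute/value pairs
#' it implies when those attributes are not stated explicitly: each cell-line
#' name implies the donor and biosample properties of that line (prostate
#' carcinoma cell lines imply a male donor, K562 implies a haematopoietic
#' and lymphoid tissue of origin and leukemia), the term `prostate` implies
#' a male donor, an assay name implies its technique type and a ChIP target
#' implies what it is investigated as. Entries are matched in order; earlier
#' entries take precedence.
#'
#' @param vocab A vocabulary as returned by [default_vocabulary()].
#' @return Named list: cue term to named character vector of implied
#'   attribute/value pairs.
#' @export
default_cue_table <- function(vocab = default_vocabulary()) {
  cues <- list()
  cl <- vocab$cell_lines
  for (i in seq_len(nrow(cl))) {
    cues[[cl$name[i]]] <- c(
      "cell type" = cl$cell_type[i], "tissue" = cl$tissue[i],
      "disease" = cl$disease[i], "sex" = cl$sex[i], "age" = cl$age[i],
      "age units" = "year", "life stage" = "adult",
      "ethnicity" = cl$ethnicity[i], "species" = "homo sapiens",
      "classification" = "cell line")
  }
  cues[["prostate"]] <- c("sex" = "male")
  for (tech in vocab$techniques) {
    cues[[tech]] <- c("technique type" = unname(vocab$technique_types[tech]))
  }
  for (tg in vocab$targets) {
    cues[[tg]] <- c("feature" = unname(vocab$target_features[tg]))
  }
  cues
}

#' Synthetic corpus generator configuration
#'
#' The generator emulates GEO sample records (gsm, title, sample type,
#' source name, organism, characteristics, description) whose ground-truth
#' attributes are known. Attributes may be stated explicitly, stated through
#' a synonym, or left implicit (dropped from the text while a cue term that
#' implies them remains).
#'
#' @param n_samples Number of samples to generate.
#' @param seed Random seed; the corpus is deterministic given the seed.
#' @param field_dropout_rate Probability that an attribute's explicit mention
#'   is omitted from the text. A dropped attribute stays in the truth only
#'   when a cue present in the text implies it (then labeled implicit).
#' @param synonym_rate Probability that a mention uses a listed synonym
#'   instead of the canonical value (the truth keeps the canonical value).
#' @param cue_table Implicit-cue table, see [default_cue_table()].
#' @param vocab Attribute vocabulary, see [default_vocabulary()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples, seed = 1L, field_dropout_rate = 0.2,
                             synonym_rate = 0.2,
                             cue_table = NULL, vocab = default_vocabulary()) {
  if (n_samples < 0) stop("n_samples must be nonnegative", call. = FALSE)
  stopifnot(field_dropout_rate >= 0, field_dropout_rate <= 1,
            synonym_rate >= 0, synonym_rate <= 1)
  if (is.null(cue_table)) cue_table <- default_cue_table(vocab)
  for (cue in cue_table) {
    bad <- setdiff(names(cue), schema_attributes())
    if (length(bad)) {
      stop("cue table references unknown attributes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 field_dropout_rate = field_dropout_rate,
                 synonym_rate = synonym_rate, cue_table = cue_table,
                 vocab = vocab),
            class = "generator_config")
}

wsample <- function(x, w = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = w)]
}

# draw the ground-truth attribute profile of one sample
draw_profile <- function(vocab) {
  truth <- empty_unified_record()
  is_cell_line <- stats::runif(1) < vocab$p_cell_line
  if (is_cell_line) {
    row <- vocab$cell_lines[sample.int(nrow(vocab$cell_lines), 1L), ]
    truth["cell line"] <- row$name
    truth["cell type"] <- row$cell_type
    truth["tissue"] <- row$tissue
    truth["disease"] <- row$disease
    truth["sex"] <- row$sex
    truth["age"] <- row$age
    truth["age units"] <- "year"
    truth["life stage"] <- "adult"
    truth["ethnicity"] <- row$ethnicity
    truth["species"] <- "homo sapiens"
    truth["classification"] <- "cell line"
    anchor <- row$name
  } else {
    tissue <- wsample(vocab$tissues)
    truth["tissue"] <- tissue
    truth["species"] <- wsample(vocab$species, vocab$species_weights)
    truth["sex"] <- if (tissue == "prostate") "male" else wsample(vocab$sexes)
    stage <- wsample(vocab$life_stages, vocab$life_stage_weights)
    truth["life stage"] <- stage
    truth["age"] <- as.character(switch(stage,
                                        adult = sample(20:80, 1L),
                                        child = sample(2:16, 1L),
                                        embryonic = sample(10:18, 1L)))
    truth["age units"] <- if (stage == "embryonic") "day" else "year"
    if (truth["species"] == "homo sapiens") {
      truth["ethnicity"] <- wsample(vocab$ethnicities, vocab$ethnicity_weights)
    }
    truth["disease"] <- wsample(vocab$diseases_tissue, vocab$disease_weights)
    truth["classification"] <- "tissue"
    anchor <- tissue
  }
  technique <- wsample(vocab$techniques, vocab$technique_weights)
  truth["technique"] <- technique
  truth["technique type"] <- unname(vocab$technique_types[technique])
  if (technique == "chip-seq") {
    target <- wsample(vocab$targets)
    truth["target"] <- target
    truth["feature"] <- unname(vocab$target_features[target])
  }
  list(truth = truth, anchor = anchor, is_cell_line = is_cell_line)
}

# attributes rendered as characteristics sub-pairs vs description pairs
CHARACTERISTIC_ATTRS <- c("cell line", "cell type", "tissue", "sex", "age",
                          "age units", "life stage", "ethnicity", "disease")
DESCRIPTION_ATTRS <- c("technique", "technique type", "target", "feature",
                       "classification")

#' Generate a synthetic GEO-like corpus with known ground truth
#'
#' Each sample is a [geo_sample()] record built from templates over the
#' configured vocabulary, paired with its ground-truth unified record and a
#' per-attribute basis label: `"explicit"` when the (possibly synonymous)
#' value is written in the text, `"implicit"` when the value was dropped but
#' remains implied by a cue term present in the text. Attributes dropped
#' without a cue leave the truth null. The biosample anchor (cell-line name
#' or tissue) always appears in the title and source name, as a real GEO
#' record names its biosample.
#'
#' @param config A [generator_config()].
#' @return A list of `labeled_sample` objects
#'   (`record`, `truth`, `basis`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_samples == 0L) return(list())
  with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      generate_sample(config, i)
    })
  })
}

generate_sample <- function(config, i) {
  vocab <- config$vocab
  prof <- draw_profile(vocab)
  truth <- prof$truth
  anchor_attr <- if (prof$is_cell_line) "cell line" else "tissue"
  present <- names(truth)[!is.na(truth)]

  dropped <- stats::runif(length(present)) < config$field_dropout_rate
  names(dropped) <- present
  dropped[anchor_attr] <- FALSE  # the record always names its biosample

  mention <- function(attr) {
    val <- truth[[attr]]
    syn <- vocab$synonyms[val]
    if (!is.na(syn) && stats::runif(1) < config$synonym_rate) unname(syn) else val
  }
  mentions <- vapply(present, mention, "")

  gsm <- sprintf("gsm%d", 100000L + i)
  gse <- sprintf("gse%d", 5000L + ((i - 1L) %/% 8L))
  rep_no <- sample(1:3, 1L)
  title <- sprintf("%s study rep%d", prof$anchor, rep_no)
  source_name <- if (prof$is_cell_line) paste(prof$anchor, "cells")
                 else paste(prof$anchor, "tissue")

  ch_attrs <- intersect(CHARACTERISTIC_ATTRS, present[!dropped[present]])
  ch <- stats::setNames(unname(mentions[ch_attrs]), ch_attrs)
  de_attrs <- intersect(DESCRIPTION_ATTRS, present[!dropped[present]])
  description <- paste(sprintf("%s: %s", de_attrs, mentions[de_attrs]),
                       collapse = " ")

  fields <- c(gsm = gsm, title = title, "sample type" = "sra",
              "source name" = source_name)
  if ("species" %in% present && !dropped[["species"]]) {
    fields <- c(fields, organism = unname(mentions[["species"]]))
  }
  fields <- c(fields, description = description)
  record <- geo_sample(gsm, fields,
                       characteristics = if (length(ch)) ch,
                       series_id = gse)

  text <- tolower(linearize(record))
  basis <- stats::setNames(rep(NA_character_, length(truth)), names(truth))
  for (attr in present) {
    if (!dropped[[attr]]) {
      basis[attr] <- "explicit"
    } else {
      implied <- cue_implies(config$cue_table, text, attr)
      if (!is.null(implied) && identical(implied, unname(truth[[attr]]))) {
        basis[attr] <- "implicit"
      } else {
        truth[attr] <- NA_character_
      }
    }
  }
  structure(list(record = record, truth = truth, basis = basis),
            class = "labeled_sample")
}

# first cue present in `text` that implies `attr` (cues matched in order)
cue_implies <- function(cue_table, text, attr) {
  for (term in names(cue_table)) {
    implied <- cue_table[[term]]
    if (attr %in% names(implied) && grepl(term, text, fixed = TRUE)) {
      return(unname(implied[[attr]]))
    }
  }
  NULL
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat("<labeled_sample>", x$record$sample_id, "\n")
  shown <- !is.na(x$truth)
  for (a in names(x$truth)[shown]) {
    cat(sprintf("  %-15s %-35s (%s)\n", a, x$truth[[a]], x$basis[[a]]))
  }
  invisible(x)
}

#' Split a corpus into train and test sets
#'
#' Seeded, disjoint and exhaustive.
#'
#' @param corpus List of labeled samples.
#' @param train_fraction Fraction assigned to the training set (strictly
#'   between 0 and 1).
#' @param seed Random seed.
#' @return List with elements `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n <- length(corpus)
  n_train <- round(n * train_fraction)
  with_seed(seed, {
    idx <- sample.int(n)
    list(train = corpus[sort(idx[seq_len(n_train)])],
         test = corpus[sort(idx[setdiff(seq_len(n), seq_len(n_train))])])
  })
}

#' Convert labeled samples into training examples
#'
#' Linearizes and preprocesses each record, then splits the ground-truth
#' record into per-attribute training examples.
#'
#' @param corpus List of labeled samples.
#' @param config A [preprocess_config()].
#' @return A list of [training_example()] objects.
#' @export
corpus_to_examples <- function(corpus, config = preprocess_config()) {
  out <- lapply(corpus, function(s) {
    input <- preprocess(linearize(s$record), config)
    split_into_training_examples(s$truth, input)
  })
  do.call(c, out)
}

#' Write or read a labeled corpus as JSON-lines
#'
#' One labeled sample per line: the record (fields, characteristics, ids),
#' the ground-truth attribute map and the per-attribute basis.
#'
#' @param corpus List of labeled samples.
#' @param path File path.
#' @return `write_corpus_jsonl` returns `path` invisibly;
#'   `read_corpus_jsonl` returns the corpus.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(s) {
    truth <- as.list(s$truth[!is.na(s$truth)])
    basis <- as.list(s$basis[!is.na(s$basis)])
    rec <- jsonlite::fromJSON(serialize_sample(s$record, "json"),
                              simplifyVector = FALSE)
    as.character(jsonlite::toJSON(list(record = rec, truth = truth,
                                       basis = basis), auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    record <- parse_sample_json(jsonlite::toJSON(o$record, auto_unbox = TRUE))
    truth <- empty_unified_record()
    for (a in names(o$truth)) truth[a] <- as.character(o$truth[[a]])
    basis <- stats::setNames(rep(NA_character_, 15L), schema_attributes())
    for (a in names(o$basis)) basis[a] <- as.character(o$basis[[a]])
    structure(list(record = record, truth = truth, basis = basis),
              class = "labeled_sample")
  })
}

#' Write corpus records as SOFT-lite text
#'
#' Concatenates the SOFT serialization of every record (blank-line
#' separated), for round trips through [parse_sample()].
#'
#' @param corpus List of labeled samples.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_corpus_soft <- function(corpus, path) {
  blocks <- vapply(corpus, function(s) serialize_sample(s$record, "soft"), "")
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
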
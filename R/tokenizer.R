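#' Word-level tokenizer with reserved special tokens
#'
#' Builds a vocabulary of whitespace-delimited words from a corpus. The
#' special keywords `<BOS>`, `<SEP>` and `<EOS>` (beginning of sentence,
#' separator between input and task, end of sentence) are reserved tokens,
#' together with `<PAD>` and `<UNK>`. Unknown words encode to `<UNK>`.
#'
#' @param texts Character vector of corpus texts the vocabulary is built from.
#' @return An object of class `word_tokenizer`.
#' @export
word_tokenizer <- function(texts) {
  words <- unlist(strsplit(trimws(texts), "\\s+"), use.names = FALSE)
  words <- words[nzchar(words)]
  reserved <- c("<PAD>", "<UNK>", "<BOS>", "<SEP>", "<EOS>")
  # radix sort is locale-independent: the vocabulary (and so the model)
  # must not depend on LC_COLLATE
  extra <- unique(setdiff(words, reserved))
  vocab <- c(reserved, if (length(extra)) sort(extra, method = "radix"))
  structure(
    list(vocab = vocab,
         index = stats::setNames(seq_along(vocab), vocab),
         pad_id = 1L, unk_id = 2L, bos_id = 3L, sep_id = 4L, eos_id = 5L),
    class = "word_tokenizer"
  )
}

#' @export
print.word_tokenizer <- function(x, ...) {
  cat("<word_tokenizer> vocabulary size", length(x$vocab), "\n")
  invisible(x)
}

#' Split a text into word tokens
#'
#' @param tokenizer A [word_tokenizer()].
#' @param text Single string.
#' @return Character vector of tokens (no ids).
#' @export
tokenize_words <- function(tokenizer, text) {
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words[nzchar(words)]
}

#' Encode text to token ids
#'
#' @param tokenizer A [word_tokenizer()].
#' @param text Single string.
#' @return Integer vector of 1-based token ids; out-of-vocabulary words map
#'   to the `<UNK>` id.
#' @export
encode_tokens <- function(tokenizer, text) {
  toks <- tokenize_words(tokenizer, text)
  ids <- unname(tokenizer$index[toks])
  ids[is.na(ids)] <- tokenizer$unk_id
  as.integer(ids)
}

#' Decode token ids to text
#'
#' Word-level tokens are joined with single spaces; reserved tokens are
#' dropped.
#'
#' @param tokenizer A [word_tokenizer()].
#' @param ids Integer vector of token ids.
#' @return Single string.
#' @export
decode_tokens <- function(tokenizer, ids) {
  ids <- ids[ids > 5L]
  paste(tokenizer$vocab[ids], collapse = " ")
}
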
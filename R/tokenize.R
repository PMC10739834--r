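#' Deterministic word/punctuation tokenizer
#'
#' Splits a text on whitespace, then peels leading and trailing punctuation
#' off each chunk into separate tokens. Internal punctuation is kept, so
#' clitics (`"it's"`) and clock times (`"2:30"`) each stay one word token.
#' Numerals count as words. Case is preserved.
#'
#' All word-count statistics in the package (corpus summaries, readability,
#' lexicon percentages) are computed on the word tokens of this tokenizer,
#' i.e. tokens containing at least one alphanumeric character. A plugged-in
#' named-entity recognizer or lemmatizer may tokenize its own way; that never
#' affects the counts reported here.
#'
#' @param text A character scalar (may be empty or `NA`).
#' @return Character vector of tokens, in order; `character(0)` for empty
#'   input.
#' @examples
#' tokenize("The cat sat.")
#' word_tokens("it's 2:30 PM") # three word tokens
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  chunks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  # peel leading/trailing runs of non-alphanumeric characters into their own
  # tokens; the residual core (internal punctuation intact) stays one token
  lead <- sub("^([^[:alnum:]]*).*$", "\\1", chunks)
  core <- substr(chunks, nchar(lead) + 1L, nchar(chunks))
  trail <- sub("^.*?([^[:alnum:]]*)$", "\\1", core)
  core <- substr(core, 1L, nchar(core) - nchar(trail))
  pieces <- rbind(lead, core, trail)   # column-major: per-chunk order kept
  out <- as.vector(pieces)
  out[nzchar(out)]
}

#' @rdname tokenize
#' @export
word_tokens <- function(text) {
  toks <- tokenize(text)
  toks[grepl("[[:alnum:]]", toks)]
}

#' @rdname tokenize
#' @export
count_words <- function(text) {
  vapply(text, function(t) length(word_tokens(t)), integer(1), USE.NAMES = FALSE)
}

# tokenize once, reuse everywhere inside extract_style_vector
is_word_token <- function(tokens) grepl("[[:alnum:]]", tokens)
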
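#' @keywords internal
"_PACKAGE"

# the 26 style-vector feature names, in canonical column order
#' Names of the 26 stylometric features
#'
#' Column order of every feature matrix produced by [extract_features()]:
#' six text-length/readability statistics (Cognitive Load cues), lexicon
#' summary and category percentages (Distancing and Reality Monitoring
#' cues), four composite sums plus the Reality Monitoring score, the mean
#' word concreteness, and four unique named-entity counts (Verifiability
#' cues).
#'
#' @return Character vector of length 26.
#' @export
style_features <- function() {
  c("num_sentences", "num_words", "num_syllables", "avg_syllabes_per_word",
    "fk_grade", "fk_read",
    "Analytic", "Authentic", "Tone",
    "tone_pos", "tone_neg", "Cognition", "memory",
    "focuspast", "focuspresent", "focusfuture",
    "Self_reference", "Other_reference",
    "Perceptual_details", "Contextual_Embedding", "Reality_Monitoring",
    "Concreteness_score",
    "People", "Temporal_details", "Spatial_details", "Quantity_details")
}

#' Percentage of word tokens matching each lexicon category
#'
#' For each category, `100 * matches / total word tokens`. Matching is
#' case-insensitive; an entry `run*` matches any token with prefix `run`;
#' one token may count toward several categories.
#'
#' @param tokens Character vector of word tokens (non-empty).
#' @param lexicon A `veristyle_lexicon` or compiled lexicon.
#' @return Named numeric vector, one percentage per category.
#' @export
score_lexicon <- function(tokens, lexicon) {
  if (length(tokens) == 0L) stop("empty token list", call. = FALSE)
  lex <- compile_lexicon(lexicon)
  toks <- tolower(tokens)
  n <- length(toks)
  vapply(lex, function(cat) {
    hit <- toks %in% cat$exact
    for (stem in cat$stems) hit <- hit | startsWith(toks, stem)
    100 * sum(hit) / n
  }, numeric(1))
}

#' Split a text into sentences
#'
#' Terminal `.`, `!` or `?` followed by whitespace and an uppercase letter
#' or digit ends a sentence; periods of a small abbreviation stop-list do
#' not.
#'
#' @param text A character scalar.
#' @param abbreviations Abbreviations whose trailing period never ends a
#'   sentence.
#' @return Character vector of sentences (at least one for non-empty text).
#' @export
split_sentences <- function(text,
                            abbreviations = c("Mr.", "Mrs.", "Ms.", "Dr.",
                                              "Prof.", "St.", "vs.", "etc.",
                                              "e.g.", "i.e.", "a.m.", "p.m.")) {
  masked <- text
  for (ab in abbreviations) {
    masked <- gsub(ab, gsub(".", "", ab, fixed = TRUE), masked,
                   fixed = TRUE, useBytes = FALSE)
    masked <- gsub(tolower(ab), gsub(".", "", tolower(ab), fixed = TRUE),
                   masked, fixed = TRUE)
  }
  parts <- strsplit(masked, "(?<=[.!?])[\"')\\]]*\\s+(?=[\"'(\\[]?[A-Z0-9])",
                    perl = TRUE)[[1]]
  parts[grepl("[[:alnum:]]", parts)]
}

#' Count syllables with a deterministic vowel-group heuristic
#'
#' Per word: count maximal runs of `a e i o u y`; subtract a silent
#' terminal `e` (a final lone-`e` group preceded by a consonant) unless it
#' is the word's only vowel group; minimum one syllable per word. Tokens
#' without letters (numerals, times) count one syllable. The heuristic is
#' documented and reproducible; exact agreement with any specific
#' readability tool is not claimed.
#'
#' @param words Character vector of word tokens.
#' @return Integer vector of syllable counts.
#' @export
count_syllables <- function(words) {
  w <- gsub("[^a-z]", "", tolower(words))
  hits <- gregexpr("[aeiouy]+", w)
  n <- vapply(hits, function(g) if (g[1] == -1L) 0L else length(g), integer(1))
  n <- n - (n > 1L & grepl("[^aeiouy]e$", w))
  pmax(n, 1L)
}

#' Length and readability statistics of a text
#'
#' The Cognitive Load block of the style vector: sentence, word and
#' syllable counts, mean syllables per word, and the Flesch-Kincaid grade
#' level `0.39 w/s + 11.8 y/w - 15.59` and Flesch reading ease
#' `206.835 - 1.015 w/s - 84.6 y/w` (w words, s sentences, y syllables).
#'
#' @param text A character scalar with at least one word token.
#' @param words Precomputed word tokens of `text` (optional; computed when
#'   omitted).
#' @return A one-row tibble: `num_sentences`, `num_words`, `num_syllables`,
#'   `avg_syllabes_per_word`, `fk_grade`, `fk_read`.
#' @export
readability_block <- function(text, words = NULL) {
  if (is.null(words)) words <- word_tokens(text)
  if (length(words) == 0L) stop("text has no word token", call. = FALSE)
  sentences <- split_sentences(text)
  s <- max(length(sentences), 1L)
  w <- length(words)
  y <- sum(count_syllables(words))
  tibble::tibble(
    num_sentences = s, num_words = w, num_syllables = y,
    avg_syllabes_per_word = y / w,
    fk_grade = 0.39 * (w / s) + 11.8 * (y / w) - 15.59,
    fk_read = 206.835 - 1.015 * (w / s) - 84.6 * (y / w)
  )
}

#' Mean concreteness of content words
#'
#' Lowercase, tokenize, drop stopwords and punctuation, lemmatize, look
#' each remaining word up in the concreteness norms and average the scores
#' of the matches. Unmatched words are excluded from the mean; a text with
#' no match returns `NA` (carried as missing downstream, never zero).
#'
#' @param text A character scalar.
#' @param table Named numeric vector, lowercase lemma -> score in `[1, 5]`.
#' @param stopwords Lowercase stopword vector.
#' @param lemmatizer Function lowercase word -> lemma.
#' @param tokens Precomputed word tokens of `text` (optional).
#' @return List with `score` (numeric or `NA`) and `n_matched`.
#' @export
concreteness_score <- function(text, table, stopwords,
                               lemmatizer = default_lemmatizer,
                               tokens = NULL) {
  stopifnot(length(table) > 0L)
  toks <- tolower(if (is.null(tokens)) word_tokens(tolower(text)) else tokens)
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0L) return(list(score = NA_real_, n_matched = 0L))
  lemmas <- lemmatizer(toks)
  # a word already in the norms wins over its stripped lemma
  key <- ifelse(toks %in% names(table), toks, lemmas)
  hits <- key[key %in% names(table)]
  if (length(hits) == 0L) return(list(score = NA_real_, n_matched = 0L))
  list(score = mean(table[hits]), n_matched = length(hits))
}

#' Unique named-entity counts per verifiability category
#'
#' Runs the pluggable recognizer and counts unique normalized surfaces
#' (case-folded, whitespace-collapsed) per category. Recognizer label
#' mapping: person-like labels -> People, date/time -> Temporal,
#' location/place/facility -> Spatial, percent/money/quantity/ordinal/
#' cardinal -> Quantity; anything else is ignored. The same surface
#' appearing in two categories counts once in each.
#'
#' @param text A character scalar.
#' @param recognizer Function text -> tibble(`surface`, `category`).
#' @return Named integer vector: `People`, `Temporal_details`,
#'   `Spatial_details`, `Quantity_details`.
#' @export
entity_counts <- function(text, recognizer = stub_recognizer) {
  ann <- recognizer(text)
  label_map <- c(
    People = "People", PERSON = "People", PER = "People",
    Temporal = "Temporal", DATE = "Temporal", TIME = "Temporal",
    Spatial = "Spatial", LOC = "Spatial", GPE = "Spatial", FAC = "Spatial",
    LOCATION = "Spatial", FACILITY = "Spatial",
    Quantity = "Quantity", PERCENT = "Quantity", MONEY = "Quantity",
    QUANTITY = "Quantity", ORDINAL = "Quantity", CARDINAL = "Quantity"
  )
  out <- c(People = 0L, Temporal_details = 0L, Spatial_details = 0L,
           Quantity_details = 0L)
  if (nrow(ann) > 0L) {
    cat <- unname(label_map[as.character(ann$category)])
    keep <- !is.na(cat)
    norm <- tolower(gsub("[[:space:]]+", " ", trimws(ann$surface[keep])))
    cat <- cat[keep]
    for (g in unique(cat)) {
      slot <- switch(g, People = "People", Temporal = "Temporal_details",
                     Spatial = "Spatial_details", Quantity = "Quantity_details")
      out[slot] <- length(unique(norm[cat == g]))
    }
  }
  out
}

#' Composite style features from category percentages
#'
#' `Self_reference = i + we`; `Other_reference = shehe + they + you`;
#' `Perceptual_details = attention + visual + auditory + feeling`;
#' `Contextual_Embedding = space + motion + time`;
#' `Reality_Monitoring = Perceptual + Contextual + Affect - Cognition`.
#' `Tone` is the bounded standardized positive/negative difference
#' `50 (1 + (pos - neg) / (pos + neg))`, 50 when both are zero.
#' `Analytic` is the categorical-dynamic index
#' `30 + article + prep - ppron - ipron - auxverb - conj - adverb - negate`
#' and `Authentic` the deception-language composite
#' `30 + Self_reference + Cognition - tone_neg - motion`, both clamped to
#' `[0, 100]`; the two are open, documented approximations of proprietary
#' summary scores (see the package vignette).
#'
#' @param categories Named numeric vector of category percentages covering
#'   all required categories.
#' @return Named numeric vector of the eight composite features.
#' @export
composite_features <- function(categories) {
  missing <- setdiff(required_categories(), names(categories))
  if (length(missing)) {
    stop("missing category percentages: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- function(nm) unname(categories[nm])
  self_ref <- g("i") + g("we")
  other_ref <- g("shehe") + g("they") + g("you")
  perceptual <- g("attention") + g("visual") + g("auditory") + g("feeling")
  contextual <- g("space") + g("motion") + g("time")
  rm_score <- perceptual + contextual + g("Affect") - g("Cognition")
  ps <- g("tone_pos") + g("tone_neg")
  tone <- if (ps > 0) 50 * (1 + (g("tone_pos") - g("tone_neg")) / ps) else 50
  clamp <- function(x) min(max(x, 0), 100)
  analytic <- clamp(30 + g("article") + g("prep") - g("ppron") - g("ipron") -
                      g("auxverb") - g("conj") - g("adverb") - g("negate"))
  authentic <- clamp(30 + self_ref + g("Cognition") - g("tone_neg") - g("motion"))
  c(Self_reference = self_ref, Other_reference = other_ref,
    Perceptual_details = perceptual, Contextual_Embedding = contextual,
    Reality_Monitoring = rm_score, Tone = tone,
    Analytic = analytic, Authentic = authentic)
}

#' Extract the 26-feature style vector of one text
#'
#' @param text A character scalar with at least one word token.
#' @param resources A `veristyle_resources` bundle ([style_resources()],
#'   [fixture_resources()]).
#' @return A one-row tibble with the 26 columns of [style_features()]
#'   (`Concreteness_score` may be `NA`).
#' @export
extract_style_vector <- function(text, resources) {
  stopifnot(inherits(resources, "veristyle_resources"))
  words <- word_tokens(text)
  read_blk <- readability_block(text, words = words)
  cats <- score_lexicon(words, resources$lexicon)
  comps <- composite_features(cats)
  concr <- concreteness_score(text, resources$concreteness,
                              resources$stopwords, resources$lemmatizer,
                              tokens = words)
  ents <- entity_counts(text, resources$recognizer)
  dplyr::bind_cols(
    read_blk,
    tibble::as_tibble_row(c(
      comps[c("Analytic", "Authentic", "Tone")],
      cats[c("tone_pos", "tone_neg", "Cognition", "memory",
             "focuspast", "focuspresent", "focusfuture")],
      comps[c("Self_reference", "Other_reference", "Perceptual_details",
              "Contextual_Embedding", "Reality_Monitoring")]
    )),
    tibble::tibble(Concreteness_score = concr$score),
    tibble::as_tibble_row(as.list(ents))
  )[, style_features()]
}

#' Extract the style-vector matrix of a corpus
#'
#' One row per statement: `id`, `subject_id`, `domain`, `veracity` plus the
#' 26 feature columns. Deterministic for fixed resources; any extraction
#' error is reported with the offending statement id.
#'
#' @param corpus A `veristyle_corpus` (or data frame with `id`, `text`,
#'   `veracity`).
#' @inheritParams extract_style_vector
#' @return A tibble of metadata plus the 26 features.
#' @export
extract_features <- function(corpus, resources = fixture_resources()) {
  feats <- purrr::map(seq_len(nrow(corpus)), function(i) {
    tryCatch(extract_style_vector(corpus$text[i], resources),
             error = function(e) {
               stop("feature extraction failed for statement `",
                    corpus$id[i], "`: ", conditionMessage(e), call. = FALSE)
             })
  })
  meta_cols <- intersect(c("id", "subject_id", "domain", "veracity"),
                         names(corpus))
  meta <- tibble::as_tibble(lapply(stats::setNames(meta_cols, meta_cols),
                                   function(cc) corpus[[cc]]))
  dplyr::bind_cols(meta, dplyr::bind_rows(feats))
}

#' Write / read a feature matrix as CSV
#' @param features Tibble from [extract_features()].
#' @param path CSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
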
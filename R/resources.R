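#' Read a category lexicon in LIWC-style .dic format
#'
#' The format is two `%`-delimited sections: a header table mapping category
#' numbers to names (one `number<TAB>name` per line) followed by entry lines
#' `word<TAB>num [num ...]`. A trailing `*` on an entry marks a stem that
#' matches any token with that prefix. Entries are lowercased on read.
#'
#' @param path Path to the `.dic` file.
#' @return A `veristyle_lexicon`: named list of character vectors (entries
#'   per category).
#' @export
read_dic <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("not a .dic file: missing % delimiters", call. = FALSE)
  head_lines <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  parts <- strsplit(trimws(head_lines), "[\t ]+")
  ids <- vapply(parts, `[`, character(1), 1L)
  nms <- vapply(parts, `[`, character(1), 2L)
  cat_names <- stats::setNames(nms, ids)

  body <- lines[(pct[2] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  entries <- strsplit(trimws(body), "[\t ]+")
  words <- tolower(vapply(entries, `[`, character(1), 1L))
  cats <- lapply(entries, function(e) cat_names[e[-1]])
  out <- lapply(stats::setNames(nms, nms), function(nm) {
    sort(unique(words[vapply(cats, function(cc) nm %in% cc, logical(1))]))
  })
  validate_lexicon(out)
}

#' @rdname read_dic
#' @param categories Named list of character vectors, entries lowercase,
#'   wildcard `*` only in final position.
#' @export
as_lexicon <- function(categories) validate_lexicon(categories)

validate_lexicon <- function(categories) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  empty <- names(categories)[lengths(categories) == 0L]
  if (length(empty)) {
    stop("empty lexicon categories: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  bad <- unlist(lapply(categories, function(w) w[grepl("\\*.", w)]))
  if (length(bad)) {
    stop("wildcard must be final: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  categories <- lapply(categories, tolower)
  structure(categories, class = "veristyle_lexicon")
}

# categories every style-vector lexicon must provide
required_categories <- function() {
  c("i", "we", "shehe", "they", "you", "article", "prep", "ppron", "ipron",
    "auxverb", "conj", "adverb", "negate", "tone_pos", "tone_neg",
    "Cognition", "memory", "focuspast", "focuspresent", "focusfuture",
    "attention", "visual", "auditory", "feeling", "space", "motion", "time",
    "Affect")
}

# split each category into exact entries and wildcard stems, once
compile_lexicon <- function(lexicon) {
  if (inherits(lexicon, "veristyle_compiled_lexicon")) return(lexicon)
  out <- lapply(lexicon, function(entries) {
    wild <- endsWith(entries, "*")
    list(exact = entries[!wild], stems = sub("\\*$", "", entries[wild]))
  })
  structure(out, class = "veristyle_compiled_lexicon")
}

#' Read a word-concreteness table
#'
#' Two tab-separated columns, `word<TAB>score`, scores on the 1 (abstract)
#' to 5 (fully concrete) rating scale of the published concreteness norms.
#' Words are lowercased; duplicate words keep their first score.
#'
#' @param path Path to the TSV file (a header row `word score` is allowed).
#' @return Named numeric vector, names = lowercase lemmas.
#' @export
read_concreteness <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("word", "score"),
                         col_types = "cd", progress = FALSE)
  if (is.na(tbl$score[1])) tbl <- tbl[-1, ] # header row
  tbl$word <- tolower(tbl$word)
  tbl <- tbl[!duplicated(tbl$word), ]
  if (any(tbl$score < 1 | tbl$score > 5, na.rm = TRUE)) {
    stop("concreteness scores must lie in [1, 5]", call. = FALSE)
  }
  stats::setNames(tbl$score, tbl$word)
}

#' Read a stopword list (one word per line)
#' @param path Path to a plain-text file.
#' @return Lowercased character vector.
#' @export
read_stopwords <- function(path) {
  w <- trimws(readLines(path, encoding = "UTF-8"))
  tolower(w[nzchar(w)])
}

#' Rule-based English lemmatizer (default plug-in)
#'
#' A deterministic suffix stripper used before concreteness lookup when no
#' external lemmatizer is plugged in: `-ies -> -y`, doubled-consonant
#' `-ing`/`-ed` undoubling, then `-ing`, `-ed`, `-es`, `-s` removal with a
#' minimum stem length of 3. Any word -> lemma function (or named character
#' map) can replace it in [style_resources()].
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of lemmas, same length.
#' @export
default_lemmatizer <- function(words) {
  vapply(words, function(w) {
    if (nchar(w) > 4L && endsWith(w, "ies")) return(paste0(substr(w, 1, nchar(w) - 3L), "y"))
    # -es only after sibilants (boxes -> box); plain -s otherwise (apples -> apple)
    sib_es <- endsWith(w, "es") && nchar(w) >= 5L &&
      (substr(w, nchar(w) - 2L, nchar(w) - 2L) %in% c("x", "s", "z") ||
         substr(w, nchar(w) - 3L, nchar(w) - 2L) %in% c("ch", "sh"))
    for (suf in c("ing", "ed", if (sib_es) "es" else "s")) {
      if (nchar(w) - nchar(suf) >= 3L && endsWith(w, suf)) {
        stem <- substr(w, 1, nchar(w) - nchar(suf))
        # undouble a doubled final consonant left by -ing/-ed (running -> run)
        n <- nchar(stem)
        if (suf %in% c("ing", "ed") && n >= 3L &&
            substr(stem, n, n) == substr(stem, n - 1L, n - 1L) &&
            !substr(stem, n, n) %in% c("l", "s")) {
          stem <- substr(stem, 1, n - 1L)
        }
        return(stem)
      }
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Deterministic gazetteer named-entity recognizer (stub plug-in)
#'
#' A small, fully deterministic recognizer standing behind the pluggable
#' recognizer interface: gazetteers of person names and place names, weekday
#' / month / holiday words, clock-time and date patterns, and numeric /
#' ordinal / currency / percentage patterns. Any function
#' `text -> tibble(surface, category)` with categories in
#' `{People, Temporal, Spatial, Quantity}` can replace it (e.g. a wrapper
#' around a trained NER model).
#'
#' @param text A character scalar.
#' @return A tibble with columns `surface`, `category`, one row per mention
#'   (not yet deduplicated; [entity_counts()] handles uniqueness).
#' @export
stub_recognizer <- function(text) {
  toks <- tokenize(text)
  n <- length(toks)
  people <- c("mary", "paul", "adam", "john", "sarah", "david", "anna",
              "tom", "emma", "james", "lucy", "peter", "maria", "carlos",
              "yuki", "omar", "ingrid", "pablo", "chen", "fatima")
  places <- c("tokyo", "london", "paris", "rome", "berlin", "madrid",
              "chicago", "boston", "seattle", "denver", "airport",
              "station", "museum", "beach", "downtown", "harbour",
              "kyoto", "lisbon", "oslo", "cairo")
  temporal <- c("monday", "tuesday", "wednesday", "thursday", "friday",
                "saturday", "sunday", "january", "february", "march",
                "april", "june", "july", "august", "september", "october",
                "november", "december", "christmas", "easter", "midnight",
                "noon")
  ordinals <- c("first", "second", "third", "fourth", "fifth", "sixth",
                "seventh", "eighth", "ninth", "tenth")
  numwords <- c("one", "two", "three", "four", "five", "six", "seven",
                "eight", "nine", "ten", "eleven", "twelve", "twenty",
                "thirty", "fifty", "hundred", "thousand", "dozen")
  units <- c("m", "km", "kg", "mi", "miles", "meters", "$", "€", "%")
  if (n == 0L) return(tibble::tibble(surface = character(), category = character()))
  lo <- tolower(toks)
  nxt <- c(toks[-1], ""); nxtlo <- tolower(nxt)
  is_time <- grepl("^[0-9]{1,2}:[0-9]{2}$", toks)
  year_num <- suppressWarnings(as.integer(toks))
  is_year <- grepl("^[0-9]{4}$", toks) & !is.na(year_num) &
    year_num >= 1900 & year_num <= 2099
  is_qtynum <- (grepl("^[0-9]+([.,][0-9]+)?%?$", toks) |
                  grepl("^\\$[0-9]+", toks) |
                  grepl("^[0-9]+(st|nd|rd|th)$", lo)) & !is_time & !is_year
  category <- rep(NA_character_, n)
  category[lo %in% places] <- "Spatial"
  category[lo %in% people & grepl("^[A-Z]", toks)] <- "People"
  category[lo %in% temporal] <- "Temporal"
  category[lo %in% c(ordinals, numwords)] <- "Quantity"
  category[is_qtynum] <- "Quantity"
  category[is_year | is_time] <- "Temporal"
  # bigrams: clock time + AM/PM, numeric quantity + unit
  pair <- (is_time & toupper(nxt) %in% c("AM", "PM")) |
    (is_qtynum & nxtlo %in% units)
  surface <- toks
  surface[pair] <- paste(toks[pair], nxt[pair])
  consumed <- c(FALSE, pair[-n])
  keep <- !is.na(category) & !consumed
  tibble::tibble(surface = surface[keep], category = category[keep])
}

#' Bundle the pluggable lexical resources for feature extraction
#'
#' @param lexicon A `veristyle_lexicon` (see [read_dic()], [as_lexicon()]).
#' @param concreteness Named numeric vector, lowercase word -> score in
#'   `[1, 5]`.
#' @param stopwords Character vector of lowercase stopwords.
#' @param lemmatizer Function (or named character map) lowercase word ->
#'   lemma.
#' @param recognizer Function text -> tibble(`surface`, `category`).
#' @return A `veristyle_resources` list.
#' @export
style_resources <- function(lexicon, concreteness, stopwords,
                            lemmatizer = default_lemmatizer,
                            recognizer = stub_recognizer) {
  if (is.character(lemmatizer)) {
    map <- lemmatizer
    lemmatizer <- function(words) {
      hit <- words %in% names(map)
      words[hit] <- unname(map[words[hit]])
      words
    }
  }
  missing <- setdiff(required_categories(), names(lexicon))
  if (length(missing)) {
    stop("lexicon is missing required categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(lexicon = compile_lexicon(lexicon), concreteness = concreteness,
         stopwords = tolower(stopwords), lemmatizer = lemmatizer,
         recognizer = recognizer),
    class = "veristyle_resources"
  )
}

#' Fixture resources shipped with the package
#'
#' A small open category lexicon (all 28 required categories), a compact
#' concreteness table and a stopword list, installed under `extdata/`. They
#' make every pipeline stage runnable and testable out of the box; feature
#' values are comparable to analyses run with a full commercial dictionary
#' only when an equivalent dictionary is supplied instead.
#'
#' @return A `veristyle_resources` bundle.
#' @export
fixture_resources <- function() {
  ext <- function(f) system.file("extdata", f, package = "veristyle", mustWork = TRUE)
  style_resources(
    lexicon = read_dic(ext("fixture_lexicon.dic")),
    concreteness = read_concreteness(ext("fixture_concreteness.tsv")),
    stopwords = read_stopwords(ext("fixture_stopwords.txt"))
  )
}
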
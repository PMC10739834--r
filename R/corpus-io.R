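#' Build a validated corpus of labelled statements
#'
#' A corpus is an ordinary tibble with columns `id`, `subject_id`, `domain`,
#' `topic`, `veracity`, `text`, one row per statement, carrying `name` and
#' `provenance` attributes. `as_corpus()` validates a data frame in place;
#' [load_corpus()] reads one from CSV or JSONL with a column mapping.
#'
#' Validation enforces: unique non-missing ids, veracity in
#' `{"truthful", "deceptive"}`, domain in
#' `{"opinion", "memory", "intention", "synthetic"}`, and text containing at
#' least one word token under [tokenize()].
#'
#' @param x A data frame with the canonical columns (`topic`, `subject_id`
#'   and `domain` may be absent; they are filled with defaults).
#' @param name Corpus name.
#' @param provenance Free-text provenance metadata.
#' @param permissive If `TRUE`, invalid rows are dropped and reported in the
#'   `"rejected"` attribute instead of raising an error.
#' @return A `veristyle_corpus` tibble.
#' @export
as_corpus <- function(x, name = "corpus", provenance = "", permissive = FALSE) {
  x <- tibble::as_tibble(x)
  if (!"id" %in% names(x)) x$id <- as.character(seq_len(nrow(x)))
  if (!"subject_id" %in% names(x)) x$subject_id <- x$id
  if (!"domain" %in% names(x)) x$domain <- "synthetic"
  if (!"topic" %in% names(x)) x$topic <- ""
  x$topic <- dplyr::coalesce(as.character(x$topic), "")
  for (col in c("veracity", "text")) {
    if (!col %in% names(x)) {
      stop("corpus is missing required column `", col, "`", call. = FALSE)
    }
  }
  x <- dplyr::select(
    x, "id", "subject_id", "domain", "topic", "veracity", "text",
    dplyr::everything()
  )
  x$id <- as.character(x$id)
  x$subject_id <- as.character(x$subject_id)

  problems <- corpus_row_problems(x)
  if (any(nzchar(problems))) {
    report <- tibble::tibble(
      row = which(nzchar(problems)),
      id = x$id[nzchar(problems)],
      problem = problems[nzchar(problems)]
    )
    if (!permissive) {
      stop(
        "invalid corpus rows:\n",
        paste0("  row ", report$row, " (id ", report$id, "): ",
               report$problem, collapse = "\n"),
        call. = FALSE
      )
    }
    x <- x[!nzchar(problems), , drop = FALSE]
  } else {
    report <- tibble::tibble(row = integer(), id = character(),
                             problem = character())
  }
  if (nrow(x) == 0L) stop("corpus has no valid statements", call. = FALSE)
  if (anyDuplicated(x$id)) {
    stop("duplicate statement ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    x,
    class = c("veristyle_corpus", class(tibble::tibble())),
    name = name, provenance = provenance, rejected = report
  )
}

corpus_row_problems <- function(x) {
  p <- character(nrow(x))
  bad_lab <- !x$veracity %in% c("truthful", "deceptive")
  p[bad_lab] <- paste0("untranslatable veracity label ",
                       encodeString(x$veracity[bad_lab], quote = "'"))
  bad_dom <- !x$domain %in% c("opinion", "memory", "intention", "synthetic")
  p[bad_dom & !nzchar(p)] <- paste0("unknown domain '", x$domain[bad_dom & !nzchar(p)], "'")
  no_text <- is.na(x$text) | count_words(dplyr::coalesce(x$text, "")) == 0L
  p[no_text & !nzchar(p)] <- "text has no word token"
  bad_id <- is.na(x$id) | !nzchar(x$id)
  p[bad_id & !nzchar(p)] <- "missing id"
  p
}

#' Load a labelled statement corpus from CSV or JSONL
#'
#' @param path Path to a CSV (RFC 4180, UTF-8, header row) or JSONL file
#'   (one object per line); format inferred from the extension unless
#'   `format` is given.
#' @param mapping Named list mapping canonical fields to source
#'   columns/keys, e.g. `list(text = "story", veracity = "label",
#'   subject_id = "worker")`. Unmapped canonical fields are taken from
#'   same-named source columns when present.
#' @param labels Named character vector translating source veracity values,
#'   e.g. `c(T = "truthful", D = "deceptive")`. Values already equal to
#'   `"truthful"`/`"deceptive"` pass through.
#' @param domain Domain to assign when the file carries no domain column.
#' @param permissive Drop and report invalid rows instead of erroring.
#' @param row_filter Optional predicate on the raw tibble (rows kept where
#'   it returns `TRUE`); lets callers reconcile archive snapshots that
#'   differ from published totals without editing the file.
#' @inheritParams as_corpus
#' @return A validated `veristyle_corpus`; rejected rows (if any) are in
#'   `attr(corpus, "rejected")`.
#' @export
load_corpus <- function(path, mapping = list(), labels = NULL,
                        domain = "synthetic", name = basename(path),
                        permissive = FALSE, row_filter = NULL,
                        format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
    dplyr::bind_rows(lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      tibble::as_tibble(lapply(rec, as.character))
    }))
  }
  if (nrow(raw) == 0L) stop("empty file: ", path, call. = FALSE)
  if (!is.null(row_filter)) raw <- raw[row_filter(raw), , drop = FALSE]

  canon <- c("id", "subject_id", "domain", "topic", "veracity", "text")
  out <- tibble::tibble(.rows = nrow(raw))
  for (field in canon) {
    src <- if (!is.null(mapping[[field]])) mapping[[field]] else field
    if (!is.null(mapping[[field]]) && !src %in% names(raw)) {
      stop("mapped column `", src, "` (for ", field, ") not in file",
           call. = FALSE)
    }
    if (src %in% names(raw)) out[[field]] <- raw[[src]]
  }
  for (field in c("text", "veracity")) {
    if (!field %in% names(out)) {
      stop("no mapping or column found for required field `", field, "`",
           call. = FALSE)
    }
  }
  if (!"domain" %in% names(out)) out$domain <- domain
  if (!is.null(labels)) {
    known <- out$veracity %in% c(names(labels), "truthful", "deceptive")
    if (!permissive && any(!known, na.rm = TRUE)) {
      stop("untranslatable veracity label in row(s) ",
           paste(which(!known), collapse = ", "), call. = FALSE)
    }
    hit <- out$veracity %in% names(labels)
    out$veracity[hit] <- unname(labels[out$veracity[hit]])
  }
  as_corpus(out, name = name, provenance = paste0("loaded from ", path),
            permissive = permissive)
}

#' Column-mapping profiles for common deposited-corpus layouts
#'
#' Ready-made `mapping`/`labels` arguments for [load_corpus()]:
#' `"hippocorpus"` for the autobiographical-memory layout (worker-keyed
#' rows, a `story` text column, a `memType` label with `recalled` treated
#' as truthful and `imagined` as deceptive — drop `retold` rows first via
#' `row_filter`), and `"osf_intention"` for the stated-intentions layout
#' (an `id` column, `text`, and a `condition` label). Deposited archives
#' occasionally differ from published row totals; discrepancies are
#' reported by the loader, never silently fixed.
#'
#' @param name `"hippocorpus"` or `"osf_intention"`.
#' @return List with `mapping`, `labels` and `domain`, ready to splice
#'   into a [load_corpus()] call.
#' @export
loader_profile <- function(name = c("hippocorpus", "osf_intention")) {
  switch(match.arg(name),
    hippocorpus = list(
      mapping = list(id = "AssignmentId", subject_id = "WorkerId",
                     text = "story", veracity = "memType"),
      labels = c(recalled = "truthful", imagined = "deceptive"),
      domain = "memory"
    ),
    osf_intention = list(
      mapping = list(id = "id", text = "text", veracity = "condition"),
      labels = c(truthful = "truthful", deceptive = "deceptive",
                 T = "truthful", D = "deceptive"),
      domain = "intention"
    )
  )
}

#' Write a corpus back to CSV or JSONL
#'
#' Canonical columns only, in canonical order; round-trips through
#' [load_corpus()] bit-identically.
#'
#' @param corpus A `veristyle_corpus`.
#' @param path Output path; `.jsonl` extension selects JSONL.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  canon <- c("id", "subject_id", "domain", "topic", "veracity", "text")
  x <- tibble::as_tibble(corpus)[, canon]
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      jsonlite::toJSON(as.list(x[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Descriptive word-count summary of a corpus
#'
#' Per-statement word counts (package tokenizer), summarized overall and per
#' veracity group: n, min, max, mean and sample standard deviation, plus the
#' truthful/deceptive vocabulary Jaccard index — the usual first table of a
#' deception-corpus description.
#'
#' @param corpus A `veristyle_corpus` or data frame with `veracity`, `text`.
#' @return A tibble with rows `all`, `truthful`, `deceptive` and columns
#'   `group`, `n`, `min_words`, `max_words`, `mean_words`, `sd_words`,
#'   `jaccard_index` (on the `all` row only). A group with no statements
#'   gets `NA` statistics.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(nrow(corpus) > 0L)
  wc <- count_words(corpus$text)
  groups <- list(all = rep(TRUE, nrow(corpus)),
                 truthful = corpus$veracity == "truthful",
                 deceptive = corpus$veracity == "deceptive")
  out <- purrr::map_dfr(names(groups), function(g) {
    w <- wc[groups[[g]]]
    if (length(w) == 0L) {
      return(tibble::tibble(group = g, n = 0L, min_words = NA_integer_,
                            max_words = NA_integer_, mean_words = NA_real_,
                            sd_words = NA_real_))
    }
    tibble::tibble(
      group = g, n = length(w),
      min_words = min(w), max_words = max(w),
      mean_words = mean(w),
      sd_words = if (length(w) > 1L) stats::sd(w) else NA_real_
    )
  })
  out$jaccard_index <- NA_real_
  if (all(out$n[out$group %in% c("truthful", "deceptive")] > 0L)) {
    out$jaccard_index[out$group == "all"] <- jaccard_vocabulary(corpus)
  }
  out
}

#' Jaccard similarity of truthful vs deceptive vocabularies
#'
#' Builds the set of unique word tokens used by each veracity group
#' (lowercased, punctuation tokens excluded, no lemmatization — the
#' normalization is configurable) and returns
#' intersection size / union size: 0 means disjoint word choices, 1
#' identical vocabularies.
#'
#' @inheritParams corpus_summary
#' @param lowercase Case-fold tokens before building the sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_vocabulary <- function(corpus, lowercase = TRUE) {
  vocab <- function(texts) {
    toks <- unlist(lapply(texts, word_tokens), use.names = FALSE)
    if (lowercase) toks <- tolower(toks)
    unique(toks)
  }
  vt <- vocab(corpus$text[corpus$veracity == "truthful"])
  vd <- vocab(corpus$text[corpus$veracity == "deceptive"])
  if (length(vt) == 0L || length(vd) == 0L) {
    stop("both veracity groups must be non-empty", call. = FALSE)
  }
  length(intersect(vt, vd)) / length(union(vt, vd))
}
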
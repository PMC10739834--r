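#' Seeded k-fold splits with optional subject exclusivity
#'
#' Shuffles statements (or subjects, when grouped) into k near-equal
#' partitions; fold i's test set is partition i and its train set the rest.
#' Grouped splitting guarantees no subject ever contributes to both train
#' and test of the same fold — the precaution that stops a classifier from
#' recognizing an author's style instead of deception. The first
#' `n mod k` folds take one extra unit. Deterministic for a fixed seed, so
#' cached splits can be reused to give different classifiers identical
#' train/test partitions.
#'
#' @param corpus A `veristyle_corpus`.
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @param group_by_subject `TRUE`/`FALSE`, or `NULL` (default) for the
#'   automatic rule: always group opinion-domain corpora; group others
#'   whenever some subject has more than one statement.
#' @return A `veristyle_folds` tibble: `fold` (0-based), `test_ids`,
#'   `train_ids` (list columns of statement ids).
#' @export
make_folds <- function(corpus, k = 10, seed = 1L, group_by_subject = NULL) {
  stopifnot(k >= 2L)
  if (is.null(group_by_subject)) {
    group_by_subject <- any(corpus$domain == "opinion") ||
      anyDuplicated(corpus$subject_id) > 0L
  }
  units <- if (group_by_subject) unique(corpus$subject_id) else corpus$id
  if (length(units) < k) {
    stop("k = ", k, " exceeds the ", length(units), " available ",
         if (group_by_subject) "subjects" else "statements", call. = FALSE)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  shuffled <- sample(units)
  sizes <- rep(length(units) %/% k, k)
  extra <- length(units) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- rep(seq_len(k) - 1L, times = sizes)
  unit_fold <- stats::setNames(assignment, shuffled)
  stmt_fold <- if (group_by_subject) {
    unname(unit_fold[corpus$subject_id])
  } else {
    unname(unit_fold[corpus$id])
  }
  out <- tibble::tibble(fold = seq_len(k) - 1L)
  out$test_ids <- lapply(out$fold, function(f) corpus$id[stmt_fold == f])
  out$train_ids <- lapply(out$fold, function(f) corpus$id[stmt_fold != f])
  structure(out, class = c("veristyle_folds", class(tibble::tibble())),
            seed = seed, grouped = group_by_subject,
            corpus = attr(corpus, "name"))
}

#' Specify one of the three evaluation scenarios
#'
#' S1: k-fold cross-validation within a single corpus. S2: train on the
#' union of two full corpora, test on the held-out third (no folds). S3:
#' fold-wise aggregation — evaluation unit i joins the corpora's fold-i
#' train sets and fold-i test sets, reusing the S1 splits.
#'
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param train_corpora,test_corpora Corpus names (S1: the same single
#'   name; S2: two train names, one disjoint test name; S3: the same set).
#' @param k Folds for S1/S3.
#' @param seed Split seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("S1", "S2", "S3"),
                          train_corpora, test_corpora = train_corpora,
                          k = 10, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "S1" &&
      !(length(train_corpora) == 1L && identical(train_corpora, test_corpora))) {
    stop("S1 trains and tests on one single corpus", call. = FALSE)
  }
  if (scenario == "S2" && any(test_corpora %in% train_corpora)) {
    stop("S2 train and test corpora must be disjoint", call. = FALSE)
  }
  if (scenario == "S3" && !setequal(train_corpora, test_corpora)) {
    stop("S3 aggregates the same corpora on both sides", call. = FALSE)
  }
  structure(list(scenario = scenario, train_corpora = train_corpora,
                 test_corpora = test_corpora, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

corpus_texts <- function(corpus, ids = NULL) {
  x <- tibble::as_tibble(corpus)[, c("id", "subject_id", "text", "veracity")]
  if (!is.null(ids)) x <- x[match(ids, x$id), , drop = FALSE]
  x
}

#' Build the train/test evaluation units of a scenario
#'
#' @param spec A [scenario_spec()].
#' @param corpora Named list of `veristyle_corpus` objects.
#' @param folds Optional named list of cached [make_folds()] results (one
#'   per corpus); computed from `spec$seed` when absent, so passing the
#'   same cache to several classifiers guarantees identical splits.
#' @return A `veristyle_scenario`: list of units, each
#'   `list(fold, train, test)` with `train`/`test` tibbles of
#'   `id, subject_id, text, veracity`.
#' @export
build_scenario <- function(spec, corpora, folds = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  need <- union(spec$train_corpora, spec$test_corpora)
  missing <- setdiff(need, names(corpora))
  if (length(missing)) {
    stop("unknown corpora: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- if (spec$scenario == "S2") {
    train <- dplyr::bind_rows(lapply(corpora[spec$train_corpora], corpus_texts))
    test <- dplyr::bind_rows(lapply(corpora[spec$test_corpora], corpus_texts))
    if (length(intersect(train$id, test$id)) > 0L) {
      stop("S2 train and test corpora share statement ids", call. = FALSE)
    }
    list(list(fold = 0L, train = train, test = test))
  } else {
    members <- spec$train_corpora
    if (is.null(folds)) {
      folds <- lapply(corpora[members], make_folds, k = spec$k, seed = spec$seed)
    }
    lapply(seq_len(spec$k) - 1L, function(f) {
      train <- dplyr::bind_rows(lapply(members, function(nm) {
        corpus_texts(corpora[[nm]], folds[[nm]]$train_ids[[f + 1L]])
      }))
      test <- dplyr::bind_rows(lapply(members, function(nm) {
        corpus_texts(corpora[[nm]], folds[[nm]]$test_ids[[f + 1L]])
      }))
      list(fold = f, train = train, test = test)
    })
  }
  structure(list(spec = spec, units = units), class = "veristyle_scenario")
}

#' Classifier adapter contract
#'
#' The harness treats every classifier through the same two functions:
#' `fit(train)` receives a tibble with `text` and `veracity` and returns a
#' model object; `predict(model, texts)` returns one character label per
#' text. Returned strings are parsed case-insensitively (surrounding
#' punctuation stripped) to `truthful`/`deceptive`; anything unparseable is
#' scored as incorrect and tallied, never re-prompted, so text-to-text
#' models that answer with the training label strings plug in directly.
#'
#' @param fit Function `train_tibble -> model`.
#' @param predict Function `(model, character vector) -> character vector`.
#' @param name Adapter name used in logs.
#' @return A `veristyle_adapter`.
#' @export
classifier_adapter <- function(fit, predict, name = "adapter") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, name = name),
            class = "veristyle_adapter")
}

parse_predictions <- function(raw) {
  norm <- tolower(gsub("^[^a-zA-Z]+|[^a-zA-Z]+$", "", trimws(raw)))
  out <- rep(NA_character_, length(raw))
  out[norm == "truthful"] <- "truthful"
  out[norm == "deceptive"] <- "deceptive"
  out
}

#' Built-in adapters
#'
#' `adapter_bow_logreg()`: unigram bag-of-words counts over a vocabulary
#' built from the training texts only, L2-regularized logistic regression
#' (ridge `glmnet` at a fixed lambda); out-of-vocabulary tokens at predict
#' time are ignored. `adapter_dummy()` always answers one label.
#' `adapter_random()` answers uniformly at random (seeded) — the null
#' classifier used to calibrate the explainability analysis.
#' `adapter_lookup()` echoes the true label of any statement of `corpus`
#' (matched by id) — a perfect classifier for harness checks.
#'
#' @param max_features Vocabulary size cap (most frequent train tokens).
#' @param lambda Ridge penalty.
#' @param min_count Minimum train frequency for a vocabulary token.
#' @return A `veristyle_adapter`.
#' @export
adapter_bow_logreg <- function(max_features = 5000, lambda = 0.01,
                               min_count = 1L) {
  fit <- function(train) {
    y <- factor(train$veracity, levels = c("deceptive", "truthful"))
    if (length(unique(train$veracity)) < 2L) {
      stop("training set contains a single class", call. = FALSE)
    }
    toks <- lapply(train$text, function(t) tolower(word_tokens(t)))
    tf <- table(unlist(toks, use.names = FALSE))
    tf <- tf[tf >= min_count]
    vocab <- names(sort(tf, decreasing = TRUE))
    vocab <- utils::head(vocab, max_features)
    X <- dtm(toks, vocab)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    list(vocab = vocab, fit = fit, lambda = lambda)
  }
  predict_fn <- function(model, texts) {
    toks <- lapply(texts, function(t) tolower(word_tokens(t)))
    X <- dtm(toks, model$vocab)
    as.character(stats::predict(model$fit, newx = X, s = model$lambda,
                                type = "class"))
  }
  classifier_adapter(fit, predict_fn, name = "bow-logreg")
}

# sparse document-term count matrix over a fixed vocabulary
dtm <- function(token_lists, vocab) {
  idx <- lapply(token_lists, function(tk) {
    j <- match(tk, vocab)
    j[!is.na(j)]
  })
  i <- rep(seq_along(idx), lengths(idx))
  X <- Matrix::sparseMatrix(
    i = i, j = unlist(idx, use.names = FALSE), x = 1,
    dims = c(length(token_lists), max(length(vocab), 2L))
  )
  X
}

#' @rdname adapter_bow_logreg
#' @param answer Constant label the dummy adapter returns.
#' @export
adapter_dummy <- function(answer = "truthful") {
  classifier_adapter(
    fit = function(train) NULL,
    predict = function(model, texts) rep(answer, length(texts)),
    name = paste0("dummy-", answer)
  )
}

#' @rdname adapter_bow_logreg
#' @param seed Seed of the random-label stream.
#' @export
adapter_random <- function(seed = 1L) {
  counter <- new.env()
  counter$calls <- 0L
  classifier_adapter(
    fit = function(train) NULL,
    predict = function(model, texts) {
      counter$calls <- counter$calls + 1L
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed((seed + counter$calls * 7919L) %% 2147483629L)
      sample(c("truthful", "deceptive"), length(texts), replace = TRUE)
    },
    name = "random"
  )
}

#' @rdname adapter_bow_logreg
#' @param corpus Corpus whose true labels the lookup adapter echoes.
#' @export
adapter_lookup <- function(corpus) {
  key <- stats::setNames(corpus$veracity, corpus$text)
  classifier_adapter(
    fit = function(train) NULL,
    predict = function(model, texts) unname(key[texts]),
    name = "lookup"
  )
}

#' Run a built scenario through an adapter
#'
#' Per evaluation unit: fit on the train split, predict the test split,
#' parse and score the predicted labels. Accuracy is reported per fold with
#' its mean and sample sd across folds, and the 2x2 confusion matrix
#' (positive class = truthful: rows true truthful/deceptive, columns
#' predicted truthful/deceptive) is averaged elementwise across folds.
#'
#' @param scenario A `veristyle_scenario` from [build_scenario()].
#' @param adapter A `veristyle_adapter`.
#' @return A `veristyle_run`: list with `predictions` (tibble
#'   `statement_id, fold, true, predicted`; unparseable predictions are
#'   `NA`), `fold_accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `confusion_mean`, `confusion_sd`, `n_unparseable`.
#' @export
run_cv <- function(scenario, adapter) {
  stopifnot(inherits(scenario, "veristyle_scenario"),
            inherits(adapter, "veristyle_adapter"))
  preds <- list(); conf <- list(); acc <- numeric(0); unparse <- 0L
  for (unit in scenario$units) {
    res <- tryCatch({
      model <- adapter$fit(unit$train)
      raw <- adapter$predict(model, unit$test$text)
      if (length(raw) != nrow(unit$test)) {
        stop("adapter returned ", length(raw), " predictions for ",
             nrow(unit$test), " texts")
      }
      raw
    }, error = function(e) {
      stop("adapter `", adapter$name, "` failed in fold ", unit$fold, ": ",
           conditionMessage(e), call. = FALSE)
    })
    parsed <- parse_predictions(res)
    unparse <- unparse + sum(is.na(parsed))
    correct <- !is.na(parsed) & parsed == unit$test$veracity
    acc <- c(acc, mean(correct))
    # unparseable outputs are scored as the incorrect cell
    eff_pred <- ifelse(is.na(parsed),
                       ifelse(unit$test$veracity == "truthful",
                              "deceptive", "truthful"),
                       parsed)
    cm <- matrix(c(
      sum(unit$test$veracity == "truthful" & eff_pred == "truthful"),
      sum(unit$test$veracity == "truthful" & eff_pred == "deceptive"),
      sum(unit$test$veracity == "deceptive" & eff_pred == "truthful"),
      sum(unit$test$veracity == "deceptive" & eff_pred == "deceptive")
    ), nrow = 2, byrow = TRUE,
    dimnames = list(true = c("truthful", "deceptive"),
                    predicted = c("truthful", "deceptive")))
    conf[[length(conf) + 1L]] <- cm
    preds[[length(preds) + 1L]] <- tibble::tibble(
      statement_id = unit$test$id, fold = unit$fold,
      true = unit$test$veracity, predicted = parsed
    )
  }
  conf_arr <- simplify2array(conf)
  structure(list(
    scenario = scenario$spec$scenario,
    adapter = adapter$name,
    predictions = dplyr::bind_rows(preds),
    fold_accuracy = acc,
    mean_accuracy = mean(acc),
    sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else NA_real_,
    confusion_mean = apply(conf_arr, c(1, 2), mean),
    confusion_sd = apply(conf_arr, c(1, 2), stats::sd),
    n_unparseable = unparse
  ), class = "veristyle_run")
}

#' Write a run's predictions and summary to disk
#'
#' `predictions.csv` holds one row per tested statement
#' (`statement_id, fold, true, predicted`); `summary.json` holds the
#' per-fold accuracies, their mean and sd, the averaged confusion matrix
#' and the unparseable-output tally.
#'
#' @param run A `veristyle_run`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "veristyle_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$predictions, file.path(dir, "predictions.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(scenario = run$scenario, adapter = run$adapter,
         fold_accuracy = run$fold_accuracy,
         mean_accuracy = run$mean_accuracy, sd_accuracy = run$sd_accuracy,
         confusion_mean = run$confusion_mean, confusion_sd = run$confusion_sd,
         n_unparseable = run$n_unparseable),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.veristyle_run <- function(x, ...) {
  cat("<veristyle_run> ", x$scenario, " / ", x$adapter, "\n", sep = "")
  cat(sprintf("  accuracy: %.3f (sd %.3f) over %d fold(s)\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracy)))
  if (x$n_unparseable > 0L) {
    cat("  unparseable predictions:", x$n_unparseable, "\n")
  }
  cat("  mean confusion (rows = true, cols = predicted; positive = truthful):\n")
  print(round(x$confusion_mean, 2))
  invisible(x)
}
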
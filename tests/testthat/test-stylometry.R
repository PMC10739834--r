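res <- fixture_resources()

test_that("lexicon percentages follow hand counts and wildcard semantics", {
  lex <- as_lexicon(list(i = c("i", "me", "my"), run = "run*"))
  pct <- score_lexicon(c("i", "lost", "my", "keys", "yesterday"), lex)
  expect_equal(unname(pct["i"]), 40.0)       # 2 of 5 tokens
  expect_equal(unname(pct["run"]), 0.0)      # empty match
  pct2 <- score_lexicon(c("running", "ran"), lex)
  expect_equal(unname(pct2["run"]), 50.0)    # prefix matches "running" only
  # matching is case-insensitive
  expect_equal(unname(score_lexicon(c("I", "ME"), lex)["i"]), 100.0)
  expect_error(score_lexicon(character(0), lex), "empty")
})

test_that("a category covering every token scores exactly 100", {
  lex <- as_lexicon(list(all = c("a", "b", "c")))
  expect_equal(unname(score_lexicon(c("a", "b", "c", "a"), lex)["all"]), 100.0)
})

test_that("concreteness pipeline lowercases, drops stopwords, excludes misses", {
  tab <- c(apple = 5.0, idea = 1.5)
  out <- concreteness_score("An apple idea!", tab, stopwords = "an")
  expect_equal(out$score, 3.25)
  expect_equal(out$n_matched, 2L)
  expect_equal(concreteness_score("APPLE apple", c(apple = 5.0), character(0))$score, 5.0)
  miss <- concreteness_score("zz qq ww", tab, character(0))
  expect_true(is.na(miss$score))
  expect_equal(miss$n_matched, 0L)
  # lemmatizer reaches inflected forms
  expect_equal(concreteness_score("many apples", c(apple = 5.0), character(0))$score, 5.0)
})

test_that("entity counts are unique per category under normalization", {
  rec1 <- function(text) tibble::tibble(
    surface = c("Mary", "mary", "Tokyo"),
    category = c("People", "People", "Spatial")
  )
  out <- entity_counts("ignored", rec1)
  expect_equal(unname(out["People"]), 1L)
  expect_equal(unname(out["Spatial_details"]), 1L)
  expect_equal(unname(out["Quantity_details"]), 0L)

  rec0 <- function(text) tibble::tibble(surface = character(), category = character())
  expect_equal(sum(entity_counts("x", rec0)), 0L)

  # the printed quantity exemplars are three distinct entities
  recq <- function(text) tibble::tibble(
    surface = c("20%", "5 $", "ten"), category = rep("Quantity", 3)
  )
  expect_equal(unname(entity_counts("x", recq)["Quantity_details"]), 3L)

  # model-style labels map onto the four verifiability categories
  recm <- function(text) tibble::tibble(
    surface = c("Paris", "Monday", "3", "Anna", "whatever"),
    category = c("GPE", "DATE", "CARDINAL", "PERSON", "UNKNOWN_LABEL")
  )
  out <- entity_counts("x", recm)
  expect_equal(unname(out), c(1L, 1L, 1L, 1L))
})

test_that("composites follow their defining sums and the Tone transform", {
  cats <- stats::setNames(rep(0, length(veristyle:::required_categories())),
                          veristyle:::required_categories())
  cats["i"] <- 40
  comp <- composite_features(cats)
  expect_equal(unname(comp["Self_reference"]), 40)

  cats2 <- cats
  cats2[c("attention", "visual")] <- c(6, 4)   # perceptual parts sum 10
  cats2[c("space", "motion")] <- c(3, 2)       # contextual parts sum 5
  cats2["Affect"] <- 2
  cats2["Cognition"] <- 3
  comp2 <- composite_features(cats2)
  expect_equal(unname(comp2["Reality_Monitoring"]), 10 + 5 + 2 - 3)

  cats3 <- cats
  cats3["tone_pos"] <- 4; cats3["tone_neg"] <- 2
  expect_equal(unname(composite_features(cats3)["Tone"]), 66.67, tolerance = 1e-3)
  cats3["tone_neg"] <- 4
  expect_equal(unname(composite_features(cats3)["Tone"]), 50)
  expect_equal(unname(composite_features(cats)["Tone"]), 50)  # both zero

  expect_error(composite_features(cats[-1]), "missing")
})

test_that("style vectors have 26 features satisfying their invariants", {
  txt <- "I went to Tokyo yesterday. We saw Mary at 2:30 PM and it was good."
  sv <- extract_style_vector(txt, res)
  expect_equal(ncol(sv), 26L)
  expect_named(sv, style_features())
  expect_equal(sv$avg_syllabes_per_word, sv$num_syllables / sv$num_words)
  pct_cols <- c("tone_pos", "tone_neg", "Cognition", "memory", "focuspast",
                "focuspresent", "focusfuture", "Self_reference",
                "Other_reference", "Perceptual_details", "Contextual_Embedding",
                "Analytic", "Authentic", "Tone")
  expect_true(all(unlist(sv[pct_cols]) >= 0 & unlist(sv[pct_cols]) <= 100))
  # determinism
  expect_identical(sv, extract_style_vector(txt, res))
})

test_that("Reality Monitoring equals its four parts on extracted vectors", {
  corp <- generate_corpus(synthetic_config(domains = "intention",
                                           n_subjects = c(intention = 20),
                                           seed = 9))$corpus
  feats <- extract_features(corp, res)
  words <- lapply(corp$text, word_tokens)
  for (i in seq_len(nrow(feats))) {
    cats <- score_lexicon(words[[i]], res$lexicon)
    expect_equal(feats$Reality_Monitoring[i],
                 feats$Perceptual_details[i] + feats$Contextual_Embedding[i] +
                   unname(cats["Affect"]) - unname(cats["Cognition"]))
  }
})

test_that("bag-of-words features are order-invariant", {
  txt <- "I saw Mary near the bright airport yesterday and we were happy"
  toks <- word_tokens(txt)
  perm <- paste(toks[c(5:12, 1:4)], collapse = " ")
  sv1 <- extract_style_vector(txt, res)
  sv2 <- extract_style_vector(perm, res)
  sentence_dependent <- c("num_sentences", "fk_grade", "fk_read")
  for (f in setdiff(style_features(), sentence_dependent)) {
    expect_equal(sv1[[f]], sv2[[f]], info = f)
  }
})

test_that("extraction agrees with a naive brute-force category counter", {
  corp <- generate_corpus(synthetic_config(domains = "memory",
                                           n_subjects = c(memory = 12),
                                           seed = 31))$corpus
  lex_raw <- read_dic(system.file("extdata", "fixture_lexicon.dic",
                                  package = "veristyle"))
  feats <- extract_features(corp, res)
  for (i in seq_len(nrow(corp))) {
    brute <- brute_category_pct(word_tokens(corp$text[i]), lex_raw)
    expect_equal(feats$Self_reference[i],
                 unname(brute["i"] + brute["we"]), tolerance = 1e-10)
    expect_equal(feats$Other_reference[i],
                 unname(brute["shehe"] + brute["they"] + brute["you"]))
    expect_equal(feats$Cognition[i], unname(brute["Cognition"]))
    expect_equal(feats$Contextual_Embedding[i],
                 unname(brute["space"] + brute["motion"] + brute["time"]))
  }
})

test_that("degenerate statements keep defined fields and flag the rest", {
  sv <- extract_style_vector("Borlit dantor meskin tralvo quendel sarnip.", res)
  expect_true(is.na(sv$Concreteness_score))
  expect_equal(sv$People + sv$Temporal_details + sv$Spatial_details +
                 sv$Quantity_details, 0L)
  expect_false(anyNA(sv[setdiff(style_features(), "Concreteness_score")]))
})

test_that("the .dic reader parses categories, stems and multi-membership", {
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\talpha", "2\tbeta", "%",
               "dog\t1", "run*\t1\t2", "cat\t2"), path)
  lex <- read_dic(path)
  expect_setequal(names(lex), c("alpha", "beta"))
  expect_setequal(lex$alpha, c("dog", "run*"))
  expect_setequal(lex$beta, c("run*", "cat"))
  pct <- score_lexicon(c("running", "dog", "x", "y"), lex)
  expect_equal(unname(pct["alpha"]), 50)
  expect_equal(unname(pct["beta"]), 25)
})
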
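test_that("ungrouped folds partition the corpus into near-equal test sets", {
  corp <- toy_corpus(100)
  folds <- make_folds(corp, k = 10, seed = 3, group_by_subject = FALSE)
  test_sets <- folds$test_ids
  expect_equal(sort(unlist(test_sets)), sort(corp$id))
  expect_true(all(lengths(test_sets) == 10L))
  for (i in seq_len(10)) {
    expect_length(intersect(folds$test_ids[[i]], folds$train_ids[[i]]), 0L)
    expect_setequal(c(folds$test_ids[[i]], folds$train_ids[[i]]), corp$id)
  }
})

test_that("grouped folds keep every subject's statements in one fold", {
  g <- generate_corpus(synthetic_config(domains = "opinion",
                                        n_subjects = c(opinion = 50),
                                        seed = 2))
  folds <- make_folds(g$corpus, k = 10, seed = 7)
  expect_true(attr(folds, "grouped"))
  for (i in seq_len(10)) {
    test_subjects <- g$corpus$subject_id[g$corpus$id %in% folds$test_ids[[i]]]
    train_subjects <- g$corpus$subject_id[g$corpus$id %in% folds$train_ids[[i]]]
    expect_length(intersect(test_subjects, train_subjects), 0L)
    # each subject's five opinions travel together
    expect_true(all(table(test_subjects) == 5L))
  }
})

test_that("folds are deterministic and respect the remainder rule", {
  corp <- toy_corpus(23)
  f1 <- make_folds(corp, k = 4, seed = 11, group_by_subject = FALSE)
  f2 <- make_folds(corp, k = 4, seed = 11, group_by_subject = FALSE)
  expect_identical(f1, f2)
  expect_equal(lengths(f1$test_ids), c(6L, 6L, 6L, 5L))  # first n mod k get extra
  expect_error(make_folds(toy_corpus(3), k = 5, group_by_subject = FALSE),
               "exceeds")
})

test_that("scenario builders produce the documented train/test structure", {
  mk <- function(dom, n, seed) generate_corpus(synthetic_config(
    domains = dom, n_subjects = stats::setNames(n, dom), seed = seed))$corpus
  corp <- list(opinion = mk("opinion", 12, 1), memory = mk("memory", 40, 2),
               intention = mk("intention", 40, 3))

  s1 <- build_scenario(scenario_spec("S1", "memory", k = 5, seed = 4), corp)
  expect_length(s1$units, 5L)
  expect_equal(sort(unlist(lapply(s1$units, function(u) u$test$id))),
               sort(corp$memory$id))

  s2 <- build_scenario(scenario_spec("S2", c("opinion", "memory"),
                                     "intention", seed = 4), corp)
  expect_length(s2$units, 1L)
  expect_equal(nrow(s2$units[[1]]$train), nrow(corp$opinion) + nrow(corp$memory))
  expect_equal(nrow(s2$units[[1]]$test), nrow(corp$intention))
  expect_length(intersect(s2$units[[1]]$train$id, s2$units[[1]]$test$id), 0L)
  expect_error(scenario_spec("S2", c("opinion", "memory"), "memory"), "disjoint")

  folds <- lapply(corp, make_folds, k = 5, seed = 4)
  s3 <- build_scenario(scenario_spec("S3", names(corp), k = 5, seed = 4),
                       corp, folds = folds)
  expect_length(s3$units, 5L)
  u0 <- s3$units[[1]]
  expect_setequal(u0$test$id, c(folds$opinion$test_ids[[1]],
                                folds$memory$test_ids[[1]],
                                folds$intention$test_ids[[1]]))
})

test_that("no unit in any scenario leaks ids or subjects from train to test", {
  mk <- function(dom, n, seed) generate_corpus(synthetic_config(
    domains = dom, n_subjects = stats::setNames(n, dom), seed = seed))$corpus
  corp <- list(opinion = mk("opinion", 12, 5), memory = mk("memory", 30, 6),
               intention = mk("intention", 30, 7))
  folds <- lapply(corp, make_folds, k = 5, seed = 8)
  scens <- list(
    build_scenario(scenario_spec("S1", "opinion", k = 5, seed = 8), corp,
                   folds = folds["opinion"]),
    build_scenario(scenario_spec("S2", c("memory", "intention"), "opinion"), corp),
    build_scenario(scenario_spec("S3", names(corp), k = 5, seed = 8), corp,
                   folds = folds)
  )
  for (sc in scens) {
    for (u in sc$units) {
      expect_length(intersect(u$train$id, u$test$id), 0L)
    }
  }
  # opinion subjects never straddle an S1 unit
  for (u in scens[[1]]$units) {
    expect_length(intersect(u$train$subject_id, u$test$subject_id), 0L)
  }
})

test_that("the BoW baseline separates a marker-word construction", {
  g <- generate_corpus(synthetic_config(domains = "memory",
                                        n_subjects = c(memory = 120),
                                        marker_rate = 1, seed = 13))
  sc <- build_scenario(scenario_spec("S1", "memory", k = 5, seed = 1),
                       list(memory = g$corpus))
  run <- run_cv(sc, adapter_bow_logreg())
  expect_gte(run$mean_accuracy, 0.95)
})

test_that("the BoW baseline sits at chance once labels are shuffled", {
  g <- generate_corpus(synthetic_config(domains = "memory",
                                        n_subjects = c(memory = 120),
                                        marker_rate = 1, seed = 14))
  shuffled <- tibble::as_tibble(g$corpus)
  set.seed(1)
  shuffled$veracity <- sample(shuffled$veracity)
  sc <- build_scenario(scenario_spec("S1", "memory", k = 5, seed = 2),
                       list(memory = as_corpus(shuffled)))
  run <- run_cv(sc, adapter_bow_logreg())
  expect_lt(abs(run$mean_accuracy - 0.5), chance_band(nrow(shuffled)) + 0.05)
})

test_that("prediction on fully out-of-vocabulary text yields a valid label", {
  train <- tibble::tibble(
    text = c("aaa bbb", "aaa ccc", "ddd eee", "ddd fff"),
    veracity = c("truthful", "truthful", "deceptive", "deceptive")
  )
  ad <- adapter_bow_logreg()
  model <- suppressWarnings(ad$fit(train))  # glmnet small-n note
  out <- ad$predict(model, "zzz qqq unseen words")
  expect_true(out %in% c("truthful", "deceptive"))
  expect_error(ad$fit(train[1:2, ]), "single class")
})

test_that("adapter outputs are parsed case-insensitively, rest scored wrong", {
  g <- generate_corpus(synthetic_config(domains = "memory",
                                        n_subjects = c(memory = 20), seed = 3))
  sc <- build_scenario(scenario_spec("S1", "memory", k = 2, seed = 1),
                       list(memory = g$corpus))
  shouty <- classifier_adapter(
    fit = function(train) NULL,
    predict = function(model, texts) rep("TRUTHFUL.", length(texts)),
    name = "shouty"
  )
  run <- run_cv(sc, shouty)
  truthful_frac <- mean(g$corpus$veracity == "truthful")
  expect_equal(mean(run$predictions$predicted == "truthful"), 1.0)
  expect_equal(run$mean_accuracy, truthful_frac, tolerance = 0.11)

  vague <- classifier_adapter(
    fit = function(train) NULL,
    predict = function(model, texts) rep("maybe", length(texts)),
    name = "vague"
  )
  run2 <- run_cv(sc, vague)
  expect_equal(run2$mean_accuracy, 0)
  expect_equal(run2$n_unparseable, nrow(g$corpus))
  expect_true(all(is.na(run2$predictions$predicted)))
})

test_that("run summaries average accuracies and confusion matrices per fold", {
  g <- generate_corpus(synthetic_config(domains = "intention",
                                        n_subjects = c(intention = 40), seed = 4))
  sc <- build_scenario(scenario_spec("S1", "intention", k = 4, seed = 1),
                       list(intention = g$corpus))
  perfect <- run_cv(sc, adapter_lookup(g$corpus))
  expect_equal(perfect$mean_accuracy, 1.0)
  expect_equal(perfect$sd_accuracy, 0.0)
  expect_equal(sum(perfect$confusion_mean[1, 2], perfect$confusion_mean[2, 1]), 0)

  dummy <- run_cv(sc, adapter_dummy("truthful"))
  expect_equal(dummy$mean_accuracy,
               mean(dummy$predictions$true == "truthful"), tolerance = 1e-9)
  # per-fold confusion rows sum to the fold test size
  expect_equal(sum(dummy$confusion_mean), nrow(g$corpus) / 4)
  # accuracy identity for equal-sized folds
  expect_equal(perfect$mean_accuracy,
               with(perfect$predictions, mean(predicted == true)))
})

test_that("identical seeds reproduce identical prediction records", {
  g <- generate_corpus(synthetic_config(domains = "memory",
                                        n_subjects = c(memory = 60),
                                        marker_rate = 0.8, seed = 6))
  mkrun <- function() {
    sc <- build_scenario(scenario_spec("S1", "memory", k = 5, seed = 3),
                         list(memory = g$corpus))
    run_cv(sc, adapter_bow_logreg())
  }
  expect_identical(mkrun()$predictions, mkrun()$predictions)
})

test_that("runs and feature matrices round-trip through their writers", {
  g <- generate_corpus(synthetic_config(domains = "memory",
                                        n_subjects = c(memory = 20), seed = 15))
  sc <- build_scenario(scenario_spec("S1", "memory", k = 2, seed = 1),
                       list(memory = g$corpus))
  run <- run_cv(sc, adapter_dummy("deceptive"))
  dir <- withr::local_tempdir()
  write_run(run, dir)
  back <- readr::read_csv(file.path(dir, "predictions.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(run$predictions))
  summ <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(summ$mean_accuracy, run$mean_accuracy)
  expect_equal(summ$n_unparseable, 0L)

  feats <- extract_features(g$corpus)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  feats2 <- read_features(path)
  expect_equal(as.data.frame(feats2), as.data.frame(feats))
})
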
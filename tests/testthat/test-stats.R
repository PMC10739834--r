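test_that("independent permutation test matches hand and degenerate cases", {
  expect_equal(perm_test_independent(c(5, 5, 5), c(5, 5, 5), 999, seed = 1), 1.0)
  # complete separation: exact p is 2 / C(10,5) ~ 0.0079
  p <- perm_test_independent(rep(0, 5), rep(10, 5), 10000, seed = 2)
  expect_lte(p, 0.01)
  expect_error(perm_test_independent(1, c(1, 2), 100), "length")
})

test_that("Monte-Carlo p agrees with full enumeration for small groups", {
  set.seed(77)
  cases <- list(
    list(x = rnorm(3), y = rnorm(3)),
    list(x = rnorm(4), y = rnorm(4)),
    list(x = rnorm(2), y = rnorm(5)),
    list(x = c(0, 0, 0, 0, 0), y = c(10, 10, 10, 10, 10)),
    list(x = rnorm(5), y = rnorm(5) + 1)
  )
  B <- 10000
  for (cs in cases) {
    p_exact <- enum_perm_p(cs$x, cs$y)
    p_mc <- perm_test_independent(cs$x, cs$y, B, seed = 11)
    se <- sqrt(p_exact * (1 - p_exact) / B) + 1 / B
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-9)
  }
})

test_that("paired sign-flip test matches its enumeration oracle", {
  expect_equal(perm_test_paired(c(1, 2, 3), c(1, 2, 3), 999, seed = 1), 1.0)
  # constant differences: exact two-sided p is 2 / 2^8
  p <- perm_test_paired(rep(3, 8), rep(0, 8), 10000, seed = 5)
  p_exact <- enum_sign_p(rep(3, 8))
  expect_equal(p_exact, 2 / 256)
  expect_lt(abs(p - p_exact), 3 * (sqrt(p_exact * (1 - p_exact) / 10000) + 1e-4))

  set.seed(42)
  for (n in c(5, 8, 10)) {
    d <- rnorm(n, 0.5)
    p_exact <- enum_sign_p(d)
    p_mc <- perm_test_paired(d + 1, rep(1, n), 10000, seed = 3)
    se <- sqrt(p_exact * (1 - p_exact) / 10000) + 1e-4
    expect_lt(abs(p_mc - p_exact), 3 * se)
  }
  expect_error(perm_test_paired(1:3, 1:2), "length")
})

test_that("permutation tests are reproducible under a fixed seed", {
  x <- rnorm(10); y <- rnorm(12)
  expect_identical(perm_test_independent(x, y, 500, seed = 9),
                   perm_test_independent(x, y, 500, seed = 9))
  expect_identical(perm_test_paired(x[1:10], y[1:10], 500, seed = 9),
                   perm_test_paired(x[1:10], y[1:10], 500, seed = 9))
})

test_that("Holm adjustment matches the hand-worked step-down and its oracle", {
  expect_equal(holm_adjust(c(0.001, 0.2, 0.03)), c(0.003, 0.2, 0.06))
  expect_equal(holm_adjust(c(1.0, 1.0)), c(1.0, 1.0))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  set.seed(3)
  for (rep in 1:25) {
    p <- stats::runif(sample(3:12, 1))^sample(1:3, 1)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    alpha <- 0.05
    expect_equal(adj < alpha, holm_reject_oracle(p, alpha))
    # Holm rejects everything Bonferroni rejects
    bonf <- pmin(p * length(p), 1)
    expect_true(all(adj <= bonf + 1e-12))
  }
})

test_that("CLES follows its defining count, ties weighted one half", {
  expect_equal(cles(c(1, 2, 3), c(1, 2, 3), n_boot = 0)$cles, 0.5)
  expect_equal(cles(c(2, 3), c(0, 1), n_boot = 0)$cles, 1.0)
  expect_equal(cles(c(0, 1), c(2, 3), n_boot = 0)$cles, 0.0)
  # enumeration: 3 strict wins + 1.5 tie credit over 9 pairs
  expect_equal(cles(c(1, 2, 3), c(1, 2, 3), n_boot = 0)$cles, (3 + 1.5) / 9)
  # complementarity with and without ties
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(1:5, 7, replace = TRUE); y <- sample(1:5, 9, replace = TRUE)
    expect_equal(cles(x, y, n_boot = 0)$cles + cles(y, x, n_boot = 0)$cles, 1.0)
  }
  ci <- cles(rnorm(20), rnorm(20), n_boot = 500, seed = 4)
  expect_true(ci$lo <= ci$cles && ci$cles <= ci$hi)
})

test_that("Cohen's d uses the pooled sd and mirrors under swap", {
  d <- cohens_d(c(2, 4), c(0, 2))
  expect_equal(d$d, 2 / sqrt(2), tolerance = 1e-6)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  a <- rnorm(15); b <- rnorm(15, 1)
  d1 <- cohens_d(a, b); d2 <- cohens_d(b, a)
  expect_equal(d1$d, -d2$d)
  expect_equal(d1$lo, -d2$hi)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))$d))
})

test_that("subject averaging pairs truthful and deceptive means per subject", {
  feats <- tibble::tibble(
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    veracity = c("truthful", "truthful", "deceptive",
                 "truthful", "deceptive", "truthful"),
    num_words = c(2, 4, 1, 10, 20, 5)
  )
  expect_warning(avg <- subject_average(feats, "num_words"), "s3")
  s1 <- avg[avg$subject_id == "s1", ]
  expect_equal(s1$num_words[s1$veracity == "truthful"], 3)
  expect_equal(s1$num_words[s1$veracity == "deceptive"], 1)
  expect_equal(nrow(avg), 4L)  # two subjects x two veracities

  # a feature undefined in all of one side drops that subject's pair only
  feats$extra <- c(NA, NA, 1, 2, 3, 4)
  expect_warning(avg2 <- subject_average(feats, c("num_words", "extra")))
  expect_true(is.na(avg2$extra[avg2$subject_id == "s1" &
                                 avg2$veracity == "truthful"]))
})

test_that("compare_groups is deterministic and flags constant features", {
  set.seed(10)
  feats <- tibble::tibble(
    veracity = rep(c("truthful", "deceptive"), each = 15),
    num_words = c(rnorm(15, 12), rnorm(15, 10)),
    Tone = rep(50, 30)
  )
  cfg <- analysis_config(n_permutations = 499, n_boot = 100, seed = 2)
  r1 <- compare_groups(feats, "independent", cfg,
                       feature_cols = c("num_words", "Tone"))
  r2 <- compare_groups(feats, "independent", cfg,
                       feature_cols = c("num_words", "Tone"))
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  tone <- r1[r1$feature == "Tone", ]
  expect_equal(tone$p_raw, 1.0)
  expect_equal(tone$cles, 0.5)
  expect_equal(tone$d, 0)
  expect_equal(tone$direction, "none")
  expect_true(all(r1$p_holm >= r1$p_raw))
  expect_equal(r1$significant, r1$p_holm < 0.05)
  # direction tracks the sign of the mean difference
  nw <- r1[r1$feature == "num_words", ]
  expect_equal(nw$direction,
               if (nw$mean_diff > 0) "higher_in_truthful" else "higher_in_deceptive")
})

test_that("paired design tests subject-averaged differences", {
  set.seed(21)
  n_sub <- 20
  feats <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", seq_len(n_sub)), each = 4),
    veracity = rep(c("truthful", "truthful", "deceptive", "deceptive"), n_sub),
    num_words = rnorm(4 * n_sub, 10) +
      rep(c(3, 3, 0, 0), n_sub)   # planted within-subject shift
  )
  cfg <- analysis_config(n_permutations = 999, n_boot = 0, seed = 5)
  out <- compare_groups(feats, "paired_by_subject", cfg,
                        feature_cols = "num_words")
  expect_equal(out$n1, n_sub)
  expect_lt(out$p_raw, 0.01)
  expect_equal(out$direction, "higher_in_truthful")
})

test_that("paired design stays null on opinion-like corpora with no effect", {
  runs_with_rejection <- 0
  for (r in 1:20) {
    g <- generate_corpus(synthetic_config(
      domains = "opinion", n_subjects = c(opinion = 40),
      length_mean = 24, length_sd = 6, seed = 90000 + r
    ))
    feats <- extract_features(g$corpus)
    cmp <- suppressWarnings(compare_groups(
      feats, "paired_by_subject",
      analysis_config(n_permutations = 999, n_boot = 0, seed = 91000 + r)
    ))
    runs_with_rejection <- runs_with_rejection +
      any(cmp$significant, na.rm = TRUE)
  }
  # familywise rate under Holm stays near alpha: most runs reject nothing
  expect_lte(runs_with_rejection, 3)
})
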
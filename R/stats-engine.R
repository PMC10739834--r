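#' Configuration for the permutation-comparison stage
#'
#' @param n_permutations Monte-Carlo permutations per test (default 10,000).
#' @param alpha Familywise significance level.
#' @param ci_level Confidence level for effect-size intervals.
#' @param seed Master seed; per-feature random streams are derived from it
#'   and the feature name, so adding a feature never perturbs the others.
#' @param correction `"holm"` (step-down Holm-Bonferroni across the feature
#'   family) or `"none"`.
#' @param n_boot Bootstrap resamples for the CLES percentile interval.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_permutations = 10000, alpha = 0.05,
                            ci_level = 0.95, seed = 1L,
                            correction = c("holm", "none"), n_boot = 2000) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1,
            ci_level > 0, ci_level < 1)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 ci_level = ci_level, seed = as.integer(seed),
                 correction = match.arg(correction),
                 n_boot = as.integer(n_boot)),
            class = "analysis_config")
}

# deterministic per-feature seed: master seed + a name hash, below 2^31
feature_seed <- function(seed, name, salt = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1000003L
  (abs(seed) + (h + salt) * 131L) %% 2147483629L + 1L
}

#' Monte-Carlo permutation test for a difference in means
#'
#' `perm_test_independent()` pools the two samples and redistributes them
#' into groups of the original sizes; `perm_test_paired()` flips the signs
#' of within-pair differences. Both use the mean-difference statistic, are
#' two-sided, and report the add-one Monte-Carlo p-value
#' `(1 + #\{|T*| >= |T_obs|\}) / (1 + B)` so p is never zero.
#'
#' @param x,y Numeric vectors (paired: equal length, aligned by subject).
#'   Remove missing values beforehand.
#' @param n_permutations Number of Monte-Carlo permutations.
#' @param seed Seed for the permutation stream.
#' @return The two-sided p-value.
#' @export
perm_test_independent <- function(x, y, n_permutations = 10000, seed = 1L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  t_obs <- mean(x) - mean(y)
  total <- sum(pooled)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  t_perm <- vapply(seq_len(n_permutations), function(b) {
    s <- sum(pooled[sample.int(n, n1)])
    s / n1 - (total - s) / n2
  }, numeric(1))
  (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_permutations)
}

#' @rdname perm_test_independent
#' @export
perm_test_paired <- function(x, y, n_permutations = 10000, seed = 1L) {
  if (length(x) != length(y)) stop("paired samples differ in length", call. = FALSE)
  stopifnot(length(x) >= 2L, !anyNA(x), !anyNA(y))
  d <- x - y
  t_obs <- mean(d)
  n <- length(d)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  nrow = n_permutations)
  t_perm <- as.numeric(signs %*% d) / n
  (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_permutations)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`: step-down
#' adjustment with monotonicity enforcement, capped at 1, output in input
#' order.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

# midrank CLES point estimate: ties weighted 0.5
cles_point <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Common-language effect size with bootstrap CI
#'
#' The probability that a value picked at random from `x` (the truthful
#' group, by convention) exceeds one picked at random from `y`, ties
#' weighted one half: `(#\{x_i > y_j\} + 0.5 #\{x_i = y_j\}) / (n1 n2)`.
#' The null value is 0.5. The CI is a seeded nonparametric percentile
#' bootstrap over statements.
#'
#' @param x,y Non-empty numeric vectors.
#' @param ci_level Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap stream.
#' @return List `cles`, `lo`, `hi`.
#' @export
cles <- function(x, y, ci_level = 0.95, n_boot = 2000, seed = 1L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  point <- cles_point(x, y)
  if (n_boot < 1L) return(list(cles = point, lo = NA_real_, hi = NA_real_))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    cles_point(x[sample.int(length(x), replace = TRUE)],
               y[sample.int(length(y), replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  list(cles = point, lo = qs[1], hi = qs[2])
}

#' Cohen's d with a normal-approximation CI
#'
#' `d = (mean x - mean y) / pooled sample sd`, CI from the asymptotic
#' standard error `sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`. A zero
#' pooled sd yields `NA` (flagged, not an error).
#'
#' @param x,y Numeric vectors of size >= 2.
#' @param ci_level Confidence level.
#' @return List `d`, `lo`, `hi`.
#' @export
cohens_d <- function(x, y, ci_level = 0.95) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(list(d = NA_real_, lo = NA_real_, hi = NA_real_))
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(d = d, lo = d - z * se, hi = d + z * se)
}

#' Average each subject's style vectors per veracity
#'
#' For corpora where every subject contributed both truthful and deceptive
#' statements (the opinion design), reduce the per-statement feature matrix
#' to one truthful and one deceptive mean vector per subject, so downstream
#' tests pair by subject and are independent of topic and stance. Undefined
#' feature values are excluded from the means. Subjects missing one
#' veracity group are dropped with a warning.
#'
#' @param features Tibble with `subject_id`, `veracity` and feature columns.
#' @param feature_cols Feature columns to average (default: the 26 style
#'   features present).
#' @return Tibble with `subject_id`, `veracity` and the averaged features.
#' @export
subject_average <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(style_features(), names(features))
  }
  both <- features |>
    dplyr::distinct(.data$subject_id, .data$veracity) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::pull(.data$subject_id)
  dropped <- setdiff(unique(features$subject_id), both)
  if (length(dropped)) {
    warning(length(dropped), " subject(s) lacking both veracity groups dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...", call. = FALSE)
  }
  features |>
    dplyr::filter(.data$subject_id %in% both) |>
    dplyr::group_by(.data$subject_id, .data$veracity) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(feature_cols),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
}

#' Permutation comparison of truthful vs deceptive style, per feature
#'
#' The core descriptive analysis: for every feature, a two-sided
#' Monte-Carlo permutation test of the truthful-minus-deceptive mean
#' difference (independent design: group-label reshuffling; paired design:
#' subject-averaged vectors and sign flips), Holm-Bonferroni adjustment
#' across the feature family, CLES and Cohen's d with CIs, and the
#' direction of the effect. Missing feature values are dropped pairwise per
#' feature with the effective n reported.
#'
#' @param features Tibble with `veracity` (and `subject_id` for the paired
#'   design) plus feature columns.
#' @param design `"independent"` or `"paired_by_subject"`.
#' @param config An [analysis_config()].
#' @param feature_cols Feature columns to test (default: the 26 style
#'   features present).
#' @return A `veristyle_comparison` tibble: `feature`, `n1`, `n2`,
#'   `mean_diff`, `p_raw`, `p_holm`, `cles`, `cles_lo`, `cles_hi`, `d`,
#'   `d_lo`, `d_hi`, `direction`, `significant`.
#' @export
compare_groups <- function(features,
                           design = c("independent", "paired_by_subject"),
                           config = analysis_config(),
                           feature_cols = NULL) {
  design <- match.arg(design)
  if (is.null(feature_cols)) {
    feature_cols <- intersect(style_features(), names(features))
  }
  stopifnot(length(feature_cols) >= 1L,
            all(features$veracity %in% c("truthful", "deceptive")))
  if (design == "paired_by_subject") {
    features <- subject_average(features, feature_cols)
  }
  rows <- purrr::map(feature_cols, function(f) {
    sd_perm <- feature_seed(config$seed, f, 1L)
    sd_boot <- feature_seed(config$seed, f, 2L)
    if (design == "independent") {
      x <- features[[f]][features$veracity == "truthful"]
      y <- features[[f]][features$veracity == "deceptive"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      n1 <- length(x); n2 <- length(y)
      if (n1 < 2L || n2 < 2L) {
        return(tibble::tibble(
          feature = f, n1 = n1, n2 = n2, mean_diff = NA_real_,
          p_raw = NA_real_, cles = NA_real_, cles_lo = NA_real_,
          cles_hi = NA_real_, d = NA_real_, d_lo = NA_real_,
          d_hi = NA_real_, direction = "none"
        ))
      }
      constant <- length(unique(c(x, y))) <= 1L
      p <- if (constant) 1.0 else {
        perm_test_independent(x, y, config$n_permutations, seed = sd_perm)
      }
    } else {
      wide <- tidyr::pivot_wider(
        features[, c("subject_id", "veracity", f)],
        names_from = "veracity", values_from = dplyr::all_of(f)
      )
      ok <- !is.na(wide$truthful) & !is.na(wide$deceptive)
      x <- wide$truthful[ok]; y <- wide$deceptive[ok]
      n1 <- n2 <- length(x)
      if (n1 < 2L) {
        return(tibble::tibble(
          feature = f, n1 = n1, n2 = n2, mean_diff = NA_real_,
          p_raw = NA_real_, cles = NA_real_, cles_lo = NA_real_,
          cles_hi = NA_real_, d = NA_real_, d_lo = NA_real_,
          d_hi = NA_real_, direction = "none"
        ))
      }
      constant <- length(unique(c(x, y))) <= 1L || all(x == y)
      p <- if (constant) 1.0 else {
        perm_test_paired(x, y, config$n_permutations, seed = sd_perm)
      }
    }
    if (constant) {
      eff <- list(cles = 0.5, lo = 0.5, hi = 0.5)
      dd <- list(d = 0, lo = 0, hi = 0)
      md <- 0
    } else {
      eff <- cles(x, y, config$ci_level, config$n_boot, seed = sd_boot)
      dd <- cohens_d(x, y, config$ci_level)
      md <- mean(x) - mean(y)
    }
    tibble::tibble(
      feature = f, n1 = n1, n2 = n2, mean_diff = md, p_raw = p,
      cles = eff$cles, cles_lo = eff$lo, cles_hi = eff$hi,
      d = dd$d, d_lo = dd$lo, d_hi = dd$hi,
      direction = if (constant || md == 0) "none" else {
        if (md > 0) "higher_in_truthful" else "higher_in_deceptive"
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- out$p_raw
  if (config$correction == "holm") {
    ok <- !is.na(out$p_raw)
    out$p_holm[ok] <- holm_adjust(out$p_raw[ok])
  }
  out$significant <- !is.na(out$p_holm) & out$p_holm < config$alpha
  out <- out[, c("feature", "n1", "n2", "mean_diff", "p_raw", "p_holm",
                 "cles", "cles_lo", "cles_hi", "d", "d_lo", "d_hi",
                 "direction", "significant")]
  structure(out,
            class = c("veristyle_comparison", class(tibble::tibble())),
            alpha = config$alpha, design = design)
}
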
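#' Partition each fold's test set into confusion quadrants
#'
#' With truthful as the positive class: TP = truthful predicted truthful,
#' TN = deceptive predicted deceptive, FN = truthful predicted deceptive,
#' FP = deceptive predicted truthful. Unparseable predictions (`NA`) were
#' scored as incorrect, so they land in FN/FP. The four sets are disjoint
#' and cover every fold's test set exactly.
#'
#' @param predictions Tibble `statement_id, fold, true, predicted` (from
#'   [run_cv()]).
#' @return Tibble `statement_id, fold, true, predicted, outcome` with
#'   `outcome` in `{TP, TN, FP, FN}`.
#' @export
partition_outcomes <- function(predictions) {
  dup <- predictions |>
    dplyr::count(.data$fold, .data$statement_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate statement(s) within a fold: ",
         paste(utils::head(dup$statement_id, 5L), collapse = ", "),
         call. = FALSE)
  }
  eff <- ifelse(is.na(predictions$predicted),
                ifelse(predictions$true == "truthful", "deceptive", "truthful"),
                predictions$predicted)
  outcome <- dplyr::case_when(
    predictions$true == "truthful" & eff == "truthful" ~ "TP",
    predictions$true == "deceptive" & eff == "deceptive" ~ "TN",
    predictions$true == "truthful" & eff == "deceptive" ~ "FN",
    TRUE ~ "FP"
  )
  dplyr::mutate(predictions, outcome = outcome)
}

contrast_pairs <- function() {
  list(FN_vs_FP = c("FN", "FP"), TN_vs_FN = c("TN", "FN"),
       TP_vs_FP = c("TP", "FP"), TP_vs_TN = c("TP", "TN"))
}

#' Stylometric contrasts between confusion quadrants, per fold
#'
#' For every fold and each of the four contrasts (FN vs FP, TN vs FN,
#' TP vs FP, TP vs TN), runs the independent-samples permutation test on
#' each style feature of the two quadrant groups, with Holm correction
#' applied within the fold-contrast family. The direction convention is
#' first-listed minus second-listed group, so CLES > 0.5 means higher in
#' the first group. Contrasts whose either group has fewer than
#' `min_group` statements are skipped and logged in the `"skipped"`
#' attribute.
#'
#' @param outcomes Output of [partition_outcomes()].
#' @param features Feature matrix covering all test statements (tibble
#'   with `id` and feature columns).
#' @param config An [analysis_config()]; the per-test seeds are derived
#'   from its seed, the fold and the contrast name.
#' @param feature_cols Feature columns (default: the 26 style features
#'   present).
#' @param min_group Minimum statements per quadrant group (default 2).
#' @return A `veristyle_contrasts` tibble: `fold`, `contrast` plus the
#'   [compare_groups()] columns; skipped fold-contrasts in
#'   `attr(x, "skipped")`.
#' @export
fold_contrasts <- function(outcomes, features, config = analysis_config(),
                           feature_cols = NULL, min_group = 2L) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(style_features(), names(features))
  }
  missing <- setdiff(outcomes$statement_id, features$id)
  if (length(missing)) {
    stop("feature matrix lacks ", length(missing), " test statement(s)",
         call. = FALSE)
  }
  results <- list()
  skipped <- list()
  for (f in sort(unique(outcomes$fold))) {
    fold_rows <- outcomes[outcomes$fold == f, ]
    for (cname in names(contrast_pairs())) {
      pair <- contrast_pairs()[[cname]]
      ids1 <- fold_rows$statement_id[fold_rows$outcome == pair[1]]
      ids2 <- fold_rows$statement_id[fold_rows$outcome == pair[2]]
      if (length(ids1) < min_group || length(ids2) < min_group) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          fold = f, contrast = cname, n1 = length(ids1), n2 = length(ids2),
          reason = "group below minimum size"
        )
        next
      }
      # first-listed group plays the role of "truthful" in the engine
      block <- dplyr::bind_rows(
        dplyr::mutate(features[match(ids1, features$id), ], veracity = "truthful"),
        dplyr::mutate(features[match(ids2, features$id), ], veracity = "deceptive")
      )
      cfg <- config
      cfg$seed <- feature_seed(config$seed, cname, salt = 100L + f)
      cmp <- compare_groups(block, design = "independent", config = cfg,
                            feature_cols = feature_cols)
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(fold = f, contrast = cname), tibble::as_tibble(cmp)
      )
    }
  }
  out <- if (length(results)) dplyr::bind_rows(results) else {
    tibble::tibble(fold = integer(), contrast = character())
  }
  structure(out, class = c("veristyle_contrasts", class(tibble::tibble())),
            skipped = dplyr::bind_rows(skipped), alpha = config$alpha)
}

#' Aggregate fold-wise contrasts across the cross-validation
#'
#' Per contrast and feature: the number of folds in which the feature
#' survived the within-fold Holm correction, the arithmetic mean of the
#' per-fold CLES and Cohen's d together with their averaged CI bounds
#' (averaged exactly as the point estimates are; the averaged bounds are a
#' summary, not a coverage-calibrated interval), and the modal direction.
#' Features are ordered by significance count, descending. A feature never
#' tested in any fold of a contrast is absent from that contrast's rows
#' rather than reported as zero.
#'
#' @param contrasts A `veristyle_contrasts` from [fold_contrasts()].
#' @return A `veristyle_contrast_aggregate` tibble: `contrast`, `feature`,
#'   `n_folds_tested`, `n_significant_folds`, `mean_cles`, `mean_cles_lo`,
#'   `mean_cles_hi`, `mean_d`, `mean_d_lo`, `mean_d_hi`,
#'   `dominant_direction`.
#' @export
aggregate_contrasts <- function(contrasts) {
  stopifnot(nrow(contrasts) > 0L)
  out <- contrasts |>
    dplyr::filter(!is.na(.data$p_raw)) |>
    dplyr::group_by(.data$contrast, .data$feature) |>
    dplyr::summarise(
      n_folds_tested = dplyr::n(),
      n_significant_folds = sum(.data$significant),
      mean_cles = mean(.data$cles), mean_cles_lo = mean(.data$cles_lo),
      mean_cles_hi = mean(.data$cles_hi),
      mean_d = mean(.data$d), mean_d_lo = mean(.data$d_lo),
      mean_d_hi = mean(.data$d_hi),
      dominant_direction = names(sort(table(.data$direction),
                                      decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$contrast, dplyr::desc(.data$n_significant_folds),
                   dplyr::desc(abs(.data$mean_cles - 0.5)))
  structure(out,
            class = c("veristyle_contrast_aggregate", class(tibble::tibble())))
}
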
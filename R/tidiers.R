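#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for veristyle results
#'
#' `tidy()` returns the per-feature (or per-statement) table of a result as
#' a plain tibble; `glance()` returns a one-row summary.
#'
#' @param x A `veristyle_comparison`, `veristyle_run` or
#'   `veristyle_contrasts` object.
#' @param ... Unused.
#' @return A tibble.
#' @name veristyle-tidiers
NULL

#' @rdname veristyle-tidiers
#' @exportS3Method generics::tidy
tidy.veristyle_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname veristyle-tidiers
#' @exportS3Method generics::glance
glance.veristyle_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    design = attr(x, "design"),
    n1 = max(x$n1), n2 = max(x$n2)
  )
}

#' @rdname veristyle-tidiers
#' @exportS3Method generics::tidy
tidy.veristyle_run <- function(x, ...) {
  x$predictions
}

#' @rdname veristyle-tidiers
#' @exportS3Method generics::glance
glance.veristyle_run <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, adapter = x$adapter,
    n_folds = length(x$fold_accuracy),
    mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
    n_tested = nrow(x$predictions), n_unparseable = x$n_unparseable
  )
}

#' @rdname veristyle-tidiers
#' @exportS3Method generics::tidy
tidy.veristyle_contrasts <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname veristyle-tidiers
#' @exportS3Method generics::glance
glance.veristyle_contrasts <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble::tibble(
    n_fold_contrasts = nrow(dplyr::distinct(tibble::as_tibble(x),
                                            .data$fold, .data$contrast)),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' Plot a truthful-vs-deceptive comparison
#'
#' Dot-and-interval chart of the common-language effect size per feature
#' (0.5 = no effect), significant features filled by the direction of the
#' effect — the package's rendering of the stacked CLES charts customary
#' in deception stylometry.
#'
#' @param object A `veristyle_comparison`.
#' @param only_significant Keep only Holm-significant features.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veristyle_comparison <- function(object, only_significant = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (only_significant) df <- df[df$significant %in% TRUE, ]
  if (nrow(df) == 0L) df <- tibble::as_tibble(object)
  df$feature <- stats::reorder(df$feature, df$cles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cles, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$cles_lo, xmax = .data$cles_hi), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 2) +
    ggplot2::scale_colour_manual(values = c(
      higher_in_truthful = "#56B4E9", higher_in_deceptive = "#E69F00",
      none = "grey60"
    )) +
    ggplot2::labs(x = "CLES (P[truthful > deceptive])", y = NULL,
                  colour = "direction") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the cross-fold averaged confusion matrix of a run
#'
#' @param object A `veristyle_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veristyle_run <- function(object, ...) {
  df <- expand.grid(true = c("truthful", "deceptive"),
                    predicted = c("truthful", "deceptive"),
                    stringsAsFactors = FALSE)
  df$mean <- mapply(function(t, p) object$confusion_mean[t, p],
                    df$true, df$predicted)
  df$sd <- mapply(function(t, p) object$confusion_sd[t, p],
                  df$true, df$predicted)
  df$label <- sprintf("%.1f\n(%.1f)", df$mean, df$sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_y_discrete(limits = c("deceptive", "truthful")) +
    ggplot2::scale_fill_gradient(low = "white", high = "#56B4E9") +
    ggplot2::labs(title = sprintf("%s / %s: mean fold confusion (sd)",
                                  object$scenario, object$adapter),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot an aggregated quadrant contrast (significance-count ranking)
#'
#' Bars of the cross-fold mean CLES for one contrast, sorted by the number
#' of folds in which each feature survived the within-fold correction
#' (annotated at the bar end), filled by the dominant direction.
#'
#' @param object A `veristyle_contrast_aggregate`.
#' @param contrast Which contrast to draw (default `"TP_vs_TN"`).
#' @param min_folds Hide features significant in fewer folds.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.veristyle_contrast_aggregate <- function(object,
                                                  contrast = "TP_vs_TN",
                                                  min_folds = 1L, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$contrast == contrast & df$n_significant_folds >= min_folds, ]
  if (nrow(df) == 0L) {
    stop("no features to plot for contrast ", contrast, call. = FALSE)
  }
  df$feature <- stats::reorder(df$feature, df$n_significant_folds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_cles, y = .data$feature,
                                   fill = .data$dominant_direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_significant_folds),
                       hjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = c(
      higher_in_truthful = "#56B4E9", higher_in_deceptive = "#E69F00",
      none = "grey60"
    )) +
    ggplot2::labs(x = "mean CLES across folds", y = NULL,
                  fill = "dominant direction", title = contrast) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
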
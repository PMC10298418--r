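# print, tidy/glance and autoplot methods for fitted result objects

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%.0f%% CI %.3f-%.3f), DeLong variance %.2e, %d pos / %d neg\n",
    x$auc, 100 * x$level, x$conf_low, x$conf_high, x$variance, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy the empirical ROC curve of a `roc_result`
#'
#' @param x A `roc_result` from [delong_ci()].
#' @param ... Unused.
#' @return A tibble of curve points `(threshold, fpr, tpr)`.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row summary of a `roc_result`
#'
#' @inheritParams tidy.roc_result
#' @return A one-row tibble: `auc`, `conf_low`, `conf_high`, `variance`,
#'   `level`, `n_pos`, `n_neg`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, conf_low = x$conf_low, conf_high = x$conf_high,
    variance = x$variance, level = x$level, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve (empirical steps plus binormal smooth)
#'
#' @param object A `roc_result` from [delong_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("AUROC %.2f (%.0f%% CI %.2f-%.2f)",
        object$auc, 100 * object$level, object$conf_low, object$conf_high)) +
    ggplot2::theme_minimal()
  if (!is.null(object$smoothed_curve) && isTRUE(attr(object$smoothed_curve, "smoothed"))) {
    p <- p + ggplot2::geom_line(data = object$smoothed_curve, colour = "steelblue")
  }
  p
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Youden operating point: threshold %.3g, J = %.3f\n", x$threshold, x$youden_j))
  cat(sprintf("  Se %.2f (%.2f-%.2f)  Sp %.2f (%.2f-%.2f)  Acc %.2f (%.2f-%.2f)\n",
    x$sensitivity$estimate, x$sensitivity$conf_low, x$sensitivity$conf_high,
    x$specificity$estimate, x$specificity$conf_low, x$specificity$conf_high,
    x$accuracy$estimate, x$accuracy$conf_low, x$accuracy$conf_high))
  invisible(x)
}

#' Tidy an operating point: one row per metric
#'
#' @param x An `operating_point` from [youden_operating_point()].
#' @param ... Unused.
#' @return A tibble with columns `metric`, `estimate`, `conf_low`,
#'   `conf_high`.
#' @method tidy operating_point
#' @export
tidy.operating_point <- function(x, ...) {
  dplyr::bind_rows(
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, .id = "metric")
}

#' One-row summary of an operating point
#'
#' @inheritParams tidy.operating_point
#' @return A one-row tibble: `threshold`, `youden_j`, `sensitivity`,
#'   `specificity`, `accuracy` and the confusion counts.
#' @method glance operating_point
#' @export
glance.operating_point <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, youden_j = x$youden_j,
    sensitivity = x$sensitivity$estimate, specificity = x$specificity$estimate,
    accuracy = x$accuracy$estimate, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Paired AUROC permutation test (%s, %d permutations)\n",
    x$method, x$n_permutations))
  cat(sprintf("  delta AUC = %+.4f, |delta| = %.4f, p = %.4g\n",
    x$delta_auc, x$statistic, x$p_value))
  invisible(x)
}

#' Tidy a permutation comparison result
#'
#' @param x A `comparison_result` from [permutation_test_auc()].
#' @param ... Unused.
#' @return A one-row tibble: `delta_auc`, `statistic`, `p_value`,
#'   `n_permutations`, `method`.
#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(delta_auc = x$delta_auc, statistic = x$statistic,
    p_value = x$p_value, n_permutations = x$n_permutations, method = x$method)
}

#' Forest-style plot of a benchmark report
#'
#' AUROC point estimates with confidence intervals, one row per reader group
#' (and the AI ensemble), faceted by modality.
#'
#' @param object A `benchmark_report` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$auroc))
  df$group <- factor(df$group, levels = rev(unique(object$group)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auroc, y = .data$group)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$auroc_lo, xmax = .data$auroc_hi), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group == "AI"), show.legend = FALSE) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "AUROC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
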
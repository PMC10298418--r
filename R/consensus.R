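#' Map a 5-point Likert score to a probability of pathology
#'
#' The rating scale is anchored at "definitely without pathology" (1, 0.0)
#' and "definitely with pathology" (5, 1.0), with "undefined" (3) at 0.5;
#' the mapping is `(score - 1) / 4`.
#'
#' @param score Integer vector with values in 1..5.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' likert_to_probability(1:5)
#' @export
likert_to_probability <- function(score) {
  if (anyNA(score) || !all(score %in% 1:5)) {
    abort("`score` must contain only integers 1..5.",
      class = "readerbench_validation_error")
  }
  (score - 1) / 4
}

# upper median: the ceiling((n+1)/2)-th order statistic. For odd n this is
# the usual median; for even n the higher of the two central values.
upper_median <- function(x) sort(x)[ceiling((length(x) + 1) / 2)]

# most frequent score; frequency ties resolved toward the higher score
mode_high <- function(x) {
  tab <- table(x)
  max(as.integer(names(tab)[tab == max(tab)]))
}

#' Reader consensus scores with exclusion rules
#'
#' Aggregates per-reader Likert ratings into one consensus score per case:
#' \enumerate{
#'   \item A case in which strictly more than 50\% of scores are "undefined"
#'     (score 3) is excluded (`undefined_majority`).
#'   \item Otherwise, if `apply_min_filter` is `TRUE` and the case has fewer
#'     than `min_responses` ratings it is excluded (`too_few_responses`).
#'     The filter is switched off for the breast-imaging-specialist
#'     subgroup analysis.
#'   \item Otherwise the consensus is the upper median of the scores (for an
#'     even number of ratings the higher of the two central scores — the
#'     higher score wins a central tie), mapped through
#'     [likert_to_probability()]. `rule = "mode_high"` instead takes the
#'     most frequent score, breaking frequency ties toward the higher
#'     score (sensitivity analysis).
#' }
#'
#' @param ratings Tibble in the `ratings` schema (`reader_id`, `case_id`,
#'   `score`); ratings for any number of cases.
#' @param min_responses Minimum ratings per case (default 5).
#' @param apply_min_filter Apply the minimum-response exclusion?
#' @param rule `"upper_median"` (default) or `"mode_high"`.
#' @return A tibble with one row per case: `case_id`, `value` (in \[0, 1\],
#'   `NA` when excluded), `n_responses`, `excluded`, `exclusion_reason`
#'   (`"none"`, `"undefined_majority"` or `"too_few_responses"`).
#' @examples
#' ratings <- tibble::tibble(
#'   reader_id = paste0("r", 1:5), case_id = "c1", score = c(1, 2, 4, 5, 5))
#' reader_consensus(ratings)
#' @export
reader_consensus <- function(ratings, min_responses = 5, apply_min_filter = TRUE,
                             rule = c("upper_median", "mode_high")) {
  rule <- rlang::arg_match(rule)
  if (nrow(ratings) == 0) {
    abort("`ratings` is empty; consensus needs at least one rating.",
      class = "readerbench_validation_error")
  }
  if (anyNA(ratings$score) || !all(ratings$score %in% 1:5)) {
    abort("All scores must be integers 1..5.", class = "readerbench_validation_error")
  }
  aggregate_scores <- if (rule == "upper_median") upper_median else mode_high
  ratings |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      n_responses = dplyr::n(),
      frac_undefined = mean(.data$score == 3),
      consensus_score = aggregate_scores(.data$score),
      .groups = "drop") |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        .data$frac_undefined > 0.5 ~ "undefined_majority",
        apply_min_filter & .data$n_responses < min_responses ~ "too_few_responses",
        TRUE ~ "none"),
      excluded = .data$exclusion_reason != "none",
      value = dplyr::if_else(.data$excluded, NA_real_,
        likert_to_probability(.data$consensus_score))) |>
    dplyr::select("case_id", "value", "n_responses", "excluded", "exclusion_reason")
}

#' Calibrate one or more AI models' scores to a common scale
#'
#' Before ensembling, each model's scores are individually mapped to a common
#' (0, 1) scale with the label-free midrank transform
#' `(midrank - 0.5) / m`, where `midrank` is the score's average rank among
#' the model's `m` scores (ties share their mean rank). The transform is
#' strictly increasing up to ties, so each model's ROC curve — and hence its
#' AUC — is unchanged; it only aligns the models' score scales so that
#' averaging them is meaningful. No ground-truth labels are used.
#'
#' @param scores Tibble in the `model_scores` schema; may contain several
#'   models, each calibrated separately.
#' @return The same tibble with `prob` replaced by the calibrated value.
#'   A model whose scores are all identical calibrates to 0.5 everywhere,
#'   with a warning (degenerate model).
#' @examples
#' scores <- tibble::tibble(model_id = "m", case_id = paste0("c", 1:3),
#'                          prob = c(0.2, 0.5, 0.9))
#' calibrate_model_scores(scores)$prob  # 1/6, 3/6, 5/6
#' @export
calibrate_model_scores <- function(scores) {
  if (nrow(scores) == 0) {
    abort("`scores` is empty.", class = "readerbench_validation_error")
  }
  degenerate <- scores |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(one = dplyr::n_distinct(.data$prob) == 1 & dplyr::n() > 1,
      .groups = "drop")
  if (any(degenerate$one)) {
    warn(paste0("Model(s) with constant scores calibrate to 0.5 everywhere: ",
      paste(degenerate$model_id[degenerate$one], collapse = ", ")))
  }
  scores |>
    dplyr::group_by(.data$model_id) |>
    dplyr::mutate(prob = (rank(.data$prob, ties.method = "average") - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
}

#' AI ensemble consensus score per case
#'
#' The AI-side consensus for a case is the arithmetic mean of the calibrated
#' per-model scores for that case. No exclusion rules apply on the AI side;
#' a case scored by no model is simply absent (with a warning if `case_ids`
#' names expected cases).
#'
#' @param calibrated Tibble in the `model_scores` schema, typically from
#'   [calibrate_model_scores()].
#' @param case_ids Optional character vector of expected cases; cases with
#'   zero model scores are reported with a warning.
#' @return A tibble with `case_id`, `value`, `n_responses` (number of
#'   contributing models), `excluded` (always `FALSE`), `exclusion_reason`
#'   (always `"none"`).
#' @export
ai_ensemble_consensus <- function(calibrated, case_ids = NULL) {
  if (nrow(calibrated) == 0) {
    abort("`calibrated` is empty.", class = "readerbench_validation_error")
  }
  out <- calibrated |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(value = mean(.data$prob), n_responses = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(excluded = FALSE, exclusion_reason = "none")
  if (!is.null(case_ids)) {
    missing <- setdiff(case_ids, out$case_id)
    if (length(missing) > 0) {
      warn(paste0(length(missing), " case(s) have no AI score and are absent ",
        "from the AI consensus: ", paste(head(missing, 5), collapse = ", ")))
    }
  }
  out
}
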
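#' Configuration for [run_benchmark()]
#'
#' @param level Confidence level for all intervals (default 0.95).
#' @param n_permutations Permutations for each AI-vs-group test
#'   (default 10000).
#' @param min_responses Minimum ratings per case before exclusion
#'   (default 5); not applied to specialist groups.
#' @param consensus_rule `"upper_median"` (default) or `"mode_high"`; see
#'   [reader_consensus()].
#' @param paired Paired per-case swap permutation scheme (default `TRUE`);
#'   `FALSE` uses the unpaired arm-reassignment scheme.
#' @param holm Apply a Holm adjustment across each modality's p-values?
#'   Default `FALSE` (per-row, unadjusted p-values).
#' @param seed Integer seed driving all permutation tests.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(level = 0.95, n_permutations = 10000,
                             min_responses = 5,
                             consensus_rule = c("upper_median", "mode_high"),
                             paired = TRUE, holm = FALSE, seed = 1) {
  consensus_rule <- rlang::arg_match(consensus_rule)
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "readerbench_config_error")
  }
  structure(
    list(level = level, n_permutations = as.integer(n_permutations),
      min_responses = min_responses, consensus_rule = consensus_rule,
      paired = isTRUE(paired), holm = isTRUE(holm), seed = as.integer(seed)),
    class = "benchmark_config")
}

empty_row <- function(modality, group, n = 0L, status = "insufficient_data") {
  tibble::tibble(modality = modality, group = group, n = as.integer(n),
    auroc = NA_real_, auroc_lo = NA_real_, auroc_hi = NA_real_,
    threshold = NA_real_, youden_j = NA_real_,
    sens = NA_real_, sens_lo = NA_real_, sens_hi = NA_real_,
    spec = NA_real_, spec_lo = NA_real_, spec_hi = NA_real_,
    acc = NA_real_, acc_lo = NA_real_, acc_hi = NA_real_,
    delta_auc = NA_real_, p_value = NA_real_, status = status)
}

#' Run the full reader-vs-AI benchmark
#'
#' End-to-end orchestration, per modality:
#' \enumerate{
#'   \item AI side: calibrate each model's scores ([calibrate_model_scores()])
#'     and average them into a per-case ensemble consensus
#'     ([ai_ensemble_consensus()]).
#'   \item Reader side: for each group (all readers, the four experience
#'     bands, and — for mammography — the breast-specialist subgroups, which
#'     are exempt from the minimum-response filter), build the consensus
#'     with [reader_consensus()] and drop excluded cases.
#'   \item Inference: on the cases shared by the group's consensus and the
#'     AI consensus, compute the AUROC with a DeLong interval, the Youden
#'     operating point with exact binomial intervals, and the paired
#'     permutation comparison against the AI ensemble. The reported `n` is
#'     the paired set size and therefore differs across rows: the
#'     minimum-response filter binds harder in small groups.
#' }
#' The AI row itself is evaluated on the cases shared with the all-readers
#' consensus. A group with no usable cases yields an `insufficient_data`
#' row; the pipeline continues. The report is deterministic given inputs,
#' config and seed.
#'
#' @param cases,readers,ratings,model_scores Tibbles in the four study
#'   schemas (see [read_study_table()]); `readers` may carry extra columns.
#' @param config A [benchmark_config()].
#' @return A tibble of class `benchmark_report`, one row per
#'   (modality, group), with columns `modality`, `group`, `n`, `auroc`,
#'   `auroc_lo`, `auroc_hi`, `threshold`, `youden_j`, `sens`, `sens_lo`,
#'   `sens_hi`, `spec`, `spec_lo`, `spec_hi`, `acc`, `acc_lo`, `acc_hi`,
#'   `delta_auc` (group AUC minus AI AUC), `p_value`, `status`. Full
#'   fitted objects are attached as `attr(report, "details")`.
#' @examples
#' study <- simulate_study(study_config(
#'   modalities = tibble::tibble(modality = "XRAY", n_cases = 60, prevalence = 0.4),
#'   reader_counts = tibble::tibble(modality = "XRAY",
#'     experience_band = c("E0_1", "E10P"), n_readers = c(8, 8), n_specialists = 0),
#'   set_size = 20, seed = 42))
#' report <- run_benchmark(study$cases, study$readers, study$ratings,
#'   study$model_scores, benchmark_config(n_permutations = 200, seed = 42))
#' report[c("modality", "group", "n", "auroc", "p_value")]
#' @export
run_benchmark <- function(cases, readers, ratings, model_scores,
                          config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  cases <- validate_study_table(cases, "cases")
  readers <- validate_study_table(readers, "readers")
  ratings <- validate_study_table(ratings, "ratings")
  model_scores <- validate_study_table(model_scores, "model_scores")

  unknown <- setdiff(ratings$case_id, cases$case_id)
  if (length(unknown) > 0) {
    abort(paste0("Ratings reference unknown case_id(s): ",
      paste(head(unknown, 5), collapse = ", ")),
      class = "readerbench_validation_error")
  }

  labels <- setNames(cases$label, cases$case_id)
  rows <- list()
  details <- list()

  for (m in unique(cases$modality)) {
    cases_m <- cases[cases$modality == m, ]
    ratings_m <- ratings[ratings$case_id %in% cases_m$case_id, ]
    scores_m <- model_scores[model_scores$case_id %in% cases_m$case_id, ]

    ai_cons <- NULL
    if (nrow(scores_m) == 0) {
      warn(paste0("No AI scores for modality ", m, "; AI comparisons omitted."))
    } else {
      ai_cons <- ai_ensemble_consensus(calibrate_model_scores(scores_m))
    }

    readers_m <- readers[readers$reader_id %in% unique(ratings_m$reader_id), ]
    groups <- tibble::tibble(
      group = c("ALL_READERS", EXPERIENCE_BANDS),
      band = c(NA, EXPERIENCE_BANDS),
      specialist = FALSE, apply_min_filter = TRUE)
    if (m == "MMG" && any(readers_m$breast_specialist)) {
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        group = c("SPECIALISTS_ALL", paste0("SPECIALISTS_", EXPERIENCE_BANDS)),
        band = c(NA, EXPERIENCE_BANDS),
        specialist = TRUE, apply_min_filter = FALSE))
    }

    # all-readers surviving consensus defines the AI row's paired case set
    all_cons <- NULL
    group_results <- vector("list", nrow(groups))

    for (g in seq_len(nrow(groups))) {
      gs <- groups[g, ]
      rd <- readers_m
      if (gs$specialist) rd <- rd[rd$breast_specialist, ]
      if (!is.na(gs$band)) rd <- rd[rd$experience_band == gs$band, ]
      rt <- ratings_m[ratings_m$reader_id %in% rd$reader_id, ]
      if (nrow(rt) == 0) {
        group_results[[g]] <- empty_row(m, gs$group)
        next
      }
      cons <- reader_consensus(rt, min_responses = config$min_responses,
        apply_min_filter = gs$apply_min_filter, rule = config$consensus_rule)
      cons <- cons[!cons$excluded, ]
      if (gs$group == "ALL_READERS") all_cons <- cons
      if (!is.null(ai_cons)) {
        paired <- dplyr::inner_join(cons, ai_cons, by = "case_id",
          suffix = c("_reader", "_ai"))
      } else {
        paired <- dplyr::rename(cons, value_reader = "value")
        paired$value_ai <- NA_real_
      }
      y <- unname(labels[paired$case_id])
      if (nrow(paired) < 4 || sum(y == 1) < 2 || sum(y == 0) < 2) {
        group_results[[g]] <- empty_row(m, gs$group, n = nrow(paired))
        next
      }
      roc <- delong_ci(paired$value_reader, y, level = config$level)
      op <- youden_operating_point(paired$value_reader, y, level = config$level)
      cmp <- NULL
      if (!is.null(ai_cons)) {
        cmp <- permutation_test_auc(paired$value_reader, paired$value_ai, y,
          n_permutations = config$n_permutations,
          seed = substream(config$seed, 100 * match(m, MODALITIES) + g),
          paired = config$paired)
      }
      group_results[[g]] <- result_row(m, gs$group, nrow(paired), roc, op, cmp)
      details[[paste(m, gs$group, sep = ".")]] <-
        list(roc = roc, op = op, comparison = cmp)
    }

    # AI row, evaluated on the cases shared with the all-readers consensus
    if (!is.null(ai_cons)) {
      ai_set <- if (!is.null(all_cons)) {
        ai_cons[ai_cons$case_id %in% all_cons$case_id, ]
      } else {
        ai_cons
      }
      y <- unname(labels[ai_set$case_id])
      if (nrow(ai_set) >= 4 && sum(y == 1) >= 2 && sum(y == 0) >= 2) {
        roc <- delong_ci(ai_set$value, y, level = config$level)
        op <- youden_operating_point(ai_set$value, y, level = config$level)
        rows <- c(rows, list(result_row(m, "AI", nrow(ai_set), roc, op, NULL)))
        details[[paste(m, "AI", sep = ".")]] <- list(roc = roc, op = op, comparison = NULL)
      } else {
        rows <- c(rows, list(empty_row(m, "AI", n = nrow(ai_set))))
      }
    }
    rows <- c(rows, group_results)
  }

  report <- dplyr::bind_rows(rows)
  if (config$holm) {
    report <- report |>
      dplyr::group_by(.data$modality) |>
      dplyr::mutate(p_value = ifelse(is.na(.data$p_value), NA,
        stats::p.adjust(.data$p_value, method = "holm"))) |>
      dplyr::ungroup()
  }
  attr(report, "details") <- details
  attr(report, "config") <- config
  class(report) <- c("benchmark_report", class(report))
  report
}

result_row <- function(modality, group, n, roc, op, cmp) {
  tibble::tibble(
    modality = modality, group = group, n = as.integer(n),
    auroc = roc$auc, auroc_lo = roc$conf_low, auroc_hi = roc$conf_high,
    threshold = op$threshold, youden_j = op$youden_j,
    sens = op$sensitivity$estimate, sens_lo = op$sensitivity$conf_low,
    sens_hi = op$sensitivity$conf_high,
    spec = op$specificity$estimate, spec_lo = op$specificity$conf_low,
    spec_hi = op$specificity$conf_high,
    acc = op$accuracy$estimate, acc_lo = op$accuracy$conf_low,
    acc_hi = op$accuracy$conf_high,
    delta_auc = if (is.null(cmp)) NA_real_ else cmp$delta_auc,
    p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
    status = "ok")
}

#' Verify the Youden identity J = Se + Sp - 1 across a report
#'
#' Recomputes the Youden index of every row from its (pre-rounding)
#' sensitivity and specificity and checks exact equality with the reported
#' value.
#'
#' @param report A `benchmark_report` from [run_benchmark()].
#' @param tol Numeric tolerance (default `1e-10`; the identity holds to
#'   machine precision by construction).
#' @return A tibble with `modality`, `group`, `j_reported`, `j_recomputed`,
#'   `pass` (`NA` for insufficient-data rows).
#' @export
youden_identity_check <- function(report, tol = 1e-10) {
  report |>
    dplyr::transmute(
      .data$modality, .data$group,
      j_reported = .data$youden_j,
      j_recomputed = .data$sens + .data$spec - 1,
      pass = ifelse(is.na(.data$youden_j), NA,
        abs(.data$j_reported - .data$j_recomputed) <= tol))
}

#' Format a benchmark report for display
#'
#' Two-decimal, half-up rounding with `"x.xx(lo-hi)"` interval cells, one
#' row per (modality, group); internal values are kept at full precision in
#' the report itself.
#'
#' @param report A `benchmark_report` from [run_benchmark()].
#' @return A tibble of formatted strings.
#' @export
format_benchmark_report <- function(report) {
  cell <- function(est, lo, hi) {
    ifelse(is.na(est), "-", sprintf("%.2f(%.2f-%.2f)",
      round_half_up(est), round_half_up(lo), round_half_up(hi)))
  }
  report |>
    dplyr::transmute(
      .data$modality, .data$group, .data$n,
      auroc = cell(.data$auroc, .data$auroc_lo, .data$auroc_hi),
      sensitivity = cell(.data$sens, .data$sens_lo, .data$sens_hi),
      specificity = cell(.data$spec, .data$spec_lo, .data$spec_hi),
      accuracy = cell(.data$acc, .data$acc_lo, .data$acc_hi),
      threshold = ifelse(is.na(.data$threshold), "-",
        formatC(.data$threshold, digits = 2, format = "fg")),
      youden_j = ifelse(is.na(.data$youden_j), "-",
        sprintf("%.2f", round_half_up(.data$youden_j))),
      p_value = dplyr::case_when(
        is.na(.data$p_value) ~ "-",
        .data$p_value < 0.001 ~ "<0.001",
        TRUE ~ sprintf("%.3f", .data$p_value)))
}
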
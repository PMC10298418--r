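# a compact but fully populated study: enough readers per band that the
# 5-response filter keeps most cases
pipeline_study <- function(seed = 42) {
  simulate_study(study_config(
    modalities = tibble::tibble(modality = c("XRAY", "MMG"), n_cases = 40L,
      prevalence = 0.45),
    reader_counts = tibble::tibble(
      modality = rep(c("XRAY", "MMG"), each = 4),
      experience_band = rep(c("E0_1", "E1_5", "E5_10", "E10P"), 2),
      n_readers = 14L,
      n_specialists = c(rep(0L, 4), rep(7L, 4))),
    ai_models = tibble::tibble(
      model_id = c("mx1", "mx2", "mm1"),
      modality = c("XRAY", "XRAY", "MMG"),
      auc = c(0.88, 0.9, 0.89), alpha = c(1, 1.5, 0.8), beta = c(0, -0.4, 0.2)),
    set_size = 20, undefined_rate = 0.03, seed = seed))
}

test_that("the benchmark report is deterministic and structurally consistent", {
  study <- pipeline_study()
  cfg <- benchmark_config(n_permutations = 300, seed = 5)
  r1 <- suppressWarnings(run_benchmark(study$cases, study$readers,
    study$ratings, study$model_scores, cfg))
  r2 <- suppressWarnings(run_benchmark(study$cases, study$readers,
    study$ratings, study$model_scores, cfg))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # both modalities, AI + all-readers + four bands; specialists only for MMG
  expect_setequal(unique(r1$modality), c("XRAY", "MMG"))
  xray_groups <- r1$group[r1$modality == "XRAY"]
  expect_false(any(grepl("SPECIALISTS", xray_groups)))
  expect_true(all(c("SPECIALISTS_ALL", "SPECIALISTS_E1_5") %in%
    r1$group[r1$modality == "MMG"]))
  # the AI row carries no self-comparison
  expect_true(all(is.na(r1$p_value[r1$group == "AI"])))
  ok <- r1[r1$status == "ok" & r1$group != "AI", ]
  expect_true(all(!is.na(ok$p_value)))
  expect_true(all(ok$p_value >= 1 / 301))
  # n is the paired set size, bounded by the modality's case count
  expect_true(all(r1$n <= 40))
})

test_that("the Youden identity holds exactly on every computed row", {
  study <- pipeline_study()
  report <- suppressWarnings(run_benchmark(study$cases, study$readers,
    study$ratings, study$model_scores,
    benchmark_config(n_permutations = 100, seed = 2)))
  chk <- youden_identity_check(report)
  expect_true(all(chk$pass[!is.na(chk$pass)]))
  expect_gt(sum(!is.na(chk$pass)), 4)
})

test_that("duplication of the whole panel leaves all consensus values unchanged", {
  study <- pipeline_study(seed = 7)
  base <- reader_consensus(study$ratings, apply_min_filter = FALSE)
  doubled <- dplyr::bind_rows(
    study$ratings,
    dplyr::mutate(study$ratings, reader_id = paste0(reader_id, "_copy")))
  dup <- reader_consensus(doubled, apply_min_filter = FALSE)
  merged <- merge(base, dup, by = "case_id", suffixes = c("_base", "_dup"))
  keep <- !merged$excluded_base & !merged$excluded_dup
  expect_true(any(keep))
  expect_equal(merged$value_base[keep], merged$value_dup[keep])
})

test_that("duplicating a median-scoring reader preserves odd-n consensus values", {
  # three readers, consensus 4; duplicating the median reader keeps it
  rt <- tibble::tibble(reader_id = c("a", "b", "c"), case_id = "c1",
    score = c(2L, 4L, 5L))
  base <- reader_consensus(rt, apply_min_filter = FALSE)
  dup <- reader_consensus(dplyr::bind_rows(rt,
    tibble::tibble(reader_id = "b2", case_id = "c1", score = 4L)),
    apply_min_filter = FALSE)
  expect_equal(dup$value, base$value)
})

test_that("degenerate groups yield insufficient-data rows, not failures", {
  # every rating undefined -> all cases excluded by the >50% rule
  cases <- tibble::tibble(case_id = paste0("c", 1:10), modality = "XRAY",
    label = rep(0:1, 5))
  readers <- tibble::tibble(reader_id = paste0("r", 1:6),
    experience_band = "E1_5", breast_specialist = FALSE)
  ratings <- tidyr::expand_grid(reader_id = readers$reader_id,
    case_id = cases$case_id)
  ratings$score <- 3L
  scores <- tibble::tibble(model_id = "m1", case_id = cases$case_id,
    prob = seq(0.05, 0.95, length.out = 10))
  report <- run_benchmark(cases, readers, ratings, scores,
    benchmark_config(n_permutations = 50, seed = 1))
  all_row <- report[report$group == "ALL_READERS", ]
  expect_identical(all_row$status, "insufficient_data")
  expect_true(is.na(all_row$auroc))
})

test_that("a modality without AI scores warns and omits comparisons", {
  study <- pipeline_study(seed = 9)
  no_mmg_ai <- study$model_scores[grepl("XRAY", study$model_scores$case_id), ]
  warnings_seen <- capture_warnings(
    report <- run_benchmark(study$cases, study$readers, study$ratings,
      no_mmg_ai, benchmark_config(n_permutations = 50, seed = 1)))
  expect_true(any(grepl("MMG", warnings_seen)))
  mmg <- report[report$modality == "MMG", ]
  expect_false("AI" %in% mmg$group)
  expect_true(all(is.na(mmg$p_value)))
  xray <- report[report$modality == "XRAY" & report$status == "ok" &
    report$group != "AI", ]
  expect_true(all(!is.na(xray$p_value)))
})

test_that("a perfectly separating consensus reports AUROC 1 and J 1", {
  cases <- tibble::tibble(case_id = paste0("c", 1:12), modality = "XRAY",
    label = rep(0:1, each = 6))
  readers <- tibble::tibble(reader_id = paste0("r", 1:5),
    experience_band = "E10P", breast_specialist = FALSE)
  ratings <- tidyr::expand_grid(reader_id = readers$reader_id,
    case_id = cases$case_id)
  ratings$score <- ifelse(ratings$case_id %in% cases$case_id[cases$label == 1], 5L, 1L)
  scores <- tibble::tibble(model_id = "m1", case_id = cases$case_id,
    prob = c(seq(0.1, 0.4, length.out = 6), seq(0.5, 0.9, length.out = 6)))
  suppressWarnings(
    report <- run_benchmark(cases, readers, ratings, scores,
      benchmark_config(n_permutations = 100, seed = 3)))
  row <- report[report$group == "E10P", ]
  expect_equal(row$auroc, 1)
  expect_equal(row$youden_j, 1)
})

test_that("formatted reports round half-up to two decimals", {
  study <- pipeline_study(seed = 12)
  report <- suppressWarnings(run_benchmark(study$cases, study$readers,
    study$ratings, study$model_scores,
    benchmark_config(n_permutations = 50, seed = 4)))
  fmt <- format_benchmark_report(report)
  expect_match(fmt$auroc[fmt$group == "AI"][1],
    "^\\d\\.\\d{2}\\(\\d\\.\\d{2}-\\d\\.\\d{2}\\)$")
  # the autoplot method returns a ggplot
  expect_s3_class(autoplot(report), "ggplot")
})
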
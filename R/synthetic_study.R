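#' Configuration for a synthetic reader-vs-AI study
#'
#' Builds the parameter set for the synthetic study generator. The defaults
#' emulate a three-modality screening benchmark: enriched case mixes of
#' 140 chest X-ray (47 with pathology), 184 fluorography (84) and 269
#' mammography (167) cases, reader panels of four experience bands with
#' experience-dependent accuracy, a breast-specialist subgroup for
#' mammography, and per-modality ensembles of AI models returning abnormality
#' probabilities rounded to 0.01.
#'
#' Readers and AI models are simulated from an equal-variance binormal latent
#' model: a case with label \eqn{y} yields a latent \eqn{z \sim N(y\,d, 1)}
#' with \eqn{d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})}, so the latent AUC equals
#' the configured target exactly. Readers discretise \eqn{z} through four
#' thresholds placed symmetrically about \eqn{d/2} (inner spacing 0.75 SD)
#' into scores 1..5, and independently replace their score by 3 ("undefined")
#' with probability `undefined_rate`. Models pass \eqn{z} through a per-model
#' logistic distortion `plogis(alpha * z + beta)` — strictly increasing, so
#' the model's ROC is untouched — and round to 2 decimals.
#'
#' @param modalities Tibble with columns `modality`, `n_cases`, `prevalence`.
#' @param reader_counts Tibble with columns `modality`, `experience_band`,
#'   `n_readers`, `n_specialists` (`n_specialists <= n_readers`).
#' @param reader_auc Named numeric: target AUC per experience band, each in
#'   (0.5, 1).
#' @param ai_models Tibble with columns `model_id`, `modality`, `auc`,
#'   `alpha`, `beta` (`alpha > 0`).
#' @param set_size Number of cases each reader rates: 20, 50 or 80.
#' @param undefined_rate Probability a rating is replaced by 3, in \[0, 1\]
#'   (1 is the degenerate all-undefined study).
#' @param seed Integer seed; all `simulate_*` output is reproducible from
#'   (config, seed).
#' @return An object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(set_size = 20, seed = 1)
#' cfg$modalities
#' @export
study_config <- function(modalities = default_modalities(),
                         reader_counts = default_reader_counts(),
                         reader_auc = c(E0_1 = 0.87, E1_5 = 0.92, E5_10 = 0.93, E10P = 0.98),
                         ai_models = default_ai_models(),
                         set_size = 50,
                         undefined_rate = 0.03,
                         seed = 20201127) {
  modalities <- tibble::as_tibble(modalities)
  reader_counts <- tibble::as_tibble(reader_counts)
  ai_models <- tibble::as_tibble(ai_models)

  stopifnot(
    all(c("modality", "n_cases", "prevalence") %in% names(modalities)),
    all(c("modality", "experience_band", "n_readers", "n_specialists") %in% names(reader_counts)),
    all(c("model_id", "modality", "auc", "alpha", "beta") %in% names(ai_models))
  )
  if (any(modalities$prevalence <= 0 | modalities$prevalence >= 1)) {
    abort("`prevalence` must lie in (0, 1).", class = "readerbench_config_error")
  }
  if (any(reader_auc <= 0.5 | reader_auc >= 1) || any(ai_models$auc <= 0.5 | ai_models$auc >= 1)) {
    abort("All target AUCs must lie in (0.5, 1).", class = "readerbench_config_error")
  }
  if (!set_size %in% c(20, 50, 80)) {
    abort("`set_size` must be one of 20, 50, 80.", class = "readerbench_config_error")
  }
  if (any(set_size > modalities$n_cases)) {
    abort("`set_size` exceeds `n_cases` for at least one modality.",
      class = "readerbench_config_error")
  }
  if (undefined_rate < 0 || undefined_rate > 1) {
    abort("`undefined_rate` must lie in [0, 1].", class = "readerbench_config_error")
  }
  if (!all(names(reader_auc) %in% EXPERIENCE_BANDS) ||
      !all(reader_counts$experience_band %in% names(reader_auc))) {
    abort("`reader_auc` must be named by the experience bands in `reader_counts`.",
      class = "readerbench_config_error")
  }
  if (any(reader_counts$n_specialists > reader_counts$n_readers)) {
    abort("`n_specialists` cannot exceed `n_readers`.", class = "readerbench_config_error")
  }
  structure(
    list(modalities = modalities, reader_counts = reader_counts,
      reader_auc = reader_auc, ai_models = ai_models, set_size = set_size,
      undefined_rate = undefined_rate, seed = as.integer(seed)),
    class = "study_config")
}

#' @rdname study_config
#' @export
default_modalities <- function() {
  tibble::tibble(
    modality   = c("XRAY", "FLG", "MMG"),
    n_cases    = c(140L, 184L, 269L),
    prevalence = c(47 / 140, 84 / 184, 167 / 269))
}

#' @rdname study_config
#' @export
default_reader_counts <- function() {
  tibble::tibble(
    modality        = rep(c("XRAY", "FLG", "MMG"), each = 4),
    experience_band = rep(EXPERIENCE_BANDS, 3),
    n_readers       = c(36L, 60L, 36L, 53L, 6L, 8L, 5L, 9L, 16L, 32L, 28L, 37L),
    n_specialists   = c(rep(0L, 8), 15L, 28L, 24L, 29L))
}

#' @rdname study_config
#' @export
default_ai_models <- function() {
  tibble::tibble(
    model_id = c("ai_xray_1", "ai_xray_2", "ai_xray_3", "ai_xray_4",
                 "ai_flg_1", "ai_flg_2", "ai_mmg_1", "ai_mmg_2"),
    modality = c("XRAY", "XRAY", "XRAY", "XRAY", "FLG", "FLG", "MMG", "MMG"),
    auc      = c(0.92, 0.90, 0.88, 0.86, 0.82, 0.84, 0.88, 0.90),
    alpha    = c(1.0, 0.7, 1.4, 0.5, 1.0, 1.8, 0.8, 1.2),
    beta     = c(0, -0.5, 0.4, 0.8, 0, -0.8, 0.3, -0.2))
}

# latent class separation giving a binormal AUC of `auc`
latent_separation <- function(auc) sqrt(2) * qnorm(auc)

# rating thresholds: symmetric about d/2, inner spacing 0.75 SD
rating_thresholds <- function(d) d / 2 + 0.75 * c(-1.5, -0.5, 0.5, 1.5)

age_sex_params <- list(
  XRAY = list(age_mean = 49, age_sd = 18, p_sex = c(M = 59, F = 77, UNKNOWN = 4)),
  FLG  = list(age_mean = 53, age_sd = 19, p_sex = c(M = 94, F = 113, UNKNOWN = 4)),
  MMG  = list(age_mean = 63, age_sd = 6,  p_sex = c(M = 0, F = 1, UNKNOWN = 0)))

#' Simulate the labelled case set of a synthetic study
#'
#' Generates exactly `n_cases` cases per modality with a fixed number of
#' positives, `round(n_cases * prevalence)` — a fixed-margin (enriched)
#' design, not Bernoulli sampling — plus plausible age/sex metadata.
#'
#' @param config A [study_config()].
#' @return A tibble in the `cases` schema (`case_id`, `modality`, `label`,
#'   `age`, `sex`), deterministic given `config$seed`.
#' @export
simulate_cases <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(substream(config$seed, 1), {
    purrr::pmap_dfr(config$modalities, function(modality, n_cases, prevalence) {
      n_pos <- round(n_cases * prevalence)
      label <- sample(c(rep(1L, n_pos), rep(0L, n_cases - n_pos)))
      ps <- age_sex_params[[modality]]
      age <- round(pmin(pmax(rnorm(n_cases, ps$age_mean, ps$age_sd), 18), 95))
      sex <- sample(names(ps$p_sex), n_cases, replace = TRUE, prob = ps$p_sex / sum(ps$p_sex))
      tibble::tibble(
        case_id = sprintf("%s-%04d", modality, seq_len(n_cases)),
        modality = modality, label = label, age = age, sex = sex)
    })
  })
}

#' Simulate the reader panel of a synthetic study
#'
#' One profile per reader, with experience band and breast-specialist flag
#' drawn from `config$reader_counts`. A `modality` column (beyond the
#' `readers` schema) records which modality's case set the reader rates.
#'
#' @param config A [study_config()].
#' @return A tibble in the `readers` schema plus a `modality` column.
#' @export
simulate_readers <- function(config) {
  stopifnot(inherits(config, "study_config"))
  countries <- c(RU = 141, UA = 17, BY = 11, KZ = 6, KG = 2, MD = 2, UZ = 2,
                 AM = 1, AZ = 1, GE = 1, LV = 1)
  with_seed(substream(config$seed, 2), {
    out <- purrr::pmap_dfr(config$reader_counts,
      function(modality, experience_band, n_readers, n_specialists) {
        if (n_readers == 0) return(NULL)
        tibble::tibble(
          modality = modality, experience_band = experience_band,
          breast_specialist = seq_len(n_readers) <= n_specialists)
      })
    out$reader_id <- sprintf("R%03d", seq_len(nrow(out)))
    out$country <- sample(names(countries), nrow(out), replace = TRUE,
      prob = countries / sum(countries))
    out[c("reader_id", "experience_band", "breast_specialist", "country", "modality")]
  })
}

#' Simulate per-reader Likert ratings
#'
#' Each reader is assigned a uniformly random subset of `set_size` cases of
#' their modality. For an assigned case with label \eqn{y} the reader draws
#' \eqn{z \sim N(y\,d, 1)} with \eqn{d = \sqrt{2}\,\Phi^{-1}(a)} for the
#' band's target AUC \eqn{a}, and the score is `1 + #`\{thresholds `<= z`\}
#' for four thresholds symmetric about \eqn{d/2}. Independently, with
#' probability `undefined_rate` the score is replaced by 3 ("undefined").
#' Readers are conditionally independent given the label.
#'
#' @param cases Tibble from [simulate_cases()] (or any `cases` table).
#' @param readers Tibble from [simulate_readers()]; must carry a `modality`
#'   column.
#' @param config A [study_config()].
#' @return A tibble in the `ratings` schema, deterministic given
#'   `config$seed`.
#' @export
simulate_reader_ratings <- function(cases, readers, config) {
  stopifnot(inherits(config, "study_config"))
  if (!"modality" %in% names(readers)) {
    abort("`readers` must have a `modality` column assigning each reader a case set.",
      class = "readerbench_config_error")
  }
  avail <- table(cases$modality)[unique(readers$modality)]
  if (any(is.na(avail)) || any(config$set_size > avail)) {
    abort("`set_size` exceeds the number of available cases for some modality.",
      class = "readerbench_config_error")
  }
  with_seed(substream(config$seed, 3), {
    purrr::pmap_dfr(readers[c("reader_id", "experience_band", "modality")],
      function(reader_id, experience_band, modality) {
        cm <- cases[cases$modality == modality, ]
        idx <- sample(nrow(cm), config$set_size)
        d <- latent_separation(config$reader_auc[[experience_band]])
        thr <- rating_thresholds(d)
        z <- rnorm(config$set_size, cm$label[idx] * d)
        score <- 1L + rowSums(outer(z, thr, ">="))
        undef <- runif(config$set_size) < config$undefined_rate
        score[undef] <- 3L
        tibble::tibble(reader_id = reader_id, case_id = cm$case_id[idx],
          score = as.integer(score))
      })
  })
}

#' Simulate AI model abnormality scores
#'
#' Every model scores every case of its modality: the binormal latent
#' \eqn{z \sim N(y\,d, 1)} is passed through the model's strictly increasing
#' logistic distortion `plogis(alpha * z + beta)` and rounded to two
#' decimals (scores are reported at 0.01 precision).
#'
#' @param cases Tibble from [simulate_cases()] (or any `cases` table).
#' @param config A [study_config()].
#' @return A tibble in the `model_scores` schema, deterministic given
#'   `config$seed`.
#' @export
simulate_model_scores <- function(cases, config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(substream(config$seed, 4), {
    purrr::pmap_dfr(config$ai_models, function(model_id, modality, auc, alpha, beta) {
      cm <- cases[cases$modality == modality, ]
      if (nrow(cm) == 0) return(NULL)
      z <- rnorm(nrow(cm), cm$label * latent_separation(auc))
      tibble::tibble(model_id = model_id, case_id = cm$case_id,
        prob = round(stats::plogis(alpha * z + beta), 2))
    })
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_cases()], [simulate_readers()], [simulate_reader_ratings()]
#' and [simulate_model_scores()] under one configuration.
#'
#' @param config A [study_config()].
#' @return A list of class `reader_study` with elements `cases`, `readers`,
#'   `ratings`, `model_scores` (tibbles) and `config`.
#' @examples
#' study <- simulate_study(study_config(set_size = 20, seed = 7))
#' vapply(study[1:4], nrow, integer(1))
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cases <- simulate_cases(config)
  readers <- simulate_readers(config)
  structure(
    list(cases = cases, readers = readers,
      ratings = simulate_reader_ratings(cases, readers, config),
      model_scores = simulate_model_scores(cases, config),
      config = config),
    class = "reader_study")
}

#' @export
print.reader_study <- function(x, ...) {
  cat("<reader_study>\n")
  cat("  cases:        ", nrow(x$cases), " (",
    sum(x$cases$label), " with pathology)\n", sep = "")
  cat("  readers:      ", nrow(x$readers), "\n", sep = "")
  cat("  ratings:      ", nrow(x$ratings), "\n", sep = "")
  cat("  model scores: ", nrow(x$model_scores), " from ",
    length(unique(x$model_scores$model_id)), " models\n", sep = "")
  invisible(x)
}

#' Write all tables of a study to a directory
#'
#' @param study A `reader_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "reader_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_study_table(study$cases, "cases", file.path(dir, "cases.csv"))
  write_study_table(study$readers, "readers", file.path(dir, "readers.csv"))
  write_study_table(study$ratings, "ratings", file.path(dir, "ratings.csv"))
  write_study_table(study$model_scores, "model_scores", file.path(dir, "model_scores.csv"))
  invisible(dir)
}
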
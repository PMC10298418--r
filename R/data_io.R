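#' Read a study table (cases, readers, ratings or model scores)
#'
#' Reads one of the four tabular study artifacts from a delimited text file
#' and validates it against its schema. The delimiter (comma or tab) is
#' sniffed from the header line; files are always written back as CSV.
#'
#' The four schemas are:
#' \describe{
#'   \item{cases}{`case_id`, `modality` (XRAY/FLG/MMG), `label` (0/1 or the
#'     strings "with pathology"/"without pathology"), optional `age`, `sex`.}
#'   \item{readers}{`reader_id`, `experience_band` (E0_1/E1_5/E5_10/E10P),
#'     `breast_specialist` (logical), optional `country`.}
#'   \item{ratings}{`reader_id`, `case_id`, `score` (integer 1..5; 3 means
#'     "undefined").}
#'   \item{model_scores}{`model_id`, `case_id`, `prob` (probability of
#'     pathology in \[0, 1\]).}
#' }
#'
#' Higher score/probability always means more likely pathological.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"cases"`, `"readers"`, `"ratings"`, `"model_scores"`.
#' @return A validated tibble with the schema's columns (extra columns are
#'   preserved). Row order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("reader_id,case_id,score", "r1,c1,5", "r1,c2,1"), tf)
#' read_study_table(tf, "ratings")
#' @export
read_study_table <- function(path, schema = c("cases", "readers", "ratings", "model_scores")) {
  schema <- rlang::arg_match(schema)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "readerbench_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE, col_types = readr::cols(.default = readr::col_character()))
  validate_study_table(df, schema, source = path)
}

schema_columns <- list(
  cases        = c("case_id", "modality", "label"),
  readers      = c("reader_id", "experience_band", "breast_specialist"),
  ratings      = c("reader_id", "case_id", "score"),
  model_scores = c("model_id", "case_id", "prob")
)

schema_keys <- list(
  cases        = "case_id",
  readers      = "reader_id",
  ratings      = c("reader_id", "case_id"),
  model_scores = c("model_id", "case_id")
)

#' Validate a study table against one of the four schemas
#'
#' Called by [read_study_table()]; exported so in-memory tables (for example
#' from [simulate_study()]) can be checked with the same rules. Raises a
#' typed condition on the first violation; malformed rows are never dropped
#' silently.
#'
#' @param df A data frame.
#' @inheritParams read_study_table
#' @param source Label used in error messages (defaults to "data frame").
#' @return The validated tibble, with typed columns.
#' @export
validate_study_table <- function(df, schema = c("cases", "readers", "ratings", "model_scores"),
                                 source = "data frame") {
  schema <- rlang::arg_match(schema)
  required <- schema_columns[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(source, ": missing required column(s) for schema '", schema, "': ",
        paste(missing, collapse = ", ")),
      class = "readerbench_schema_error")
  }
  df <- tibble::as_tibble(df)

  fail_rows <- function(bad, what) {
    abort(
      paste0(source, ": ", what, " in row(s) ",
        paste(head(which(bad), 5), collapse = ", "),
        if (sum(bad) > 5) paste0(" (and ", sum(bad) - 5, " more)") else ""),
      class = "readerbench_validation_error")
  }

  if (schema == "cases") {
    df$modality <- toupper(as.character(df$modality))
    bad <- !df$modality %in% MODALITIES
    if (any(bad)) fail_rows(bad, "modality not one of XRAY/FLG/MMG")
    lab <- as.character(df$label)
    lab[tolower(lab) %in% c("with pathology", "pathology", "abnormal")] <- "1"
    lab[tolower(lab) %in% c("without pathology", "no pathology", "normal")] <- "0"
    bad <- !lab %in% c("0", "1")
    if (any(bad)) fail_rows(bad, "label not binary (0/1 or with/without pathology)")
    df$label <- as.integer(lab)
    if ("age" %in% names(df)) df$age <- suppressWarnings(as.numeric(df$age))
    if ("sex" %in% names(df)) {
      df$sex <- toupper(as.character(df$sex))
      bad <- !(df$sex %in% c("M", "F", "UNKNOWN") | is.na(df$sex))
      if (any(bad)) fail_rows(bad, "sex not one of M/F/unknown")
    }
  } else if (schema == "readers") {
    bad <- !df$experience_band %in% EXPERIENCE_BANDS
    if (any(bad)) fail_rows(bad, "experience_band not one of E0_1/E1_5/E5_10/E10P")
    bs <- tolower(as.character(df$breast_specialist))
    bad <- !bs %in% c("true", "false", "t", "f", "1", "0")
    if (any(bad)) fail_rows(bad, "breast_specialist not logical")
    df$breast_specialist <- bs %in% c("true", "t", "1")
  } else if (schema == "ratings") {
    sc <- suppressWarnings(as.numeric(df$score))
    bad <- is.na(sc) | !sc %in% 1:5
    if (any(bad)) fail_rows(bad, "score not an integer in 1..5")
    df$score <- as.integer(sc)
  } else if (schema == "model_scores") {
    pr <- suppressWarnings(as.numeric(df$prob))
    bad <- is.na(pr) | pr < 0 | pr > 1
    if (any(bad)) fail_rows(bad, "prob not in [0, 1]")
    df$prob <- pr
  }

  keys <- schema_keys[[schema]]
  keyed <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(keyed)) {
    dup <- unique(keyed[duplicated(keyed)])
    abort(
      paste0(source, ": duplicate ", paste(keys, collapse = "+"), " key(s): ",
        paste(gsub("\r", "/", head(dup, 5)), collapse = ", ")),
      class = "readerbench_validation_error")
  }
  df
}

#' Write a study table as CSV
#'
#' Validates `df` against the schema, then writes a comma-delimited file so
#' that [read_study_table()] round-trips it exactly.
#'
#' @inheritParams validate_study_table
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(df, schema = c("cases", "readers", "ratings", "model_scores"), path) {
  schema <- rlang::arg_match(schema)
  df <- validate_study_table(df, schema)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

report_columns <- c(
  "modality", "group", "n", "auroc", "auroc_lo", "auroc_hi", "threshold",
  "youden_j", "sens", "sens_lo", "sens_hi", "spec", "spec_lo", "spec_hi",
  "acc", "acc_lo", "acc_hi", "p_value")

#' Write a benchmark report as CSV
#'
#' Writes one row per (modality, group) with AUROC, sensitivity, specificity
#' and accuracy plus their 95\% confidence bounds, the operating threshold,
#' the Youden index and the permutation p-value, at full precision, so that
#' [read_report()] reproduces the values exactly. Use
#' [format_benchmark_report()] for a display table with `"x.xx(lo-hi)"` cells.
#'
#' @param report A tibble from [run_benchmark()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (nrow(report) == 0) {
    warn("Writing an empty benchmark report (header only).")
  }
  missing <- setdiff(report_columns, names(report))
  if (length(missing) > 0) {
    abort(paste0("Report is missing column(s): ", paste(missing, collapse = ", ")),
      class = "readerbench_schema_error")
  }
  readr::write_csv(report[report_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a benchmark report written by [write_report()]
#'
#' @param path Path to a report CSV.
#' @return A tibble with the report columns.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "readerbench_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      modality = readr::col_character(),
      group = readr::col_character(),
      n = readr::col_integer(),
      .default = readr::col_double()))
  missing <- setdiff(report_columns, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, ": not a benchmark report; missing column(s): ",
      paste(missing, collapse = ", ")), class = "readerbench_schema_error")
  }
  df
}
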
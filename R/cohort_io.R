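#' Default column mapping for cohort CSV files
#'
#' Maps the package's logical field names to source column names and
#' supplies label dictionaries for sex and region. Any entry can be
#' replaced, e.g. `default_column_mapping(glucose = "FBG", sex = "GENDER")`.
#'
#' @param ... named overrides of individual mapping entries.
#' @return named list with one source-column name per logical field
#'   (`glucose`, `sbp`, `dbp`, `triglycerides`, `hdl`, `waist`, `sex`,
#'   `region`, `age`, `race`, `id`) plus `sex_labels` and `region_labels`
#'   dictionaries.
#' @export
default_column_mapping <- function(...) {
  m <- list(
    glucose = "glucose", sbp = "sbp", dbp = "dbp",
    triglycerides = "triglycerides", hdl = "hdl", waist = "waist",
    sex = "sex", region = "region", age = "age", race = "race", id = "id",
    sex_labels = c(male = "male", m = "male", "1" = "male",
                   female = "female", f = "female", "2" = "female"),
    region_labels = c(korean = "korean", kr = "korean",
                      american = "american", us = "american")
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(m))
  if (length(bad) > 0) {
    stop("unknown mapping entr(y/ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m[names(ov)] <- ov
  m
}

#' Read and validate a cohort CSV
#'
#' Reads one subject per row, renames columns through `mapping`, normalizes
#' sex/region labels, and rejects rows that cannot be scored: a missing or
#' non-numeric measurement, a non-positive measurement, systolic pressure
#' not exceeding diastolic, or an unrecognized sex label. The first failing
#' rule per row is reported. Absent region defaults to `"korean"` with a
#' warning.
#'
#' @param path CSV file with a header row.
#' @param mapping a [default_column_mapping()] list.
#' @param row_filter optional one-sided formula, e.g. `~ age <= 80`,
#'   evaluated on the renamed data; rows where it is not `TRUE` are
#'   rejected with reason `"filtered"`. Off by default: cohort-specific
#'   exclusions are the caller's policy, not score logic.
#' @return list with `data` (tibble of valid `SubjectRecord` rows, canonical
#'   column names) and `report`, a `validation_report` with `n_read`,
#'   `n_valid`, `n_rejected` and a `rejections` tibble of (row, id, reason).
#' @export
read_cohort <- function(path, mapping = default_column_mapping(),
                        row_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)

  meas <- c("glucose", "sbp", "dbp", "triglycerides", "hdl", "waist")
  mandatory <- c(meas, "sex")
  src <- vapply(mandatory, function(f) mapping[[f]], character(1))
  missing_cols <- src[!src %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n_read <- nrow(raw)
  df <- tibble::tibble(.rows = n_read)
  for (f in c(meas, "sex", "region", "age", "race", "id")) {
    col <- mapping[[f]]
    df[[f]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  for (f in meas) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  df$age <- suppressWarnings(as.numeric(df$age))
  if (all(is.na(df$id))) df$id <- as.character(seq_len(n_read))

  sex_dict <- mapping$sex_labels
  region_dict <- mapping$region_labels
  df$sex <- unname(sex_dict[tolower(trimws(df$sex))])
  region_raw <- tolower(trimws(df$region))
  df$region <- unname(region_dict[region_raw])
  if (n_read > 0 && all(is.na(region_raw) | region_raw == "")) {
    warning("no region column/values: defaulting to 'korean'", call. = FALSE)
  }
  df$region[is.na(df$region)] <- "korean"

  # first failing rule per row, in a fixed precedence order
  reason <- rep(NA_character_, n_read)
  for (f in meas) {
    reason <- ifelse(is.na(reason) & is.na(df[[f]]),
                     paste0("missing or non-numeric ", f), reason)
  }
  for (f in meas) {
    reason <- ifelse(is.na(reason) & df[[f]] <= 0,
                     paste0("non-positive ", f), reason)
  }
  reason <- ifelse(is.na(reason) & df$sbp <= df$dbp, "implausible bp", reason)
  reason <- ifelse(is.na(reason) & is.na(df$sex), "unrecognized sex", reason)
  if (!is.null(row_filter)) {
    stopifnot(inherits(row_filter, "formula"))
    keep <- eval(row_filter[[2]], envir = df, enclos = environment(row_filter))
    reason <- ifelse(is.na(reason) & !(keep %in% TRUE), "filtered", reason)
  }

  ok <- is.na(reason)
  rejections <- tibble::tibble(
    row = which(!ok),
    id = df$id[!ok],
    reason = reason[!ok]
  )
  report <- structure(
    list(n_read = n_read, n_valid = sum(ok), n_rejected = sum(!ok),
         rejections = rejections),
    class = "validation_report"
  )
  list(data = df[ok, , drop = FALSE], report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("cohort validation: %d read, %d valid, %d rejected\n",
              x$n_read, x$n_valid, x$n_rejected))
  if (x$n_rejected > 0) {
    tab <- table(x$rejections$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Write scored subjects to CSV
#'
#' Writes a [score_cohort()] result with a deterministic column order: the
#' input columns first, then the scaled axes, RMRS, count, and the two
#' diagnoses. Scores are stored at full precision unless `digits` is given
#' (half-away-from-zero rounding, a presentation choice only).
#'
#' @param scored tibble returned by [score_cohort()].
#' @param path output CSV path.
#' @param digits optional decimal places for score columns.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scored, path, digits = NULL) {
  score_cols <- c(paste0("s_", rmrs_factors()), "rmrs")
  lead <- setdiff(names(scored),
                  c(score_cols, "risk_factor_count", "mets_by_count",
                    "mets_by_rmrs"))
  ordered <- scored[c(lead,
                      intersect(score_cols, names(scored)),
                      intersect(c("risk_factor_count", "mets_by_count",
                                  "mets_by_rmrs"), names(scored)))]
  if (!is.null(digits)) {
    for (col in intersect(score_cols, names(ordered))) {
      ordered[[col]] <- round_half_away(ordered[[col]], digits)
    }
  }
  readr::write_csv(ordered, path, progress = FALSE)
  invisible(path)
}
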
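# Per-row threshold columns for a cohort, honouring global overrides.
# Returns a tibble with one threshold column per factor plus bp_unit.
cohort_thresholds <- function(data, overrides = NULL) {
  sex <- tolower(as.character(data$sex))
  if (any(!sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female' for every row", call. = FALSE)
  }
  region <- if ("region" %in% names(data) && !all(is.na(data$region))) {
    r <- tolower(as.character(data$region))
    r[is.na(r)] <- "korean"
    r
  } else {
    rep("korean", nrow(data))
  }
  if (any(!region %in% c("korean", "american"))) {
    stop("`region` must be 'korean' or 'american'", call. = FALSE)
  }

  ov <- overrides %||% list()
  pick <- function(key, default) if (!is.null(ov[[key]])) ov[[key]] else default

  hdl <- pick("hdl_mgdl", ifelse(sex == "male", 40, 50))
  waist_default <- ifelse(region == "american",
                          ifelse(sex == "male", 102, 88),
                          ifelse(sex == "male", 90, 85))
  waist <- pick("waist_cm", waist_default)
  sbp <- pick("sbp_mmhg", 130)
  dbp <- pick("dbp_mmhg", 85)

  tibble::tibble(
    glucose_mgdl = rep_len(pick("glucose_mgdl", 100), nrow(data)),
    sbp_mmhg = rep_len(sbp, nrow(data)),
    dbp_mmhg = rep_len(dbp, nrow(data)),
    triglycerides_mgdl = rep_len(pick("triglycerides_mgdl", 150), nrow(data)),
    hdl_mgdl = rep_len(hdl, nrow(data)),
    waist_cm = rep_len(waist, nrow(data)),
    bp_unit_mmhg = rep_len(0.1 * abs(dbp - sbp), nrow(data))
  )
}

#' Count abnormal MetS risk factors
#'
#' Applies the diagnostic inequalities in raw measurement space: glucose
#' >= 100 mg/dl; systolic BP >= 130 or diastolic BP >= 85 mmHg;
#' triglycerides >= 150 mg/dl; HDL strictly below the sex-specific cutpoint;
#' waist at or above the region/sex-specific cutpoint. Three or more
#' abnormal factors constitute the count-based MetS diagnosis.
#'
#' @param data data frame with columns `glucose`, `sbp`, `dbp`,
#'   `triglycerides`, `hdl`, `waist`, `sex` and optionally `region`
#'   (default `"korean"`).
#' @param overrides optional named list of cutpoint overrides (see
#'   [mets_thresholds()]).
#' @return integer vector of counts in 0..5.
#' @export
count_risk_factors <- function(data, overrides = NULL) {
  data <- tibble::as_tibble(data)
  th <- cohort_thresholds(data, overrides)
  as.integer(
    (data$glucose >= th$glucose_mgdl) +
    (data$sbp >= th$sbp_mmhg | data$dbp >= th$dbp_mmhg) +
    (data$triglycerides >= th$triglycerides_mgdl) +
    (data$hdl < th$hdl_mgdl) +
    (data$waist >= th$waist_cm)
  )
}

#' Score a whole cohort
#'
#' Scales every subject's five factors onto the unit radar axes, computes the
#' RMRS over all ten factor triads, counts abnormal factors in raw space,
#' and applies both diagnostic rules.
#'
#' @inheritParams count_risk_factors
#' @param diagnostic_threshold fixed RMRS cutoff; default 0.547 (see
#'   [derive_diagnostic_threshold()]). Diagnosis is positive when
#'   `rmrs >= diagnostic_threshold`.
#' @param explain if `TRUE`, also attach the summed per-triad interaction
#'   masses `i_p_total` and `i_n_total` and the number of triads in each
#'   decomposition case (`n_case1` .. `n_case4`), from [tas_decompose()].
#' @return the input tibble with appended columns `s_gl`, `s_bp`, `s_tg`,
#'   `s_hdl`, `s_wc`, `rmrs`, `risk_factor_count`, `mets_by_count`,
#'   `mets_by_rmrs` (and the explain columns when requested).
#' @examples
#' cohort <- simulate_cohort(n = 20, seed = 1)
#' scored <- score_cohort(cohort)
#' scored[, c("rmrs", "risk_factor_count", "mets_by_rmrs")]
#' @export
score_cohort <- function(data, overrides = NULL, diagnostic_threshold = 0.547,
                         explain = FALSE) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    out <- data
    for (col in c(paste0("s_", rmrs_factors()), "rmrs")) out[[col]] <- numeric(0)
    out$risk_factor_count <- integer(0)
    out$mets_by_count <- logical(0)
    out$mets_by_rmrs <- logical(0)
    return(out)
  }
  th <- cohort_thresholds(data, overrides)

  meas <- c("glucose", "sbp", "dbp", "triglycerides", "hdl", "waist")
  miss <- setdiff(meas, names(data))
  if (length(miss) > 0) {
    stop("missing measurement column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(data[meas])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all measurements must be finite and strictly positive; ",
         "use read_cohort() to reject invalid rows", call. = FALSE)
  }
  if (any(data$sbp <= data$dbp)) {
    stop("implausible blood pressure (sbp <= dbp); ",
         "use read_cohort() to reject invalid rows", call. = FALSE)
  }

  scaled <- cbind(
    s_gl  = elliot_sigmoid((data$glucose - th$glucose_mgdl) / (0.1 * th$glucose_mgdl)),
    s_bp  = elliot_sigmoid(pmax(data$sbp - th$sbp_mmhg, data$dbp - th$dbp_mmhg) /
                             th$bp_unit_mmhg),
    s_tg  = elliot_sigmoid((data$triglycerides - th$triglycerides_mgdl) /
                             (0.1 * th$triglycerides_mgdl)),
    s_hdl = elliot_sigmoid(-(data$hdl - th$hdl_mgdl) / (0.1 * th$hdl_mgdl)),
    s_wc  = elliot_sigmoid((data$waist - th$waist_cm) / (0.1 * th$waist_cm))
  )

  out <- data
  out[colnames(scaled)] <- as.data.frame(scaled)
  out$rmrs <- rmrs_score(scaled)
  out$risk_factor_count <- count_risk_factors(data, overrides)
  out$mets_by_count <- out$risk_factor_count >= 3L
  out$mets_by_rmrs <- out$rmrs >= diagnostic_threshold

  if (explain) {
    idx <- triad_index()
    ip <- 0; iin <- 0
    case_n <- matrix(0L, nrow(out), 4)
    for (k in seq_len(nrow(idx))) {
      d <- tas_decompose(scaled[, idx[k, 1]], scaled[, idx[k, 2]],
                         scaled[, idx[k, 3]])
      ip <- ip + d$i_p
      iin <- iin + d$i_n
      for (cs in 1:4) case_n[, cs] <- case_n[, cs] + (d$case_id == cs)
    }
    out$i_p_total <- ip
    out$i_n_total <- iin
    out$n_case1 <- case_n[, 1]; out$n_case2 <- case_n[, 2]
    out$n_case3 <- case_n[, 3]; out$n_case4 <- case_n[, 4]
  }
  out
}

#' Score a single subject
#'
#' @param record named list or one-row data frame with the six measurements
#'   plus `sex` and optionally `region`.
#' @param overrides optional cutpoint overrides (see [mets_thresholds()]).
#' @param diagnostic_threshold fixed RMRS cutoff, default 0.547.
#' @return an object of class `rmrs_result`: a list with `scaled` (named
#'   length-5 vector), `triads` (the 10-row [triad_table()]), `rmrs`,
#'   `risk_factor_count`, `diagnosis_by_count`, `diagnosis_by_rmrs`, and
#'   `threshold_used`.
#' @examples
#' rec <- list(glucose = 100, sbp = 130, dbp = 85, triglycerides = 150,
#'             hdl = 40, waist = 90, sex = "male", region = "korean")
#' score_subject(rec)
#' @export
score_subject <- function(record, overrides = NULL,
                          diagnostic_threshold = 0.547) {
  record <- as.list(record)
  th <- mets_thresholds(sex = record$sex %||% "male",
                        region = record$region %||% "korean",
                        overrides = overrides)
  scaled <- scale_subject(record, th)
  df <- tibble::as_tibble(record[c("glucose", "sbp", "dbp", "triglycerides",
                                   "hdl", "waist")])
  df$sex <- tolower(record$sex %||% "male")
  df$region <- tolower(record$region %||% "korean")
  structure(
    list(
      scaled = scaled,
      triads = triad_table(scaled),
      rmrs = rmrs_score(scaled),
      risk_factor_count = count_risk_factors(df, overrides),
      diagnosis_by_count = count_risk_factors(df, overrides) >= 3L,
      diagnosis_by_rmrs = rmrs_score(scaled) >= diagnostic_threshold,
      threshold_used = diagnostic_threshold
    ),
    class = "rmrs_result"
  )
}

#' @export
print.rmrs_result <- function(x, ...) {
  cat("RMRS subject score\n")
  cat("  scaled axes:",
      paste(sprintf("%s=%.3f", names(x$scaled), x$scaled), collapse = " "),
      "\n")
  cat(sprintf("  RMRS: %.3f (cutoff %.3f) -> MetS by score: %s\n",
              x$rmrs, x$threshold_used, x$diagnosis_by_rmrs))
  cat(sprintf("  abnormal factors: %d/5 -> MetS by count: %s\n",
              x$risk_factor_count, x$diagnosis_by_count))
  invisible(x)
}
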
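#' Normalize a measurement against its diagnostic cutpoint
#'
#' Maps a raw clinical value to a dimensionless deviation Z where the
#' cutpoint sits at 0 and one unit equals 10% of the cutpoint. For factors
#' where risk grows with the value (glucose, triglycerides, waist),
#' `Z = (value - threshold) / (0.1 * threshold)`; for HDL, where lower values
#' carry risk, the sign is flipped so Z still increases with risk.
#'
#' @param value raw measurement(s), finite numeric.
#' @param threshold strictly positive cutpoint (recycled).
#' @param direction `"higher_is_risk"` (default) or `"lower_is_risk"`.
#' @return numeric vector of normalized deviations.
#' @examples
#' normalize_factor(110, 100)                       # one unit above cutpoint
#' normalize_factor(36, 40, "lower_is_risk")        # low HDL -> positive risk
#' @export
normalize_factor <- function(value, threshold,
                             direction = c("higher_is_risk", "lower_is_risk")) {
  direction <- match.arg(direction)
  if (any(!is.finite(threshold)) || any(threshold <= 0)) {
    stop("`threshold` must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(value))) {
    stop("`value` must be finite", call. = FALSE)
  }
  z <- (value - threshold) / (0.1 * threshold)
  if (direction == "lower_is_risk") -z else z
}

#' Normalize blood pressure against both cutpoints
#'
#' Blood pressure is abnormal when either the systolic or the diastolic
#' reading exceeds its cutpoint, so the larger threshold exceedance is taken
#' and divided by a common unit: 10% of the gap between the two cutpoints
#' (4.5 mmHg at the default 130/85).
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg; must satisfy `sbp > dbp`.
#' @param thresholds a [mets_thresholds()] object.
#' @return numeric vector of normalized BP deviations.
#' @examples
#' th <- mets_thresholds("male", "korean")
#' normalize_bp(130, 85, th)   # both at cutpoint -> 0
#' normalize_bp(139, 80, th)   # max(9, -5) / 4.5 -> 2
#' @export
normalize_bp <- function(sbp, dbp, thresholds) {
  stopifnot(inherits(thresholds, "mets_thresholds"))
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop("blood pressure values must be finite", call. = FALSE)
  }
  if (any(sbp <= dbp)) {
    stop("implausible blood pressure: sbp must exceed dbp", call. = FALSE)
  }
  pmax(sbp - thresholds$sbp_mmhg, dbp - thresholds$dbp_mmhg) /
    thresholds$bp_unit_mmhg
}

#' Elliot sigmoid scaling
#'
#' Bounded monotone transform `S = 0.5 * Z / (1 + |Z|) + 0.5` mapping the
#' normalized deviation onto (0, 1): the cutpoint (Z = 0) maps to 0.5 and one
#' 10%-of-cutpoint unit to 0.25 / 0.75. Symmetric about (0, 0.5) and robust
#' to outliers, which are compressed toward the bounds.
#'
#' @param z finite numeric vector of normalized deviations.
#' @return numeric vector in (0, 1).
#' @examples
#' elliot_sigmoid(c(-1, 0, 1))  # 0.25 0.50 0.75
#' @export
elliot_sigmoid <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  0.5 * z / (1 + abs(z)) + 0.5
}

#' Scale a subject's five risk factors onto the unit radar axes
#'
#' Composes [normalize_factor()] / [normalize_bp()] with [elliot_sigmoid()]
#' for all five factors, producing the scaled axis vector in canonical order
#' (glucose, blood pressure, triglycerides, HDL, waist). Every component
#' equals 0.5 exactly when the raw value sits at its cutpoint.
#'
#' @param record named list or one-row data frame with `glucose`, `sbp`,
#'   `dbp`, `triglycerides`, `hdl`, `waist` (and optionally `sex`, `region`
#'   used to resolve thresholds when `thresholds` is `NULL`).
#' @param thresholds a [mets_thresholds()] object; resolved from the record's
#'   `sex`/`region` when omitted.
#' @return named numeric vector `c(s_gl, s_bp, s_tg, s_hdl, s_wc)`.
#' @examples
#' rec <- list(glucose = 100, sbp = 130, dbp = 85, triglycerides = 150,
#'             hdl = 40, waist = 90, sex = "male", region = "korean")
#' scale_subject(rec)  # all 0.5
#' @export
scale_subject <- function(record, thresholds = NULL) {
  record <- as.list(record)
  if (is.null(thresholds)) {
    thresholds <- mets_thresholds(
      sex = record$sex %||% "male",
      region = record$region %||% "korean"
    )
  }
  need <- c("glucose", "sbp", "dbp", "triglycerides", "hdl", "waist")
  miss <- need[!vapply(need, function(f) {
    v <- record[[f]]
    !is.null(v) && is.finite(v) && v > 0
  }, logical(1))]
  if (length(miss) > 0) {
    stop("missing or non-positive measurement(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  z <- c(
    gl  = normalize_factor(record$glucose, thresholds$glucose_mgdl),
    bp  = normalize_bp(record$sbp, record$dbp, thresholds),
    tg  = normalize_factor(record$triglycerides, thresholds$triglycerides_mgdl),
    hdl = normalize_factor(record$hdl, thresholds$hdl_mgdl, "lower_is_risk"),
    wc  = normalize_factor(record$waist, thresholds$waist_cm)
  )
  s <- elliot_sigmoid(z)
  names(s) <- paste0("s_", rmrs_factors())
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
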
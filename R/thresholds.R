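#' Diagnostic cutpoints for the five MetS risk factors
#'
#' Resolves the AHA/NHLBI (revised NCEP-ATP III) diagnostic thresholds for a
#' given sex and region. Glucose, blood pressure and triglyceride cutpoints
#' are universal; the HDL cutpoint is sex-specific and the waist cutpoint is
#' region- and sex-specific (Korean waist cutpoints follow the Korean Society
#' for Obesity).
#'
#' @param sex `"male"` or `"female"`.
#' @param region `"korean"` or `"american"`; controls the waist cutpoint.
#' @param overrides optional named list (or path handled by
#'   [read_threshold_config()]) overriding any of `glucose_mgdl`, `sbp_mmhg`,
#'   `dbp_mmhg`, `triglycerides_mgdl`, `hdl_mgdl`, `waist_cm`.
#'
#' @return An object of class `mets_thresholds`: a named list with elements
#'   `glucose_mgdl` (100), `sbp_mmhg` (130), `dbp_mmhg` (85),
#'   `triglycerides_mgdl` (150), `hdl_mgdl` (40 male / 50 female),
#'   `waist_cm` (American 102/88, Korean 90/85), plus `sex`, `region` and
#'   `bp_unit_mmhg`, the normalization unit for blood pressure
#'   (10% of |dbp cutpoint - sbp cutpoint|, 4.5 mmHg at defaults).
#'
#' @examples
#' mets_thresholds("male", "korean")
#' mets_thresholds("female", "american", overrides = list(waist_cm = 90))
#' @export
mets_thresholds <- function(sex = c("male", "female"),
                            region = c("korean", "american"),
                            overrides = NULL) {
  sex <- match.arg(tolower(sex[1]), c("male", "female"))
  region <- match.arg(tolower(region[1]), c("korean", "american"))

  hdl <- if (sex == "male") 40 else 50
  waist <- switch(region,
    american = if (sex == "male") 102 else 88,
    korean   = if (sex == "male") 90 else 85
  )

  th <- list(
    glucose_mgdl = 100,
    sbp_mmhg = 130,
    dbp_mmhg = 85,
    triglycerides_mgdl = 150,
    hdl_mgdl = hdl,
    waist_cm = waist
  )

  if (!is.null(overrides)) {
    if (!is.list(overrides)) stop("`overrides` must be a named list", call. = FALSE)
    bad <- setdiff(names(overrides), names(th))
    if (length(bad) > 0) {
      stop("unknown threshold override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    th[names(overrides)] <- overrides
  }

  vals <- unlist(th)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be finite and strictly positive", call. = FALSE)
  }
  bp_span <- abs(th$dbp_mmhg - th$sbp_mmhg)
  if (bp_span <= 0) {
    stop("systolic and diastolic cutpoints must differ", call. = FALSE)
  }

  structure(
    c(th, list(sex = sex, region = region, bp_unit_mmhg = 0.1 * bp_span)),
    class = "mets_thresholds"
  )
}

#' @export
print.mets_thresholds <- function(x, ...) {
  cat("MetS diagnostic thresholds (", x$sex, ", ", x$region, ")\n", sep = "")
  cat("  glucose       >= ", x$glucose_mgdl, " mg/dl\n", sep = "")
  cat("  blood pressure>= ", x$sbp_mmhg, "/", x$dbp_mmhg, " mmHg (unit ",
      x$bp_unit_mmhg, " mmHg)\n", sep = "")
  cat("  triglycerides >= ", x$triglycerides_mgdl, " mg/dl\n", sep = "")
  cat("  HDL           <  ", x$hdl_mgdl, " mg/dl\n", sep = "")
  cat("  waist         >= ", x$waist_cm, " cm\n", sep = "")
  invisible(x)
}

#' Read a threshold / scoring configuration file
#'
#' Reads a JSON or YAML file whose top-level keys may include any
#' [mets_thresholds()] cutpoint name and `diagnostic_threshold` (default
#' 0.547). Used by the command-line interface; exposed for programmatic use.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return named list of overrides.
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got: ", ext, call. = FALSE)
  )
  known <- c("glucose_mgdl", "sbp_mmhg", "dbp_mmhg", "triglycerides_mgdl",
             "hdl_mgdl", "waist_cm", "diagnostic_threshold")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

# canonical reporting order for the five risk-factor axes
rmrs_factors <- function() c("gl", "bp", "tg", "hdl", "wc")
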
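# Per-sex marginal moments (mean, sd) of the six measurements in large
# Korean and U.S. health-examination cohorts; used as simulation defaults.
cohort_marginals <- function(region = c("korean", "american"),
                             sex = c("male", "female")) {
  region <- match.arg(region)
  sex <- match.arg(sex)
  tabs <- list(
    korean = list(
      male   = list(glucose = c(94.8, 17.5),  sbp = c(124, 14.3),
                    dbp = c(77.9, 9.8),       triglycerides = c(145.3, 105.6),
                    hdl = c(50.4, 12.1),      waist = c(84.6, 7.4)),
      female = list(glucose = c(89.9, 13),    sbp = c(118.3, 14.7),
                    dbp = c(73.4, 9.6),       triglycerides = c(104.4, 66.7),
                    hdl = c(57.3, 12.9),      waist = c(77.3, 7.8))
    ),
    american = list(
      male   = list(glucose = c(100.2, 19.3), sbp = c(119.6, 13),
                    dbp = c(69.3, 12.1),      triglycerides = c(122.7, 116.2),
                    hdl = c(49.6, 13.5),      waist = c(94.2, 15.5)),
      female = list(glucose = c(95.3, 15.1),  sbp = c(112.5, 13.9),
                    dbp = c(67.1, 10.5),      triglycerides = c(94.4, 70),
                    hdl = c(58.3, 15.3),      waist = c(91, 16.1))
    )
  )
  tabs[[region]][[sex]]
}

# Plausible inter-factor dependence; the source cohorts report no
# correlations, so this is a stated modelling assumption, not an estimate.
default_dependence <- function() {
  v <- c("glucose", "sbp", "dbp", "triglycerides", "hdl", "waist")
  R <- diag(6)
  dimnames(R) <- list(v, v)
  set_cor <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_cor("sbp", "dbp", 0.70)
  set_cor("glucose", "sbp", 0.20); set_cor("glucose", "dbp", 0.15)
  set_cor("glucose", "triglycerides", 0.25); set_cor("glucose", "waist", 0.30)
  set_cor("glucose", "hdl", -0.15)
  set_cor("triglycerides", "hdl", -0.40); set_cor("triglycerides", "waist", 0.30)
  set_cor("triglycerides", "sbp", 0.15); set_cor("triglycerides", "dbp", 0.15)
  set_cor("hdl", "waist", -0.30)
  set_cor("waist", "sbp", 0.25); set_cor("waist", "dbp", 0.20)
  R
}

# clamp bounds keeping measurements positive and clinically plausible
measurement_bounds <- function() {
  list(glucose = c(40, 500), sbp = c(60, 260), dbp = c(30, 160),
       triglycerides = c(20, 2000), hdl = c(10, 200), waist = c(40, 200))
}

#' Simulate a synthetic subject cohort
#'
#' Draws subjects from a Gaussian copula with specified marginals: latent
#' correlated normals are transformed through their CDF and mapped back
#' through each factor's marginal quantile function. Marginal moments
#' default to large-cohort per-sex statistics ([cohort_marginals()]);
#' triglycerides default to a lognormal marginal (its dispersion approaches
#' its mean, so the distribution is strongly right-skewed) with parameters
#' matched to the requested mean and sd. Measurements are clamped to
#' plausible positive ranges and rows with systolic not exceeding diastolic
#' pressure are resampled.
#'
#' @param n number of subjects.
#' @param sex_ratio fraction of male subjects; default 0.307, the male
#'   fraction of the Korean reference cohort.
#' @param region `"korean"` (default) or `"american"`; selects the default
#'   marginals and is written into the records.
#' @param marginals optional list overriding [cohort_marginals()]: per sex, a
#'   named list of `c(mean, sd)` per measurement.
#' @param dependence 6 x 6 correlation matrix over (glucose, sbp, dbp,
#'   triglycerides, hdl, waist), or `NULL` for independence; default
#'   [default_dependence()].
#' @param lognormal_factors measurement names given a lognormal marginal;
#'   default `"triglycerides"`.
#' @param seed optional integer for reproducibility.
#' @return tibble of `SubjectRecord` rows: `id`, the six measurements,
#'   `sex`, `region`, `age` (uniform 20-79, a nuisance column).
#' @examples
#' simulate_cohort(n = 5, seed = 42)
#' @export
simulate_cohort <- function(n, sex_ratio = 0.307,
                            region = c("korean", "american"),
                            marginals = NULL,
                            dependence = default_dependence(),
                            lognormal_factors = "triglycerides",
                            seed = NULL) {
  stopifnot(n > 0, sex_ratio >= 0, sex_ratio <= 1)
  region <- match.arg(region)
  if (!is.null(seed)) set.seed(seed)

  v <- c("glucose", "sbp", "dbp", "triglycerides", "hdl", "waist")
  if (is.null(dependence)) dependence <- diag(6)
  dependence <- as.matrix(dependence)
  if (!isTRUE(all.equal(dependence, t(dependence))) ||
      any(diag(dependence) != 1) ||
      min(eigen(dependence, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8) {
    stop("`dependence` must be a symmetric PSD correlation matrix",
         call. = FALSE)
  }

  n_male <- rbinom(1, n, sex_ratio)
  sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))

  draw_block <- function(m, which_sex) {
    if (m == 0) return(NULL)
    marg <- marginals[[which_sex]] %||% cohort_marginals(region, which_sex)
    # chol of a PSD matrix with a tiny ridge for numerically singular inputs
    L <- chol(dependence + diag(1e-10, 6))
    gen <- function(m) {
      u <- stats::pnorm(matrix(stats::rnorm(m * 6), m, 6) %*% L)
      out <- matrix(NA_real_, m, 6, dimnames = list(NULL, v))
      for (j in seq_along(v)) {
        mu <- marg[[v[j]]][1]; sd <- marg[[v[j]]][2]
        if (v[j] %in% lognormal_factors) {
          sdlog <- sqrt(log(1 + (sd / mu)^2))
          meanlog <- log(mu) - sdlog^2 / 2
          out[, j] <- stats::qlnorm(u[, j], meanlog, sdlog)
        } else {
          out[, j] <- stats::qnorm(u[, j], mu, sd)
        }
      }
      b <- measurement_bounds()
      for (j in seq_along(v)) {
        out[, j] <- pmin(pmax(out[, j], b[[v[j]]][1]), b[[v[j]]][2])
      }
      out
    }
    x <- gen(m)
    for (i in 1:100) {
      bad <- x[, "sbp"] <= x[, "dbp"]
      if (!any(bad)) break
      x[bad, ] <- gen(sum(bad))
    }
    if (any(x[, "sbp"] <= x[, "dbp"])) {
      stop("could not enforce sbp > dbp; check the dependence matrix",
           call. = FALSE)
    }
    x
  }

  x <- matrix(NA_real_, n, 6, dimnames = list(NULL, v))
  for (s in c("male", "female")) {
    rows <- sex == s
    x[rows, ] <- draw_block(sum(rows), s)
  }

  tibble::tibble(
    id = sprintf("S%05d", seq_len(n)),
    glucose = x[, "glucose"], sbp = x[, "sbp"], dbp = x[, "dbp"],
    triglycerides = x[, "triglycerides"], hdl = x[, "hdl"],
    waist = x[, "waist"],
    sex = sex, region = region,
    age = round(stats::runif(n, 20, 79))
  )
}

#' Simulate scaled axis vectors with a fixed abnormal-factor count
#'
#' Draws five-vectors in scaled space with exactly `k` components at or
#' above the 0.5 cutpoint (uniform on `[0.5, 1]`) and `5 - k` below it
#' (uniform on `[0, 0.5)`), in random axis positions. Used to probe the
#' theoretical RMRS range for each abnormal-factor count.
#'
#' @param n number of vectors.
#' @param k abnormal-factor count, 0..5.
#' @param seed optional integer.
#' @return an `n x 5` numeric matrix, columns in canonical factor order.
#' @export
simulate_scaled_vectors <- function(n, k, seed = NULL) {
  stopifnot(n > 0, k %in% 0:5)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, paste0("s_", rmrs_factors())))
  hi <- matrix(stats::runif(n * 5, 0.5, 1), n, 5)
  lo <- matrix(stats::runif(n * 5, 0, 0.5 - 1e-12), n, 5)
  for (i in seq_len(n)) {
    pos <- sample(5, k)
    row <- lo[i, ]
    row[pos] <- hi[i, pos]
    out[i, ] <- row
  }
  out
}
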
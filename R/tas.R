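#' Enumerate the ten three-factor radar-chart triads
#'
#' A three-axis radar chart yields an axis-order-independent triangle area,
#' so the five MetS factors combine into choose(5, 3) = 10 basic graph units,
#' each a MetS subtype candidate (diagnosis requires any three abnormal
#' factors).
#'
#' @param factors character vector of exactly five distinct labels; defaults
#'   to the canonical axis order `c("gl", "bp", "tg", "hdl", "wc")`. Any
#'   permutation of the same set yields the same set of triads.
#' @return a 10 x 3 character matrix, one triad per row, in a deterministic
#'   canonical order.
#' @examples
#' triad_combinations()
#' @export
triad_combinations <- function(factors = rmrs_factors()) {
  factors <- as.character(factors)
  if (length(factors) != 5 || anyDuplicated(factors)) {
    stop("`factors` must contain exactly five distinct labels", call. = FALSE)
  }
  # canonical ordering: the package's axis order when applicable, else sorted
  ord <- if (setequal(factors, rmrs_factors())) rmrs_factors() else sort(factors)
  t(utils::combn(ord, 3))
}

#' Area of a radar-chart triangle
#'
#' Planar area of the triangle whose vertices lie at radii `x1`, `x2`, `x3`
#' on three axes separated by 120 degrees:
#' `area = 1/2 * sin(pi/3) * (x1*x2 + x2*x3 + x3*x1)`.
#'
#' @param x1,x2,x3 scaled axis values in `[0, 1]` (vectorized).
#' @return numeric vector of areas.
#' @examples
#' triangle_area(1, 1, 1)          # maximum triangle, ~1.299
#' triangle_area(0.5, 0.5, 0.5)    # threshold triangle, ~0.3248
#' @export
triangle_area <- function(x1, x2, x3) {
  check_unit_interval(x1, x2, x3)
  0.5 * sin(pi / 3) * (x1 * x2 + x2 * x3 + x3 * x1)
}

#' Clip scaled values at the diagnostic threshold
#'
#' Builds the internal measurement triangle: each scaled value exceeding the
#' threshold radius 0.5 is limited to 0.5.
#'
#' @param x numeric vector of scaled values in `[0, 1]`.
#' @return `pmin(x, 0.5)`.
#' @export
clip_internal <- function(x) {
  check_unit_interval(x)
  pmin(x, 0.5)
}

check_unit_interval <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("scaled values must lie in [0, 1]", call. = FALSE)
  }
  invisible(v)
}

#' Triangular areal similarity (TAS) of one factor triad
#'
#' Scores a three-axis radar chart by comparing four triangles: the
#' threshold triangle (all radii 0.5, area constant C_alpha), the maximum
#' triangle (all radii 1, excess capacity C_beta = 3 * C_alpha), and the
#' internal/external measurement triangles through the clipped and raw
#' scaled values. With `X = x1*x2 + x2*x3 + x3*x1` and `X'` its
#' threshold-clipped analogue (the areas divided by the common factor
#' `1/2 * sin(pi/3)`):
#'
#' * closeness = `X / (0.75 + X - X')`, the proximity of the chart to the
#'   diagnostic triangle, in `[0, 1]`;
#' * severity = `I * (4/9) * (X - X')`, the excess area beyond the
#'   threshold relative to its capacity, active only when all three factors
#'   reach their cutpoints (indicator `I`);
#' * `tas = (closeness + severity) / 2`, in `[0, 1]`.
#'
#' @param x1,x2,x3 scaled values in `[0, 1]` (vectorized).
#' @return numeric vector of TAS scores. See [tas_components()] for the
#'   per-triad intermediate quantities.
#' @examples
#' tas_score(0.5, 0.5, 0.5)  # exactly at onset: 0.5
#' tas_score(1, 1, 1)        # maximal severity: 1
#' @export
tas_score <- function(x1, x2, x3) {
  tas_components(x1, x2, x3)$tas
}

#' TAS score with all intermediate quantities
#'
#' @inheritParams tas_score
#' @return a [tibble::tibble] with columns `x1`, `x2`, `x3`, `big_x` (X),
#'   `big_x_prime` (X'), `indicator`, `closeness`, `severity`, `tas`.
#' @export
tas_components <- function(x1, x2, x3) {
  check_unit_interval(x1, x2, x3)
  n <- max(length(x1), length(x2), length(x3))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n); x3 <- rep_len(x3, n)

  big_x <- x1 * x2 + x2 * x3 + x3 * x1
  c1 <- pmin(x1, 0.5); c2 <- pmin(x2, 0.5); c3 <- pmin(x3, 0.5)
  big_x_prime <- c1 * c2 + c2 * c3 + c3 * c1
  # indicator of MetS onset within the triad; tested on the raw values, not
  # on X' == 0.75, to avoid a floating-point area equality
  ind <- as.integer(x1 >= 0.5 & x2 >= 0.5 & x3 >= 0.5)

  closeness <- big_x / (0.75 + big_x - big_x_prime)
  severity <- ind * (4 / 9) * (big_x - big_x_prime)

  tibble::tibble(
    x1 = x1, x2 = x2, x3 = x3,
    big_x = big_x, big_x_prime = big_x_prime,
    indicator = ind, closeness = closeness, severity = severity,
    tas = (closeness + severity) / 2
  )
}

#' Per-triad TAS table for one scaled five-vector
#'
#' @param scaled numeric length-5 vector of scaled axis values in `[0, 1]`,
#'   in the canonical order `(gl, bp, tg, hdl, wc)` (names optional).
#' @return a 10-row [tibble::tibble]: triad factor labels plus the
#'   [tas_components()] columns.
#' @export
triad_table <- function(scaled) {
  scaled <- as_scaled_vector(scaled)
  tri <- triad_combinations()
  idx <- matrix(match(tri, rmrs_factors()), ncol = 3)
  out <- tas_components(scaled[idx[, 1]], scaled[idx[, 2]], scaled[idx[, 3]])
  tibble::tibble(
    f1 = tri[, 1], f2 = tri[, 2], f3 = tri[, 3],
    out
  )
}

as_scaled_vector <- function(scaled) {
  scaled <- as.numeric(scaled)
  if (length(scaled) != 5) {
    stop("a scaled vector must have exactly five components", call. = FALSE)
  }
  check_unit_interval(scaled)
  scaled
}

# row indices of the 10 triads into a 5-column scaled matrix
triad_index <- function() {
  t(utils::combn(5L, 3L))
}

#' Robust MetS Risk Score (RMRS)
#'
#' The square root of the mean TAS score over all ten factor triads:
#' `RMRS = sqrt(mean(TAS_i))`, a continuous severity score in `[0, 1]` that
#' is invariant under permutation of the five factors. Factors beyond their
#' cutpoints are structurally up-weighted because each factor participates
#' in six of the ten triads.
#'
#' @param scaled a length-5 numeric vector, or an n x 5 matrix / data frame
#'   of scaled axis values in `[0, 1]` (one row per subject).
#' @return numeric vector of RMRS values, one per row.
#' @examples
#' rmrs_score(c(0.5, 0.5, 0.5, 0, 0))   # 0.387: minimal three-factor score
#' rmrs_score(rep(0.5, 5))              # 0.707: all factors at onset
#' @export
rmrs_score <- function(scaled) {
  if (is.data.frame(scaled)) scaled <- as.matrix(scaled)
  if (is.null(dim(scaled))) scaled <- matrix(as_scaled_vector(scaled), nrow = 1)
  if (ncol(scaled) != 5) {
    stop("`scaled` must have five columns (one per risk factor)", call. = FALSE)
  }
  check_unit_interval(scaled)
  idx <- triad_index()
  tas_sum <- 0
  for (k in seq_len(nrow(idx))) {
    tas_sum <- tas_sum +
      tas_score(scaled[, idx[k, 1]], scaled[, idx[k, 2]], scaled[, idx[k, 3]])
  }
  sqrt(tas_sum / 10)
}

#' Derive the fixed RMRS diagnostic threshold
#'
#' MetS is diagnosed when at least three factors are abnormal, but the RMRS
#' of a three-factor subject varies over a range that overlaps the
#' two-factor range. The fixed cutoff is the centre of that overlap: the
#' midpoint between the minimal three-factor RMRS (three factors exactly at
#' their cutpoints, two at the scale minimum) and the supremum of the
#' two-factor RMRS (two factors maximal, three approaching the cutpoint from
#' below). The supremum is evaluated at a small epsilon below 0.5.
#'
#' @param eps offset below the 0.5 cutpoint used to evaluate the limiting
#'   two-factor configuration; default `1e-9`.
#' @return named list: `min_three` (0.387...), `max_two` (0.707...),
#'   `threshold` (their midpoint, 0.547...). The values are structural
#'   constants of the score, independent of any cohort.
#' @examples
#' derive_diagnostic_threshold()
#' @export
derive_diagnostic_threshold <- function(eps = 1e-9) {
  stopifnot(is.numeric(eps), eps > 0, eps < 0.5)
  min_three <- rmrs_score(c(0.5, 0.5, 0.5, 0, 0))
  max_two <- rmrs_score(c(1, 1, 0.5 - eps, 0.5 - eps, 0.5 - eps))
  list(
    min_three = min_three,
    max_two = max_two,
    threshold = (min_three + max_two) / 2
  )
}

#' Round half away from zero
#'
#' Decimal rounding with the half-away-from-zero rule used for reported
#' scores (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
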
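#' Interaction-term decomposition of a TAS triad
#'
#' Rewrites the triangular-area TAS score of a triad in terms of pairwise
#' interaction masses of the deviations `alpha_i = x_i - 0.5` from the
#' cutpoint. With `I_T = 0.75` the reference (threshold) interaction, the
#' deviations split into a non-negative part `I_P` (risk accumulated beyond
#' the cutpoints) and a non-positive part `I_N` (a penalty from factors
#' below their cutpoints), according to the number of non-negative
#' deviations:
#'
#' * case 1 (none): `I_P = 0`, `I_N = sum(alpha) + sum(alpha_i * alpha_j)`
#' * case 2 (one, say a1): `I_P = a1 + a1*a2 + a1*a3`,
#'   `I_N = a2 + a3 + a2*a3`
#' * case 3 (two, say a1, a2): `I_P = a1 + a2 + a1*a2 + a2*a3 + a3*a1`,
#'   `I_N = a3`
#' * case 4 (all three): `I_P = sum(alpha) + sum(alpha_i * alpha_j)`,
#'   `I_N = 0`
#'
#' The case formulas assume the non-negative deviations occupy the leading
#' positions, so the deviations are sorted in decreasing order before the
#' formulas are applied; TAS is permutation-invariant, so this loses
#' nothing.
#'
#' @param x1,x2,x3 scaled values in `[0, 1]` (vectorized).
#' @return a [tibble::tibble] with columns `alpha1`, `alpha2`, `alpha3`
#'   (sorted deviations), `i_t` (0.75), `i_p` (>= 0), `i_n` (<= 0),
#'   `indicator` and `case_id` (1-4).
#' @examples
#' tas_decompose(0.3, 0.3, 0.3)  # case 1, pure penalty
#' tas_decompose(0.7, 0.7, 0.7)  # case 4, pure excess
#' @export
tas_decompose <- function(x1, x2, x3) {
  check_unit_interval(x1, x2, x3)
  n <- max(length(x1), length(x2), length(x3))
  a <- cbind(rep_len(x1, n), rep_len(x2, n), rep_len(x3, n)) - 0.5
  # decreasing sort puts the non-negative deviations first
  a <- t(apply(a, 1, sort, decreasing = TRUE))
  a1 <- a[, 1]; a2 <- a[, 2]; a3 <- a[, 3]

  n_pos <- rowSums(a >= 0)
  sum_a <- a1 + a2 + a3
  sum_aa <- a1 * a2 + a2 * a3 + a3 * a1

  i_p <- ifelse(n_pos == 0, 0,
         ifelse(n_pos == 1, a1 + a1 * a2 + a1 * a3,
         ifelse(n_pos == 2, a1 + a2 + sum_aa, sum_a + sum_aa)))
  i_n <- ifelse(n_pos == 0, sum_a + sum_aa,
         ifelse(n_pos == 1, a2 + a3 + a2 * a3,
         ifelse(n_pos == 2, a3, 0)))

  tibble::tibble(
    alpha1 = a1, alpha2 = a2, alpha3 = a3,
    i_t = 0.75, i_p = i_p, i_n = i_n,
    indicator = as.integer(n_pos == 3),
    case_id = as.integer(n_pos + 1)
  )
}

#' TAS score from interaction terms
#'
#' Recombines an interaction decomposition into the TAS score:
#' `tas = 1/2 * ((I_T + I_P + I_N) / (I_T + I_P) + I * (4/9) * I_P)`.
#' Agrees with [tas_score()] to machine precision, because
#' `X = I_T + I_P + I_N` and `X - X' = I_P` identically.
#'
#' @param terms a tibble from [tas_decompose()] (or any data frame with
#'   `i_t`, `i_p`, `i_n`, `indicator` columns).
#' @return numeric vector of TAS scores.
#' @examples
#' tas_from_interactions(tas_decompose(1, 1, 1))  # 1
#' @export
tas_from_interactions <- function(terms) {
  need <- c("i_t", "i_p", "i_n", "indicator")
  if (!all(need %in% names(terms))) {
    stop("`terms` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  with(terms, 0.5 * ((i_t + i_p + i_n) / (i_t + i_p) +
                       indicator * (4 / 9) * i_p))
}
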
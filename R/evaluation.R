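#' Summarize a score by abnormal-factor count
#'
#' Groups a continuous risk score by the count-based number of abnormal
#' factors (0..5) and reports, per count, the group size, its percentage of
#' the cohort, and the score mean, sd, min and max. Empty counts are
#' reported with `n = 0`.
#'
#' @param scores numeric vector.
#' @param counts integer vector in 0..5, same length.
#' @return tibble with columns `count`, `n`, `percent`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
per_count_summary <- function(scores, counts) {
  stopifnot(length(scores) == length(counts))
  if (any(!counts %in% 0:5)) stop("`counts` must be integers in 0..5",
                                  call. = FALSE)
  tibble::tibble(score = scores, count = as.integer(counts)) |>
    dplyr::group_by(count) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(score), sd = stats::sd(score),
      min = min(score), max = max(score),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(count = 0:5), by = "count") |>
    dplyr::mutate(
      n = ifelse(is.na(n), 0L, n),
      percent = 100 * n / length(scores)
    ) |>
    dplyr::arrange(count) |>
    dplyr::select(count, n, percent, mean, sd, min, max)
}

#' Score-count association
#'
#' Pearson product-moment correlation between the abnormal-factor count and
#' a continuous score, plus the adjusted R-squared of the simple linear
#' regression of score on count.
#'
#' @param scores numeric vector, length >= 3, nonzero variance.
#' @param counts numeric vector, same length, nonzero variance.
#' @return list with `pearson_r` and `adjusted_r_squared`.
#' @export
score_count_association <- function(scores, counts) {
  if (length(scores) < 3 || length(scores) != length(counts)) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(scores) == 0 || stats::sd(counts) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  fit <- stats::lm(scores ~ counts)
  list(
    pearson_r = stats::cor(scores, counts),
    adjusted_r_squared = summary(fit)$adj.r.squared
  )
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' positive outranks a negative, with tied pairs counting one half
#' (midranks).
#'
#' @param scores numeric vector.
#' @param labels 0/1 (or logical) vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: both classes required",
                               call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix classification metrics
#'
#' Dichotomizes a score at `threshold` (positive iff `score >= threshold`,
#' the same inclusive convention as the fixed RMRS cutoff) and returns
#' accuracy, recall (sensitivity) and specificity.
#'
#' @param scores numeric vector.
#' @param labels 0/1 (or logical) vector; both classes must be present.
#' @param threshold cutoff.
#' @return list with `accuracy`, `recall`, `specificity`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (all(labels == 1) || all(labels == 0)) {
    stop("both classes required", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  list(
    accuracy = mean(pred == labels),
    recall = mean(pred[labels == 1] == 1),
    specificity = mean(pred[labels == 0] == 0)
  )
}

#' Youden-optimal threshold
#'
#' Scans candidate cutpoints -- midpoints of adjacent distinct sorted
#' scores, plus sentinels below and above all scores -- and returns the one
#' maximizing Youden's J = recall + specificity - 1. Ties are broken toward
#' the lower threshold.
#'
#' @inheritParams auc_mann_whitney
#' @return list with `threshold` and `j` (the maximal Youden index).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (all(labels == 1) || all(labels == 0)) {
    stop("both classes required", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            max(u) + 1)
  j <- vapply(cand, function(t) {
    m <- classification_metrics(scores, labels, t)
    m$recall + m$specificity - 1
  }, numeric(1))
  best <- which.max(j)  # first maximum = lowest candidate
  list(threshold = cand[best], j = j[best])
}

#' Per-subgroup evaluation report
#'
#' Splits a scored cohort by one or more grouping columns and reports, per
#' non-empty group, the score-count correlation, adjusted R-squared, AUC
#' against the count-based diagnosis, and the classification metrics at the
#' fixed threshold. Groups with a single diagnostic class, or smaller than
#' `min_n`, have their undefined metrics set to `NA` and are flagged.
#'
#' @param scored tibble from [score_cohort()] (needs `rmrs`,
#'   `risk_factor_count`, `mets_by_count` and the grouping columns).
#' @param group_by character vector of column names; `character(0)` gives a
#'   single whole-cohort row.
#' @param threshold score cutoff for classification metrics; default 0.547.
#' @param min_n groups below this size are flagged; default 20.
#' @return tibble: one row per group with `n`, `pearson_r`,
#'   `adjusted_r_squared`, `auc`, `accuracy`, `recall`, `specificity`,
#'   `threshold_used`, `flag`.
#' @export
subgroup_report <- function(scored, group_by = character(0),
                            threshold = 0.547, min_n = 20) {
  miss <- setdiff(group_by, names(scored))
  if (length(miss) > 0) {
    stop("grouping column(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(group_by) == 0) {
    scored$.all <- "all"
    group_by <- ".all"
  }
  groups <- split(scored, scored[group_by], drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    one_class <- length(unique(d$mets_by_count)) < 2
    assoc <- if (nrow(d) >= 3 && stats::sd(d$rmrs) > 0 &&
                 stats::sd(d$risk_factor_count) > 0) {
      score_count_association(d$rmrs, d$risk_factor_count)
    } else {
      list(pearson_r = NA_real_, adjusted_r_squared = NA_real_)
    }
    cls <- if (!one_class) {
      classification_metrics(d$rmrs, d$mets_by_count, threshold)
    } else {
      list(accuracy = NA_real_, recall = NA_real_, specificity = NA_real_)
    }
    tibble::tibble(
      group = g, n = nrow(d),
      pearson_r = assoc$pearson_r,
      adjusted_r_squared = assoc$adjusted_r_squared,
      auc = if (one_class) NA_real_ else
        auc_mann_whitney(d$rmrs, d$mets_by_count),
      accuracy = cls$accuracy, recall = cls$recall,
      specificity = cls$specificity,
      threshold_used = threshold,
      flag = dplyr::case_when(
        one_class ~ "single-class",
        nrow(d) < min_n ~ "small-n",
        .default = ""
      )
    )
  })
  dplyr::bind_rows(rows)
}
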
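test_that("per-count summary groups scores by abnormal-factor count", {
  s <- per_count_summary(c(0.2, 0.4, 0.6), c(0, 1, 3))
  expect_equal(s$count, 0:5)
  expect_equal(s$n, c(1L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(s$mean[s$count == 0], 0.2)
  expect_equal(s$mean[s$count == 3], 0.6)
  expect_equal(sum(s$percent), 100)

  one <- per_count_summary(rep(0.5, 4), rep(2, 4))
  expect_equal(one$percent[one$count == 2], 100)
  expect_true(all(one$n[one$count != 2] == 0))

  expect_error(per_count_summary(1:3, c(0, 1, 9)), "0..5")
})

test_that("score-count association returns Pearson r and adjusted R squared", {
  x <- c(1, 2, 3, 4, 5)
  # suppressWarnings: summary.lm warns on these deliberately perfect fits
  expect_equal(suppressWarnings(score_count_association(2 * x + 1, x))$pearson_r, 1)
  expect_equal(suppressWarnings(score_count_association(-x, x))$pearson_r, -1)
  # hand-computed product-moment correlation
  expect_equal(score_count_association(c(1, 3, 2), c(1, 2, 3))$pearson_r, 0.5)

  a <- suppressWarnings(score_count_association(2 * x + 1, x))
  expect_equal(a$adjusted_r_squared, 1)

  expect_error(score_count_association(rep(1, 5), x), "zero variance")
  expect_error(score_count_association(1:2, 1:2), "at least 3")
})

test_that("rank AUC matches its anchors and the pairwise brute force", {
  expect_equal(auc_mann_whitney(c(0.1, 0.9), c(0, 1)), 1)
  expect_equal(auc_mann_whitney(rep(0.5, 10), rep(0:1, 5)), 0.5)
  # 4 positive-negative pairs: 3 wins out of 4
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "both classes")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mann_whitney(scores, labels),
                 auc_brute_force(scores, labels), tolerance = 1e-12)
  }
})

test_that("confusion-matrix metrics use the inclusive >= convention", {
  m <- classification_metrics(c(0.2, 0.6, 0.7, 0.4), c(0, 1, 1, 0), 0.5)
  expect_equal(m$accuracy, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$specificity, 1)

  all_pos <- classification_metrics(c(0.6, 0.7, 0.8), c(0, 1, 1), 0)
  expect_equal(all_pos$recall, 1)
  expect_equal(all_pos$specificity, 0)

  # a score exactly at the threshold is predicted positive
  at <- classification_metrics(c(0.547, 0.2), c(1, 0), 0.547)
  expect_equal(at$recall, 1)
  expect_error(classification_metrics(1:3, c(1, 1, 1), 0.5), "both classes")
})

test_that("Youden threshold maximizes J over the exhaustive cutpoint scan", {
  y <- youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(y$threshold, 2.5)
  expect_equal(y$j, 1)

  set.seed(32)
  for (i in 1:10) {
    scores <- runif(60)
    labels <- as.integer(scores + rnorm(60, sd = 0.3) > 0.5)
    if (length(unique(labels)) < 2) next
    y <- youden_threshold(scores, labels)
    # exhaustive scan over a fine grid can do no better
    grid <- seq(min(scores) - 0.01, max(scores) + 0.01, length.out = 2001)
    j_grid <- vapply(grid, function(t) {
      m <- classification_metrics(scores, labels, t)
      m$recall + m$specificity - 1
    }, numeric(1))
    expect_gte(y$j, max(j_grid) - 1e-12)
    m <- classification_metrics(scores, labels, y$threshold)
    expect_equal(m$recall + m$specificity - 1, y$j)
  }

  # J is never negative at the optimum: the sentinel cutpoints give J = 0
  noise <- youden_threshold(runif(50), rbinom(50, 1, 0.5))
  expect_gte(noise$j, 0)
})

test_that("subgroup reports cover the cohort and tolerate degenerate groups", {
  cohort <- simulate_cohort(300, seed = 55)
  scored <- score_cohort(cohort)

  whole <- subgroup_report(scored)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$n, 300)
  expect_equal(whole$auc, auc_mann_whitney(scored$rmrs, scored$mets_by_count))

  by_sex <- subgroup_report(scored, "sex")
  expect_equal(sum(by_sex$n), 300)
  expect_true(all(by_sex$group %in% c("male", "female")))

  # a single-class group reports NA metrics instead of failing
  healthy <- scored[scored$risk_factor_count == 0, ]
  if (nrow(healthy) >= 2) {
    rep0 <- subgroup_report(healthy)
    expect_true(is.na(rep0$auc))
    expect_equal(rep0$flag, "single-class")
  }
  expect_error(subgroup_report(scored, "nope"), "absent")
})

test_that("per-count mean RMRS rises strictly with the abnormal count", {
  set.seed(60)
  scores <- numeric(0); counts <- integer(0)
  for (k in 0:5) {
    s <- simulate_scaled_vectors(400, k, seed = 600 + k)
    scores <- c(scores, rmrs_score(s))
    counts <- c(counts, rep(k, 400))
  }
  summ <- per_count_summary(scores, counts)
  expect_true(all(diff(summ$mean) > 0))
  expect_true(all(diff(summ$min) > 0))
  expect_true(all(diff(summ$max) > 0))
  expect_gt(score_count_association(scores, counts)$pearson_r, 0.9)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- runif(150)
  labels <- as.integer(scores + rnorm(150, sd = 0.4) > 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mann_whitney(scores, labels), ref, tolerance = 1e-12)
})
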
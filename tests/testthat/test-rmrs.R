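test_that("RMRS reproduces the structural boundary configurations", {
  expect_equal(round_half_away(rmrs_score(c(0.5, 0.5, 0.5, 0, 0)), 3), 0.387)
  expect_equal(round_half_away(rmrs_score(c(0.5, 0.5, 0, 0, 0)), 3), 0.224)
  expect_equal(round_half_away(rmrs_score(rep(0.5, 5)), 3), 0.707)
  expect_equal(rmrs_score(rep(1, 5)), 1)
  expect_equal(rmrs_score(rep(0, 5)), 0)
})

test_that("RMRS is permutation-invariant, bounded and monotone", {
  set.seed(11)
  for (i in 1:200) {
    x <- runif(5)
    base <- rmrs_score(x)
    expect_gte(base, 0); expect_lte(base, 1)
    expect_equal(rmrs_score(sample(x)), base)
    y <- pmin(x + runif(5, 0, 0.3), 1)
    expect_gte(rmrs_score(y) - base, -1e-12)
  }
})

test_that("matrix and vector interfaces agree", {
  set.seed(12)
  m <- matrix(runif(50), 10, 5)
  by_matrix <- rmrs_score(m)
  by_row <- apply(m, 1, rmrs_score)
  expect_equal(by_matrix, by_row)
  expect_error(rmrs_score(matrix(0.5, 2, 4)), "five columns")
  expect_error(rmrs_score(c(0.5, 0.5)), "five components")
})

test_that("the fixed diagnostic threshold derives from the range overlap", {
  d <- derive_diagnostic_threshold()
  expect_equal(round_half_away(d$min_three, 3), 0.387)
  expect_equal(round_half_away(d$max_two, 3), 0.707)
  expect_equal(round_half_away(d$threshold, 3), 0.547)
  # the midpoint construction
  expect_equal(d$threshold, (d$min_three + d$max_two) / 2)
})

test_that("simulated per-count RMRS stays inside the theoretical ranges", {
  lo <- c(0, 0, 0.224, 0.387, 0.548, 0.707)
  hi <- c(0.707, 0.707, 0.707, 0.742, 0.837, 1)
  for (k in 0:5) {
    s <- simulate_scaled_vectors(2000, k, seed = 500 + k)
    r <- rmrs_score(s)
    # printed endpoints are 3 d.p. roundings of the exact bounds
    expect_gte(min(r), lo[k + 1] - 5e-4)
    expect_lte(max(r), hi[k + 1] + 5e-4)
  }
})

test_that("risk factors are counted with the raw-space inequalities", {
  base <- tibble::tibble(glucose = 100, sbp = 120, dbp = 80,
                         triglycerides = 150, hdl = 40, waist = 90,
                         sex = "male", region = "korean")
  # GL, TG, WC at their inclusive cutpoints count; HDL = 40 is not < 40;
  # both BP readings below their cutpoints
  expect_equal(count_risk_factors(base), 3L)

  low <- tibble::tibble(glucose = 80, sbp = 110, dbp = 70,
                        triglycerides = 90, hdl = 70, waist = 75,
                        sex = "male", region = "korean")
  expect_equal(count_risk_factors(low), 0L)

  all5 <- tibble::tibble(glucose = 120, sbp = 140, dbp = 90,
                         triglycerides = 200, hdl = 30, waist = 95,
                         sex = "male", region = "korean")
  expect_equal(count_risk_factors(all5), 5L)

  # sex/region resolution: same raw values, female American thresholds
  fem <- dplyr::mutate(all5, sex = "female", region = "american")
  expect_equal(count_risk_factors(fem), 5L)  # hdl 30 < 50, waist 95 >= 88
})

test_that("score_subject bundles scaling, RMRS and both diagnoses", {
  res <- score_subject(at_threshold_record())
  expect_s3_class(res, "rmrs_result")
  expect_equal(round_half_away(res$rmrs, 3), 0.707)
  # HDL exactly at its cutpoint is normal (strict <), so 4 of 5 count
  expect_equal(res$risk_factor_count, 4L)
  expect_true(res$diagnosis_by_count)
  expect_true(res$diagnosis_by_rmrs)

  rec5 <- at_threshold_record()
  rec5$hdl <- 39.9
  expect_equal(score_subject(rec5)$risk_factor_count, 5L)
  expect_equal(nrow(res$triads), 10)
  expect_equal(res$rmrs, sqrt(mean(res$triads$tas)))

  # far below every cutpoint
  low <- list(glucose = 70, sbp = 100, dbp = 60, triglycerides = 60,
              hdl = 90, waist = 60, sex = "male", region = "korean")
  res_low <- score_subject(low)
  expect_lt(res_low$rmrs, 0.2)
  expect_equal(res_low$risk_factor_count, 0L)
  expect_false(res_low$diagnosis_by_count)
  expect_false(res_low$diagnosis_by_rmrs)

  # exactly three factors at threshold, two far below: positive by count,
  # but the score sits at the bottom of the three-factor range, below 0.547
  mixed <- list(glucose = 100, sbp = 100, dbp = 60, triglycerides = 150,
                hdl = 90, waist = 90, sex = "male", region = "korean")
  res_mixed <- score_subject(mixed)
  expect_equal(res_mixed$risk_factor_count, 3L)
  expect_true(res_mixed$diagnosis_by_count)
  expect_lt(res_mixed$rmrs, 0.547)
  expect_false(res_mixed$diagnosis_by_rmrs)
})

test_that("cohort scoring matches subject-by-subject scoring", {
  cohort <- simulate_cohort(25, seed = 77)
  scored <- score_cohort(cohort)
  for (i in c(1, 10, 25)) {
    one <- score_subject(as.list(cohort[i, ]))
    expect_equal(scored$rmrs[i], one$rmrs)
    expect_equal(scored$risk_factor_count[i], one$risk_factor_count)
  }
  expect_identical(scored$mets_by_count, scored$risk_factor_count >= 3L)
  expect_identical(scored$mets_by_rmrs, scored$rmrs >= 0.547)

  empty <- score_cohort(cohort[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("rmrs", "mets_by_rmrs") %in% names(empty)))
})
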
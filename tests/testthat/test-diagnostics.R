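test_that("category summaries report computed counts, percentages and moments", {
  summaries <- reference_category_summaries()
  cohort <- generate_calibrated_cohort(summaries, seed = 31)
  st <- summarize_categories(cohort)
  expect_equal(st$by_category$n, c(74L, 319L, 135L, 197L, 308L))
  # percentages as computed from the counts; note the second category is
  # 319/1033 = 30.9% by arithmetic (the reference report prints 30.1% for
  # that row, which is not consistent with its own counts)
  expect_equal(st$by_category$percent, c(7.2, 30.9, 13.1, 19.1, 29.8))
  expect_equal(st$capture_share_percent, 70.2)
  expect_equal(sum(st$by_category$percent), 100, tolerance = 0.11)

  single <- records_from(5, 1)
  st1 <- summarize_categories(single)
  expect_equal(st1$by_category$percent[1], 100)
  expect_false(st1$by_category$sd_defined[1])
  expect_equal(st1$by_category$sd_mm[1], 0)
  expect_error(summarize_categories(records_from(numeric(0), integer(0))), "no records")
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$rho, -1)
  expect_false(spearman_rho(rep(1, 5), 1:5)$defined)

  # hand-computable tied example against a from-scratch mid-rank computation
  x <- c(1, 1, 2, 2, 3, 3)
  y <- c(2.0, 3.1, 2.9, 4.0, 4.1, 5.2)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)
})

test_that("Welch t-test matches a permutation oracle and degenerate cases", {
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  same <- c(4.2, 5.1, 6.3, 4 : 8)
  res <- welch_t_test(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  set.seed(41)
  a <- c(12.1, 14.3, 11.8, 13.5, 15.0, 12.7, 14.9, 13.2)
  b <- c(15.2, 16.8, 14.9, 17.3, 15.7, 16.1, 18.0, 15.5)
  welch_p <- welch_t_test(a, b)$p_value
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(1e5, {
    i <- sample.int(16, 8)
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  perm_p <- mean(perm >= obs - 1e-12)
  expect_lt(abs(welch_p - perm_p), 0.01)
})

test_that("adjacent lowest categories separate only marginally, as reported", {
  ps <- vapply(1:40, function(s) {
    cohort <- generate_calibrated_cohort(seed = 500 + s)
    a <- cohort$distance_mm[cohort$category == "<=10 mA"]
    b <- cohort$distance_mm[cohort$category == ">10-<=20 mA"]
    welch_t_test(a, b)$p_value
  }, numeric(1))
  expect_gt(stats::median(ps), 0.01)
  expect_lt(stats::median(ps), 0.3)
})

test_that("rank-sum AUC equals the concordance double loop and behaves at the null", {
  set.seed(51)
  cohort <- generate_calibrated_cohort(seed = 61)
  sub <- cohort[sample.int(nrow(cohort), 400), ]
  pos <- sub$distance_mm > 10
  auc <- rank_sum_auc(as.integer(sub$category), pos)
  expect_equal(auc, oracle_concordance_auc(as.integer(sub$category), pos),
               tolerance = 1e-12)

  # independent library cross-check on the same data
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = as.integer(sub$category),
    direction = "<", quiet = TRUE)))
  expect_equal(auc, proc_auc, tolerance = 1e-9)
})

test_that("label permutation drives the AUC to one half", {
  cohort <- generate_calibrated_cohort(seed = 71)
  pos <- cohort$distance_mm > 10
  set.seed(81)
  null_auc <- vapply(1:10, function(i) {
    rank_sum_auc(as.integer(cohort$category), sample(pos))
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
})

test_that("sensitivity and specificity follow their definitions and nesting", {
  # 2x2 at the >30 mA cutoff: TP = 9, FN = 1, TN = 8, FP = 2
  rec <- rbind(
    records_from(rep(15, 9), rep(5, 9)),   # TP: remote, category beyond cutoff
    records_from(rep(15, 1), rep(2, 1)),   # FN
    records_from(rep(5, 8), rep(2, 8)),    # TN
    records_from(rep(5, 2), rep(5, 2))     # FP
  )
  t2 <- build_table2(rec)
  expect_equal(t2$sensitivity[t2$cutoff == ">30 mA"], 0.9)
  expect_equal(t2$specificity[t2$cutoff == ">30 mA"], 0.8)

  # all-positive predictor: Se 1, Sp 0 at every cutoff below the top
  allpos <- records_from(c(15, 15, 5, 5), rep(5, 4))
  t2a <- build_table2(allpos)
  expect_equal(t2a$sensitivity[1:3], rep(1, 3))
  expect_equal(t2a$specificity[1:3], rep(0, 3))

  # nesting across cutoffs on a realistic cohort
  cohort <- generate_calibrated_cohort(seed = 91)
  t2c <- build_table2(cohort)
  expect_true(all(diff(t2c$sensitivity) <= 0))
  expect_true(all(diff(t2c$specificity) >= 0))
})

test_that("perfect separation yields AUC 1 with unit Se/Sp at the split", {
  rec <- rbind(records_from(rep(15, 10), rep(5, 10)),
               records_from(rep(5, 10), rep(1, 10)))
  roc <- roc_analysis(rec, n_boot = 0)
  expect_equal(roc$auc, 1)
  expect_equal(roc$by_cutoff$sensitivity[4], 1)
  expect_equal(roc$by_cutoff$specificity[4], 1)
  expect_error(roc_analysis(records_from(rep(15, 4), c(1, 2, 3, 4)), n_boot = 0),
               "both classes")
})

test_that("bootstrap CI covers the point AUC and narrows roughly as 1/sqrt(n)", {
  widths <- vapply(c(250, 1000, 4000), function(n) {
    set.seed(n)
    cohort <- generate_calibrated_cohort(seed = 101)
    idx <- sample.int(nrow(cohort), n, replace = TRUE)
    roc <- roc_analysis(cohort[idx, ], n_boot = 500, seed = 3)
    expect_gte(roc$auc, roc$auc_ci_low)
    expect_lte(roc$auc, roc$auc_ci_high)
    roc$auc_ci_high - roc$auc_ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  shrink <- widths[1] / widths[3]
  expect_gt(shrink, sqrt(4000 / 250) * 0.5)  # ~4x expected, allow slack
})
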
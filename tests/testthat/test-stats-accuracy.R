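test_that("accuracy arithmetic matches hand-computed confusion rates", {
  rep <- accuracy_from_counts(tp = 90, fn = 10, tn = 80, fp = 20)
  expect_equal(rep$sensitivity, 90)
  expect_equal(rep$specificity, 80)
  expect_equal(round(rep$ppv, 2), 81.82)
  expect_equal(round(rep$npv, 2), 88.89)
  expect_equal(length(rep$undefined), 0)
})

test_that("a perfect test scores 100 on every rate", {
  rec <- data.frame(class = factor(rep(c("live", "dead"), c(7, 5)),
                                   levels = CELL_CLASSES_test()))
  rep <- accuracy_from_records(rec)
  expect_equal(c(rep$sensitivity, rep$specificity, rep$ppv, rep$npv),
               c(100, 100, 100, 100))
})

test_that("zero denominators are flagged undefined, not fabricated", {
  rec <- data.frame(class = factor(rep("live", 4),
                                   levels = CELL_CLASSES_test()))
  rep <- accuracy_from_records(rec)   # no dextran-positive cells at all
  expect_true(is.na(rep$specificity))
  expect_true("specificity" %in% rep$undefined)
  empty <- accuracy_from_records(data.frame(
    class = factor(character(0), levels = CELL_CLASSES_test())))
  expect_setequal(empty$undefined, c("sensitivity", "specificity", "ppv", "npv"))
})

test_that("ROC endpoints and monotonicity hold", {
  set.seed(8)
  rec <- data.frame(f_ryr = runif(100), f_dextran = runif(100))
  roc <- roc_sweep(rec, theta_grid = c(0, 0.25, 0.5, 0.75, 1.049))
  expect_equal(roc$tpr[1], 1); expect_equal(roc$fpr[1], 1)
  expect_equal(roc$tpr[nrow(roc)], 0); expect_equal(roc$fpr[nrow(roc)], 0)
  expect_true(all(diff(roc$tpr) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))
})

test_that("ROC separates classes on the exclusive-state slice", {
  an <- analysis_excl()
  roc <- roc_sweep(an$records)
  expect_gte(attr(roc, "auc"), 0.95)
})

test_that("force regression recovers exact and noisy slopes", {
  f <- c(0.1, 0.4, 0.5, 0.8)
  fit <- force_regression(f, 200 + 1000 * f)
  expect_equal(fit$slope, 1000)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$p_value, 1e-8)
  # degenerate: no variance in fractions
  d <- force_regression(rep(0.5, 5), rnorm(5))
  expect_true(d$degenerate)
  expect_true(is.na(d$slope))
  expect_error(force_regression(c(0.1, 0.5), c(1, 2)), "at least 3")
  expect_error(force_regression(c(0.1, 0.5, 1.4), c(1, 2, 3)), "\\[0, 1\\]")
})

test_that("F-test p-values are uniform under the null", {
  set.seed(19)
  p <- vapply(1:400, function(i) {
    x <- runif(12); y <- rnorm(12)
    force_regression(x, y)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("distribution summary matches hand computation", {
  s <- distribution_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  se <- sd(1:5) / sqrt(5)
  expect_equal(s$ci_lower, 3 - 1.96 * se)
  expect_equal(s$ci_upper, 3 + 1.96 * se)
  one <- distribution_summary(7)
  expect_equal(one$median, 7)
  expect_true("degenerate" %in% one$flags)
  expect_error(distribution_summary(numeric(0)), "no values")
})

test_that("Holm adjustment reproduces the step-down arithmetic", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  p <- c(0.2, 0.01, 0.8)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("group tests run Welch and paired families with Holm correction", {
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10, 2)
  res <- group_tests(list(
    shifted = list(x = x, y = y),
    identical = list(x = x, y = x),
    paired_shift = list(x = x, y = x + 1 + rnorm(10, 0, 0.01), paired = TRUE)))
  expect_equal(nrow(res), 3)
  expect_lt(res$p_raw[res$comparison == "shifted"], 0.01)
  # Welch on two identical non-constant samples: t = 0, p = 1
  expect_equal(res$p_raw[res$comparison == "identical"], 1)
  expect_true(all(res$p_holm >= res$p_raw, na.rm = TRUE))
  # degenerate paired design (all differences zero) is flagged
  res2 <- group_tests(list(zero = list(x = x, y = x, paired = TRUE)))
  expect_true(res2$degenerate)
  expect_true(is.na(res2$p_raw))
  # clear separation
  res3 <- group_tests(list(sep = list(x = c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                                      y = c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))))
  expect_lt(res3$p_raw, 0.001)
})
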
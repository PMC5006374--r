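test_that("contrast estimate is the coefficient-weighted cell means", {
  d <- long_sample(list(c(1, 1), c(0, 0), c(0, 0), c(1, 1)))
  expect_equal(contrast_estimate(d, "interaction"), 2)

  d2 <- long_sample(rep(list(rep(5, 3)), 4))
  expect_equal(contrast_estimate(d2, c(2, -1, -1, 0)), 0)

  set.seed(3)
  obs <- lapply(c(5, 8, 6, 9), function(n) rnorm(n))
  fit3 <- welch_contrast_test(long_sample(obs), "mainA")
  expect_equal(fit3$estimate,
               sum(c(1, 1, -1, -1) * vapply(obs, mean, 0)))
  expect_equal(contrast_estimate(long_sample(obs), "mainA"), fit3$estimate)
})

test_that("a two-cell contrast reduces to the classical two-sample Welch test", {
  set.seed(11)
  x <- rnorm(9, 1, 1)
  y <- rnorm(14, 0, 2.5)
  d <- long_sample(list(x, y, c(0, 0), c(0, 0)))
  fit <- welch_contrast_test(d, c(1, -1, 0, 0), null_value = 0.3)
  ref <- t.test(x, y, mu = 0.3, var.equal = FALSE)
  expect_equal(fit$statistic, unname(ref$statistic))
  expect_equal(fit$df, unname(ref$parameter))
  expect_equal(fit$p.value, ref$p.value)
})

test_that("a sample estimating exactly the null gives T = 0 and p = 1", {
  d <- long_sample(list(c(1, 3), c(0, 2), c(-1, 1), c(0, 4)))
  fit <- welch_contrast_test(d, "interaction",
                             null_value = welch_contrast_test(d, "interaction")$estimate)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p.value, 1)
  expect_false(fit$reject)
})

test_that("the test is scale equivariant", {
  set.seed(5)
  obs <- lapply(c(6, 7, 8, 9), function(n) rnorm(n, 1, 2))
  d <- long_sample(obs)
  f1 <- welch_contrast_test(d, "interaction", null_value = 0.4)
  d2 <- dplyr::mutate(d, response = response * 7.3)
  f2 <- welch_contrast_test(d2, "interaction", null_value = 0.4 * 7.3)
  expect_equal(f2$statistic, f1$statistic)
  expect_equal(f2$df, f1$df)
  expect_equal(f2$p.value, f1$p.value)
})

test_that("estimated df agrees with the population formula at the sample variances", {
  set.seed(21)
  obs <- lapply(c(12, 9, 15, 10), function(n) rnorm(n, 0, runif(1, 0.5, 3)))
  fit <- welch_contrast_test(long_sample(obs), "interaction")
  cells <- factorial_cells(vapply(obs, mean, 0),
                           variances = vapply(obs, var, 0))
  expect_equal(fit$df, satterthwaite_df(cells, lengths(obs)))
})

test_that("rejection flag, critical value and p-value are mutually consistent", {
  set.seed(31)
  for (i in 1:20) {
    obs <- lapply(c(5, 6, 7, 8), function(n) rnorm(n, rnorm(1), runif(1, 0.5, 2)))
    fit <- welch_contrast_test(long_sample(obs), "interaction", alpha = 0.2)
    expect_identical(fit$reject, abs(fit$statistic) > fit$critical_value)
    expect_identical(fit$reject, fit$p.value < 0.2)
  }
})

test_that("null rejection rate is near alpha and p-values look uniform", {
  cells <- factorial_cells(rep(1, 4), variances = c(1, 4, 2, 8))
  sim <- simulate_power(cells, c(12, 15, 10, 18), reps = 4000, seed = 17)
  expect_lt(abs(sim$simulated_power - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))

  set.seed(8)
  pvals <- replicate(600, {
    obs <- lapply(c(10, 12, 9, 14), function(n) rnorm(n, 2, 1.5))
    welch_contrast_test(long_sample(obs), "interaction")$p.value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("degenerate and malformed samples are rejected with clear errors", {
  const <- long_sample(list(c(1, 1), c(2, 2), c(3, 3), c(4, 4)))
  expect_error(welch_contrast_test(const, "interaction"), "Degenerate")
  missing_cell <- long_sample(list(c(1, 2), c(3, 4), c(5, 6), numeric(0)))
  expect_error(welch_contrast_test(missing_cell, "interaction"), "\\(2,2\\)")
  expect_error(welch_contrast_test(tibble::tibble(factor_a = 1, factor_b = 1),
                                   "interaction"),
               "missing column")
})

test_that("tidiers return one-row summaries", {
  set.seed(2)
  fit <- welch_contrast_test(
    long_sample(lapply(c(5, 5, 5, 5), function(n) rnorm(n))), "interaction")
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(td, c("estimate", "std.error", "statistic", "df", "p.value",
                     "reject"))
  expect_equal(glance(fit)$alpha, 0.05)
})
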
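test_that("contrast effects combine the cell means linearly", {
  expect_equal(contrast_effect(ec_cells("interaction")), 1.06)
  expect_equal(contrast_effect(ec_cells("mainA")), 1.14)
  expect_equal(contrast_effect(ec_cells("mainB")), 0.56)
  equal_means <- factorial_cells(rep(3, 4), variances = 1:4)
  expect_equal(contrast_effect(equal_means), 0)
})

test_that("estimator variance sums per-cell contributions", {
  cells <- factorial_cells(1:4, variances = c(1, 4, 9, 16))
  expect_equal(estimator_variance(cells, 10), 3.0)
  # frozen by direct four-term summation, independently of the implementation
  expect_equal(estimator_variance(ec_cells("interaction"), c(11, 16, 13, 19)),
               0.135124843577, tolerance = 1e-10)
  # homogeneity: doubling every cell halves the variance
  n <- c(7, 9, 11, 13)
  expect_equal(estimator_variance(cells, 2 * n),
               estimator_variance(cells, n) / 2)
})

test_that("approximate df has the closed form, frozen value and bounds", {
  # equal variances, balanced, unit coefficients: exactly 4(n - 1)
  for (n in c(5, 12, 40)) {
    cells <- factorial_cells(1:4, variances = rep(2.7, 4))
    expect_equal(satterthwaite_df(cells, n), 4 * (n - 1))
  }
  # frozen by independent spreadsheet-style evaluation of the formula
  expect_equal(satterthwaite_df(vg_cells(), c(20, 40, 60, 79)),
               194.9753593221, tolerance = 1e-9)
  expect_error(satterthwaite_df(vg_cells(), c(2, 2, 2, 1)), "at least 2")

  # df always between min(n - 1) and sum(n - 1)
  set.seed(41)
  for (i in 1:50) {
    cells <- factorial_cells(rnorm(4), variances = exp(rnorm(4)),
                             contrast = sample(c(-2, -1, 1, 2), 4, TRUE))
    n <- sample(2:60, 4, TRUE)
    df <- satterthwaite_df(cells, n)
    expect_gte(df, min(n - 1) - 1e-9)
    expect_lte(df, sum(n - 1) + 1e-9)
  }
})

test_that("approximate power matches published benchmark allocations", {
  p1 <- ws_power(ec_cells("interaction"), c(11, 16, 13, 19))
  expect_equal(p1$power, 0.8005, tolerance = 1e-4)
  expect_equal(p1$effect, 1.06)
  p2 <- ws_power(vg_cells(), c(20, 40, 60, 79))
  expect_equal(p2$power, 0.8016, tolerance = 1e-4)
})

test_that("the power function has size alpha at the null", {
  set.seed(99)
  for (i in 1:25) {
    cells <- factorial_cells(rnorm(4), variances = exp(rnorm(4)))
    alpha <- runif(1, 0.001, 0.3)
    psi <- contrast_effect(cells)
    pw <- ws_power(cells, sample(2:50, 4, TRUE), null_value = psi,
                   alpha = alpha)
    expect_equal(pw$power, alpha, tolerance = 1e-10)
  }
})

test_that("power is monotone in each cell size and symmetric in the sign of the effect", {
  set.seed(7)
  for (i in 1:10) {
    cells <- factorial_cells(c(1.5, 0.2, -0.3, 0.9),
                             variances = exp(rnorm(4, 0, 0.7)))
    n <- sample(5:30, 4, TRUE)
    base <- ws_power(cells, n)$power
    for (k in 1:4) {
      up <- n
      up[k] <- up[k] + 1
      expect_gt(ws_power(cells, up)$power, base)
    }
    # negating all coefficients flips the sign of psi but not |delta|
    flipped <- dplyr::mutate(cells, coef = -coef)
    expect_equal(ws_power(flipped, n)$power, base)
  }
})

test_that("fractional allocations are accepted by the power pipeline", {
  pw <- ws_power(vg_cells(), c(19.83, 39.64, 59.45, 79.26))
  expect_true(pw$power > 0.79 && pw$power < 0.81)
  expect_true(pw$df > 0)
})

test_that("total cost is linear in sizes with overhead", {
  expect_equal(
    allocation_cost(ec_cells("interaction", ec_cost_varied), c(11, 16, 13, 19)),
    18604.08
  )
  expect_equal(allocation_cost(ec_cells("mainB"), c(56, 49, 23, 52)), 180)
  expect_equal(allocation_cost(vg_cells(), c(2, 2, 2, 2), overhead = 100), 108)
  expect_error(allocation_cost(vg_cells(), c(2, 2, 2, 2), overhead = -1),
               "nonnegative")
})

test_that("power curves rise with scale and plot", {
  pc <- power_curve(vg_cells(), c(10, 20, 30, 40), scale = c(0.5, 1, 1.5, 2))
  expect_true(all(diff(pc$power) > 0))
  expect_s3_class(autoplot(pc), "ggplot")
})
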
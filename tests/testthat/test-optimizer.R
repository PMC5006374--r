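test_that("a fully symmetric problem has a balanced continuous solution", {
  cells <- factorial_cells(c(1, 0, 0, 1), variances = rep(4, 4))
  cont <- continuous_optimum(cells, target_power = 0.8)
  expect_lt(max(cont) - min(cont), 1e-3 * mean(cont))
  expect_equal(ws_power(cells, cont)$power, 0.8, tolerance = 1e-8)
})

test_that("the continuous solution lower-bounds every feasible integer allocation", {
  cells <- ec_cells("interaction")  # equal unit costs
  cont <- continuous_optimum(cells, target_power = 0.8)
  cont_cost <- sum(cont)
  # brute force over a generous integer box
  grid <- as.matrix(expand.grid(10:22, 8:20, 3:13, 9:21))
  cost <- rowSums(grid)
  cheaper <- grid[cost < cont_cost - 1e-6, , drop = FALSE]
  pw <- apply(cheaper, 1, function(n) ws_power(cells, n)$power)
  expect_true(all(pw < 0.8))
})

test_that("screening returns an integer continuous solution unchanged", {
  cells <- vg_cells()
  n0 <- c(21, 41, 61, 80)
  target <- ws_power(cells, n0)$power  # boundary: n0 itself is feasible
  scr <- screen_candidates(cells, as.numeric(n0), target_power = target)
  expect_identical(scr$sizes, as.integer(n0))
  expect_equal(nrow(scr$candidates), 16)
})

test_that("screening audits all sixteen candidates and respects the tie-break chain", {
  cells <- vg_cells(c(1, 2, 3, 4))
  cont <- continuous_optimum(cells, 0.8)
  scr <- screen_candidates(cells, cont, 0.8)
  cand <- scr$candidates
  expect_equal(nrow(cand), 16)
  expect_true(all(cand$feasible[cand$n11 == max(cand$n11) &
                                  cand$n12 == max(cand$n12) &
                                  cand$n21 == max(cand$n21) &
                                  cand$n22 == max(cand$n22)]))
  feas <- cand[cand$feasible, ]
  best_cost <- min(feas$cost)
  expect_equal(scr$cost, best_cost)
  expect_equal(scr$power, max(feas$power[feas$cost == best_cost]))
})

test_that("optimal allocations reproduce benchmark scenarios with audit invariants", {
  for (i in c(2, 3, 5)) {  # a spread of the variance-gradient cost patterns
    sc <- vg_scenarios[i, ]
    fit <- optimize_allocation(vg_cells(sc$unit_costs[[1]]), target_power = 0.8)
    expect_identical(fit$sizes, sc$opt_n[[1]])
    expect_equal(fit$cost, sc$opt_cost)
    # invariants of the result object
    expect_gte(fit$power, 0.8)
    expect_equal(fit$cost, sum(sc$unit_costs[[1]] * fit$sizes))
    expect_equal(fit$total_n, sum(fit$sizes))
    in_audit <- any(
      fit$candidates$n11 == fit$sizes[1] & fit$candidates$n12 == fit$sizes[2] &
        fit$candidates$n21 == fit$sizes[3] & fit$candidates$n22 == fit$sizes[4] &
        fit$candidates$feasible
    )
    expect_true(in_audit)
    # dominance over the naive all-ceiling adjustment
    ceiling_cost <- sum(sc$unit_costs[[1]] * (floor(fit$continuous) + 1))
    expect_lte(fit$cost, ceiling_cost)
  }
})

test_that("rescaling all unit costs rescales the cost but not the allocation", {
  fit1 <- optimize_allocation(vg_cells(c(1, 2, 3, 4)), target_power = 0.8)
  fit3 <- optimize_allocation(vg_cells(3 * c(1, 2, 3, 4)), target_power = 0.8)
  expect_identical(fit3$sizes, fit1$sizes)
  expect_equal(fit3$cost, 3 * fit1$cost)
})

test_that("with unit costs of one, total cost equals total sample size", {
  fit <- optimize_allocation(ec_cells("mainA"), target_power = 0.8)
  expect_equal(fit$cost, fit$total_n)
})

test_that("a zero contrast effect is rejected as infeasible", {
  cells <- factorial_cells(rep(1, 4), variances = 1:4)
  expect_error(optimize_allocation(cells), "Infeasible")
  expect_error(luh_guo_allocation(cells), "Infeasible")
})

test_that("overhead shifts the reported cost without moving the optimum", {
  fit0 <- optimize_allocation(vg_cells(c(5, 2, 1, 1)), target_power = 0.8)
  fit500 <- optimize_allocation(vg_cells(c(5, 2, 1, 1)), target_power = 0.8,
                                overhead = 500)
  expect_identical(fit500$sizes, fit0$sizes)
  expect_equal(fit500$cost, fit0$cost + 500)
})

test_that("control settings are validated", {
  expect_error(allocation_control(cell_floor = 1), "at least 2")
  expect_error(allocation_control(power_slack = 1e-3), "1e-6")
})

test_that("tidy, glance and autoplot expose the fitted allocation", {
  fit <- optimize_allocation(vg_cells(), target_power = 0.8)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(td$n, fit$sizes)
  gl <- glance(fit)
  expect_equal(gl$total_cost, fit$cost)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Cost-optimal allocation")
})
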
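# Shared planning configurations used across the test files.
#
# Emergency-care design: real planning values (means on a transformed cost
# scale) with mild heteroscedasticity; two unit-cost sets, one strongly
# varied and one flat.
ec_means <- c(1.23, 0.42, 0.13, 0.38)
ec_vars <- c(0.6889, 0.5184, 0.1156, 0.5929)
ec_cost_varied <- c(784.74, 267.96, 82.94, 242.44)

# Variance-gradient design: hypothetical cells with variances 1..16 and an
# interaction effect of 2, stressed under six unit-cost patterns.
vg_means <- c(1, 0, 0, 1)
vg_vars <- c(1, 4, 9, 16)
vg_cost_sets <- list(
  equal = c(1, 1, 1, 1), rising = c(1, 2, 3, 4), falling = c(4, 3, 2, 1),
  late_heavy = c(1, 1, 2, 5), early_heavy = c(5, 2, 1, 1),
  inner_heavy = c(1, 3, 3, 1)
)

ec_cells <- function(contrast, unit_costs = 1) {
  factorial_cells(ec_means, variances = ec_vars, contrast = contrast,
                  unit_costs = unit_costs)
}
vg_cells <- function(unit_costs = 1) {
  factorial_cells(vg_means, variances = vg_vars, contrast = "interaction",
                  unit_costs = unit_costs)
}

# The twelve benchmark scenarios (six per design) with their published
# optimal allocations, total costs, attained powers (4 decimals) and the
# two-step comparator's results.
ec_scenarios <- tibble::tribble(
  ~contrast, ~cost_set, ~opt_n, ~opt_cost, ~opt_power, ~lg_n, ~lg_cost, ~lg_power,
  "interaction", "varied", c(11L, 16L, 13L, 19L), 18604.08, 0.8005, c(12L, 17L, 14L, 19L), 19739.72, 0.8254,
  "interaction", "equal",  c(16L, 14L,  7L, 15L),    52.00, 0.8038, c(17L, 14L,  7L, 15L),    53.00, 0.8113,
  "mainA",       "varied", c(10L, 13L, 12L, 16L), 16205.20, 0.8004, c(10L, 15L, 13L, 17L), 17066.50, 0.8208,
  "mainA",       "equal",  c(14L, 12L,  6L, 13L),    45.00, 0.8014, c(15L, 13L,  6L, 14L),    48.00, 0.8273,
  "mainB",       "varied", c(38L, 56L, 48L, 62L), 63838.28, 0.8000, c(38L, 57L, 48L, 64L), 64591.12, 0.8046,
  "mainB",       "equal",  c(56L, 49L, 23L, 52L),   180.00, 0.8021, c(56L, 49L, 23L, 52L),   180.00, 0.8021
)
ec_scenarios$unit_costs <- lapply(
  ec_scenarios$cost_set, function(s) if (s == "varied") ec_cost_varied else rep(1, 4)
)

vg_scenarios <- tibble::tribble(
  ~cost_set, ~opt_n, ~opt_cost, ~opt_power, ~lg_n, ~lg_cost, ~lg_power,
  "equal",       c(20L, 40L, 60L, 79L),  199, 0.8016, c(20L, 40L, 60L,  80L), 200, 0.8036,
  "rising",      c(33L, 48L, 58L, 68L),  575, 0.8000, c(34L, 48L, 59L,  68L), 579, 0.8028,
  "falling",     c(14L, 32L, 57L, 108L), 374, 0.8009, c(14L, 32L, 58L, 109L), 377, 0.8041,
  "late_heavy",  c(32L, 63L, 68L, 58L),  521, 0.8001, c(33L, 65L, 69L,  58L), 526, 0.8038,
  "early_heavy", c(11L, 34L, 72L, 95L),  290, 0.8006, c(11L, 34L, 73L,  97L), 293, 0.8046,
  "inner_heavy", c(27L, 32L, 47L, 107L), 371, 0.8004, c(28L, 32L, 48L, 109L), 377, 0.8067
)
vg_scenarios$unit_costs <- vg_cost_sets[vg_scenarios$cost_set]

# Long-format sample with the given per-cell observations (list of four
# numeric vectors in cell order).
long_sample <- function(obs) {
  tibble::tibble(
    factor_a = rep(c(1L, 1L, 2L, 2L), lengths(obs)),
    factor_b = rep(c(1L, 2L, 1L, 2L), lengths(obs)),
    response = unlist(obs)
  )
}
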
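---
title: "Power, cost and optimal allocation for heteroscedastic 2x2 factorial designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power, cost and optimal allocation for heteroscedastic 2x2 factorial designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(welch22)
```

## The design problem

A 2x2 factorial study crosses two factors, each at two levels, and asks
questions about linear combinations of the four cell means: the two main
effects and, most importantly, the interaction. When the cell variances are
unequal — the rule rather than the exception in clinical and behavioural
data — the classical pooled-variance *t* and ANOVA procedures misbehave, and
the Welch–Satterthwaite test is the standard replacement. welch22 answers
the planning question for that test: **how many subjects should go into each
cell so that the test attains a target power at the smallest possible
study cost**, when recruiting a subject may cost a different amount in each
cell.

## Model and power function

Observations are independent normals with cell-specific means and variances,

$$X_{ijk} \sim N(\mu_{ij}, \sigma_{ij}^2), \qquad i,j \in \{1,2\},
\quad k = 1, \dots, N_{ij},$$

and the effect of interest is $\psi = \sum_{ij} L_{ij}\,\mu_{ij}$ with
coefficients $L_{ij}$ chosen by the analyst (`factorial_cells()` offers the
unit-coefficient presets; all four-cell vectors everywhere in the package
are in the row-major cell order (1,1), (1,2), (2,1), (2,2)). The test
statistic is

$$T^* = \frac{\hat\psi - \psi_0}{\hat\omega}, \qquad
\hat\omega^2 = \sum_{ij} \frac{L_{ij}^2 S_{ij}^2}{N_{ij}},$$

referred to a *t* distribution with the data-dependent
Welch–Satterthwaite degrees of freedom $\hat\nu$ (`welch_contrast_test()`).
For planning, the population-variance analogue of $\hat\nu$,

$$\nu = \frac{\left(\sum L_{ij}^2\sigma_{ij}^2/N_{ij}\right)^2}
{\sum L_{ij}^4\sigma_{ij}^4 \,/\, \left[N_{ij}^2 (N_{ij}-1)\right]},$$

together with the noncentrality $\delta = (\psi - \psi_0)/\omega$, gives the
approximate power function used throughout:

$$\pi(\delta) = P\{\,|t(\nu, \delta)| > t_{\nu, \alpha/2}\,\}.$$

`ws_power()` evaluates this via the noncentral *t* distribution functions of
base R. Two numerical details are worth stating. First, when $\delta = 0$
the identity $\pi(0) = \alpha$ is returned exactly rather than through the
noncentral CDF, so the size property holds to machine precision. Second,
$\nu$ is well defined for *fractional* cell sizes, and the optimizer relies
on that: sizes are treated as continuous during optimization and only
restored to integers at the end.

The approximation is accurate in practice: across the twelve benchmark
scenarios exercised by the test suite, 10,000-replication Monte Carlo power
(`simulate_power()`) stays within about 0.01 of $\pi(\delta)$, and the
acceptance script recomputes that gap on every run.

## Cost-optimal allocation

Study cost is modelled linearly: $C_T = C_O + \sum_{ij} C_{ij} N_{ij}$ with
fixed overhead $C_O$ and per-subject cell costs $C_{ij}$. With $C_O = 0$
and unit costs all 1, cost is simply the total sample size, so "cheapest
design" and "smallest study" are the same special case.

`optimize_allocation()` minimizes $C_T$ subject to
$\pi(\delta) \ge 1 - \beta$ in three stages:

1. **Continuous stage** (`continuous_optimum()`). The four sizes are
   continuous. Because power is strictly increasing in every cell size
   (when its coefficient is nonzero), the constraint is active at any
   optimum, which suggests the parametrization the package uses: search
   over the three log size-*ratios*, and for each candidate ratio vector
   solve the one-dimensional equation $\pi = 1-\beta$ for the common scale
   by bisection (`uniroot`, tolerance 1e-11). Every evaluated allocation
   then lies exactly on the constraint boundary, and the outer problem is a
   smooth three-parameter minimization handled by Nelder–Mead with a BFGS
   polish. The outer search starts from the normal-theory ratios of
   `allocation_ratios()` (cell standard deviation over the square root of
   the cell unit cost), which are close to optimal, plus a handful of
   deterministic perturbations of that start; the optimizer involves no
   random numbers, so results are reproducible without a seed. Cell sizes
   are bounded below by 2, the weakest floor under which every cell sample
   variance exists.

2. **Floor/ceiling screen** (`screen_candidates()`). The continuous
   solution is almost never integer. All $2^4 = 16$ combinations of
   rounding each cell down or up are evaluated; among the combinations that
   meet the power target (always a nonempty set, since the all-ceiling
   combination is feasible) the cheapest is kept. Cost ties are broken by
   largest power, then smallest total size, then lexicographic order of the
   four cells — the last two rules exist purely to make the choice
   deterministic. The screen is evaluated with a feasibility slack of
   1e-10 so that an allocation whose power equals the target up to rounding
   is not excluded on a knife edge. All sixteen candidates are kept in the
   result as an audit trail.

3. **Box refinement.** The floor/ceiling box is a heuristic neighbourhood:
   the cheapest feasible *integer* allocation can, in uncommon cost
   geometries, sit just outside it (one cell two units away from the
   continuous value, compensated by others). The package therefore finishes
   with an exhaustive search of the integer box extending `refine_radius`
   (default 5) units around the continuous solution, pruned to allocations
   no more expensive than the screened choice, all evaluated in one
   vectorized power computation. If this finds a strictly cheaper feasible
   allocation — or an equally cheap one with larger power — it replaces the
   screened choice and the result's `screen_suboptimal` flag records that
   the screen alone would have been misled. Two of the twelve benchmark
   scenarios in the test suite exercise exactly this situation. Exhaustive
   search over the box also means the returned allocation is provably
   optimal within it; the test suite re-verifies this with an independent
   brute-force pass for every benchmark scenario.

## The two-step comparator

`luh_guo_allocation()` implements the earlier two-step procedure the
optimizer is designed to improve on. It fixes the allocation ratios at
$r_{ij} = \sigma_{ij}\sqrt{C_{11}}/(\sigma_{11}\sqrt{C_{ij}})$ — optimal
under a known-variance normal approximation — then sizes the first cell
with standard-normal quantiles,
$N_{Z11} = (z_{\alpha/2} + z_\beta)^2 w^2/(\psi - \psi_0)^2$ with
$w^2 = \sum L_{ij}^2\sigma_{ij}^2/r_{ij}$, computes approximate degrees of
freedom at the resulting fractional sizes, resizes with $t$ quantiles, and
finally rounds every cell with $\lfloor N_T\rfloor + 1$. Three faithful
implementation choices matter for exact reproduction of its published
results: the stage-one sizes stay fractional when the degrees of freedom
are computed (no intermediate rounding); the procedure runs exactly once
(no fixed-point iteration); and the rounding rule literally adds one even
when $N_T$ happens to be an exact integer (`exact_ceiling = TRUE` switches
to a true ceiling, default off). The comparator generally costs more than
the optimized allocation — the ratios ignore the noncentral-*t* geometry
and the rounding ignores cost — and the package's tests confirm its cost is
never smaller across all benchmark scenarios, with equality only in the
flat-cost main-effect scenario where the two methods coincide.

## Monte Carlo engine

`simulate_power()` draws each replication from the assumed normal model —
cell (1,1) for all replications first, then (1,2), (2,1), (2,2) — applies
the data-level test, and reports the rejection proportion with its binomial
standard error alongside $\pi(\delta)$ and the difference. Statistics are
computed vectorized across replications with the same formulas as
`welch_contrast_test()`, and a unit test pins the two code paths together
replication by replication. Given a seed the result is bitwise
reproducible, and the seed is applied without disturbing the caller's RNG
state. The generator emulates exactly the assumptions of the planning
model: independent normal cells with known planning variances. It does not
emulate skewed or heavy-tailed responses, dependence, dropout, or variance
misspecification — so agreement between simulated and approximate power
validates the *approximation*, not the robustness of the design to wrong
planning values.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided significance level of the test |
| `target_power` | 0.8 | required $1-\beta$ at the planning effect |
| `null_value` | 0 | $\psi_0$, response-scale units |
| `unit_costs` | 1 | per-subject cost of each cell, currency units |
| `overhead` | 0 | fixed cost $C_O$, shifts cost but never the optimum |
| `cell_floor` | 2 | smallest admissible cell size |
| `restarts` | 4 | extra deterministic starts of the continuous stage |
| `power_slack` | 1e-10 | feasibility slack at the integer screen |
| `refine_radius` | 5 | half-width of the final integer search box |
| `reps` | 10000 | Monte Carlo replications (SE $\approx 0.004$ at power 0.8) |

## Degenerate inputs and edge cases

A zero planning effect ($\psi = \psi_0$) makes every target power
unattainable and raises an infeasibility error in both allocation methods.
Cells with zero contrast coefficient contribute nothing to power, so the
optimizer drives them to the floor of 2. A raw sample in which every
active cell is constant has $\hat\omega = 0$ and is rejected as degenerate
rather than yielding an infinite statistic, since the approximation's
derivation assumes positive variances. Coefficient conventions are the
caller's: the package does not rescale $L_{ij}$, because power is invariant
only to *joint* rescaling of the coefficients and $\psi - \psi_0$.

## Problem sizes used in the tests

The test suite works at the scale the methodology is meant for: designs of
roughly 45–225 subjects, brute-force verification boxes of about 10^4–10^5
integer allocations per scenario, property checks over a few dozen
randomized configurations, and Monte Carlo validation at 10,000
replications per scenario (smaller counts are used for quick calibration
checks where binomial error bounds are applied explicitly).

## Limitations

The package covers a single linear combination of four heteroscedastic
normal cells: no designs larger than 2x2, no simultaneous inference on
several contrasts with multiplicity control, no one-sided tests, no
budget-constrained power *maximization* (the dual problem), and no robust
(trimmed or rank-based) test variants. The attained power is the
noncentral-*t* approximation; it is validated by simulation under the
normal model but is still an approximation to the exact distribution of the
Welch–Satterthwaite statistic.
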
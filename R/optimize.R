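#' Control settings for the allocation optimizer
#'
#' @param cell_floor Smallest admissible cell size (default 2, the weakest
#'   bound under which every cell sample variance exists).
#' @param restarts Number of deterministically perturbed starting directions
#'   tried in addition to the normal-theory start.
#' @param max_iterations Iteration cap per Nelder-Mead run.
#' @param reltol Relative convergence tolerance of the continuous stage.
#' @param power_slack Feasibility slack used when screening integer
#'   candidates, guarding against knife-edge exclusion of allocations whose
#'   power equals the target to rounding; must lie in [0, 1e-6].
#' @param refine_radius Half-width of the integer box searched exhaustively
#'   around the continuous solution after the sixteen-candidate screen
#'   (0 disables refinement).
#' @return A list of class `allocation_control`.
#' @export
allocation_control <- function(cell_floor = 2L, restarts = 4L,
                               max_iterations = 2000L, reltol = 1e-13,
                               power_slack = 1e-10, refine_radius = 5L) {
  if (cell_floor < 2) abort("`cell_floor` must be at least 2.")
  if (power_slack < 0 || power_slack > 1e-6) {
    abort("`power_slack` must lie in [0, 1e-6].")
  }
  structure(
    list(cell_floor = as.integer(cell_floor), restarts = as.integer(restarts),
         max_iterations = as.integer(max_iterations), reltol = reltol,
         power_slack = power_slack, refine_radius = as.integer(refine_radius)),
    class = "allocation_control"
  )
}

#' Continuous cost-minimizing allocation under a power constraint
#'
#' Stage one of [optimize_allocation()]: treats the four cell sizes as
#' continuous variables and minimizes the linear cost
#' \eqn{C_T = C_O + \sum C_{ij} N_{ij}} subject to the approximate power
#' [ws_power()] being at least `target_power` and every size at least
#' `cell_floor`. The search is parametrized by the three log size-ratios;
#' for any candidate direction the power constraint is solved exactly for
#' the common scale by root finding (power is increasing in scale), so every
#' evaluated allocation sits on the constraint boundary and the outer
#' minimization is over ratios only. The outer search runs Nelder-Mead from
#' the normal-theory ratios of [allocation_ratios()] plus deterministic
#' perturbations, with a quasi-Newton polish.
#'
#' @inheritParams luh_guo_allocation
#' @param control An [allocation_control()] list.
#' @return A numeric vector of four (generally fractional) cell sizes whose
#'   approximate power equals the target (up to root-finding tolerance)
#'   unless the floor binds.
#' @export
continuous_optimum <- function(cells, target_power = 0.8, null_value = 0,
                               alpha = 0.05, overhead = 0,
                               control = allocation_control()) {
  cells <- check_cells(cells)
  check_alpha(alpha)
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must be strictly between 0 and 1.")
  }
  psi <- sum(cells$coef * cells$mean)
  shift <- psi - null_value
  if (shift == 0) {
    abort("Infeasible design: the contrast effect equals the null value, so no sample size attains the target power.")
  }
  l2v <- cells$coef^2 * cells$variance
  l4v2 <- cells$coef^4 * cells$variance^2
  cost <- cells$unit_cost
  floor_n <- control$cell_floor

  scale_to_target <- function(u) {
    f <- function(s) {
      n <- pmax(s * u, floor_n)
      power_t(ws_df(n, l2v, l4v2), shift / sqrt(sum(l2v / n)), alpha) -
        target_power
    }
    lo <- floor_n / max(u)
    hi <- 2 * lo
    while (f(hi) < 0) hi <- 2 * hi
    uniroot(f, c(lo, hi), tol = 1e-11)$root
  }
  objective <- function(theta) {
    theta <- pmin(pmax(theta, -15), 15)
    u <- c(1, exp(theta))
    s <- scale_to_target(u)
    sum(cost * pmax(s * u, floor_n))
  }

  r0 <- allocation_ratios(cells)
  base <- log(r0[-1] / r0[1])
  # deterministic perturbations of the starting ratios, no RNG involved
  pert <- list(c(0.25, 0, -0.25), c(-0.25, 0.25, 0), c(0, -0.25, 0.25),
               c(0.4, 0.4, 0.4), c(-0.4, -0.4, -0.4), c(0.3, -0.3, 0.3))
  starts <- c(list(base),
              lapply(utils::head(pert, control$restarts), function(p) base + p))
  best <- NULL
  for (th0 in starts) {
    fit <- optim(th0, objective, method = "Nelder-Mead",
                 control = list(maxit = control$max_iterations,
                                reltol = control$reltol))
    fit <- optim(fit$par, objective, method = "Nelder-Mead",
                 control = list(maxit = control$max_iterations,
                                reltol = control$reltol))
    polish <- tryCatch(
      optim(fit$par, objective, method = "BFGS",
            control = list(maxit = 200, reltol = control$reltol)),
      error = function(e) fit
    )
    if (polish$value <= fit$value) fit <- polish
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) {
    abort("Continuous optimization failed to converge from every start.")
  }
  u <- c(1, exp(pmin(pmax(best$par, -15), 15)))
  pmax(scale_to_target(u) * u, floor_n)
}

#' Screen the sixteen floor/ceiling integer allocations
#'
#' Stage two of [optimize_allocation()]: evaluates approximate power and
#' total cost for all \eqn{2^4 = 16} integer allocations obtained by taking
#' each cell of the continuous solution to its floor or floor plus one
#' (floors clamped to `cell_floor`), and selects the feasible combination
#' with least cost. Cost ties are broken by largest power, then smallest
#' total size, then lexicographic order of the four cells. The all-ceiling
#' combination always meets the power target, so a feasible candidate always
#' exists. All sixteen candidates are returned as an audit trail.
#'
#' This screen is a heuristic: the true integer optimum can fall outside the
#' floor/ceiling box. [optimize_allocation()] follows it with an exhaustive
#' box refinement and flags any improvement.
#'
#' @inheritParams continuous_optimum
#' @param continuous A length-4 numeric vector of continuous cell sizes,
#'   typically from [continuous_optimum()].
#' @return A list with `sizes`, `power`, `cost`, `total_n` of the selected
#'   allocation and a 16-row `candidates` tibble
#'   (`n11,n12,n21,n22,power,cost,total_n,feasible`).
#' @export
screen_candidates <- function(cells, continuous, target_power = 0.8,
                              null_value = 0, alpha = 0.05, overhead = 0,
                              control = allocation_control()) {
  cells <- check_cells(cells)
  lo <- pmax(floor(continuous), control$cell_floor)
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  nmat <- sweep(grid, 2, lo, "+")
  nmat <- pmax(nmat, control$cell_floor)
  select_best(cells, nmat, target_power, null_value, alpha, overhead,
              control$power_slack)
}

# Evaluate a matrix of integer allocations, pick least cost among feasible
# with the deterministic tie-break chain. Returns selection + audit tibble.
select_best <- function(cells, nmat, target_power, null_value, alpha,
                        overhead, power_slack) {
  psi <- sum(cells$coef * cells$mean)
  l2v <- cells$coef^2 * cells$variance
  l4v2 <- cells$coef^4 * cells$variance^2
  pw <- power_matrix(nmat, l2v, l4v2, psi - null_value, alpha)
  cost <- overhead + as.vector(nmat %*% cells$unit_cost)
  total_n <- rowSums(nmat)
  feasible <- pw >= target_power - power_slack
  cand <- tibble(
    n11 = nmat[, 1], n12 = nmat[, 2], n21 = nmat[, 3], n22 = nmat[, 4],
    power = pw, cost = cost, total_n = total_n, feasible = feasible
  )
  idx <- which(feasible)
  if (!length(idx)) abort("No feasible integer candidate found.")
  ord <- idx[order(cost[idx], -pw[idx], total_n[idx],
                   nmat[idx, 1], nmat[idx, 2], nmat[idx, 3], nmat[idx, 4])]
  i <- ord[1]
  list(sizes = as.integer(nmat[i, ]), power = pw[i], cost = cost[i],
       total_n = as.integer(total_n[i]), candidates = cand)
}

#' Cost-optimal integer allocation for a target power
#'
#' Finds the cheapest integer allocation of subjects to the four cells of a
#' heteroscedastic 2x2 factorial design such that the Welch-Satterthwaite
#' test of the planned contrast attains a target approximate power. Three
#' stages: (1) [continuous_optimum()] minimizes cost over continuous sizes
#' with the power constraint active; (2) [screen_candidates()] evaluates the
#' sixteen floor/ceiling integer combinations around the continuous solution
#' and keeps the cheapest feasible one; (3) an exhaustive, cost-pruned search
#' of the integer box of half-width `refine_radius` around the continuous
#' solution replaces the screened choice if a strictly cheaper (or equally
#' cheap, more powerful) feasible allocation exists there, in which case
#' `screen_suboptimal` is set. Stage 3 guards against the rare geometry in
#' which the true integer optimum lies outside the floor/ceiling box.
#'
#' @inheritParams luh_guo_allocation
#' @param control An [allocation_control()] list.
#' @return An object of class `ws_allocation`: a list with the continuous
#'   solution, the final integer `sizes`, attained `power`, total `cost` and
#'   `total_n`, the screened choice, a `screen_suboptimal` flag, and the
#'   candidate audit trail (the sixteen screened allocations plus, when
#'   refinement wins, the refined one tagged in `source`). Use [tidy()],
#'   [glance()] or [autoplot()] on the result.
#' @examples
#' cells <- factorial_cells(c(1, 0, 0, 1), variances = c(1, 4, 9, 16))
#' fit <- optimize_allocation(cells, target_power = 0.8)
#' fit
#' glance(fit)
#' @export
optimize_allocation <- function(cells, target_power = 0.8, null_value = 0,
                                alpha = 0.05, overhead = 0,
                                control = allocation_control()) {
  cells <- check_cells(cells)
  cont <- continuous_optimum(cells, target_power, null_value, alpha,
                             overhead, control)
  scr <- screen_candidates(cells, cont, target_power, null_value, alpha,
                           overhead, control)
  cand <- dplyr::mutate(scr$candidates, source = "screen")
  best <- scr
  screen_suboptimal <- FALSE
  if (control$refine_radius > 0) {
    ref <- refine_box(cells, cont, scr, target_power, null_value, alpha,
                      overhead, control)
    if (!is.null(ref)) {
      screen_suboptimal <- TRUE
      best <- ref
      cand <- dplyr::bind_rows(
        cand,
        tibble(n11 = ref$sizes[1], n12 = ref$sizes[2], n21 = ref$sizes[3],
               n22 = ref$sizes[4], power = ref$power, cost = ref$cost,
               total_n = ref$total_n, feasible = TRUE, source = "refine")
      )
    }
  }
  structure(
    list(
      cells = cells, target_power = target_power, alpha = alpha,
      null_value = null_value, overhead = overhead, control = control,
      continuous = cont, sizes = best$sizes, power = best$power,
      cost = best$cost, total_n = best$total_n,
      screen_sizes = scr$sizes, screen_cost = scr$cost,
      screen_suboptimal = screen_suboptimal, candidates = cand
    ),
    class = "ws_allocation"
  )
}

# Exhaustive cost-pruned search of the +/- radius integer box around the
# continuous solution; NULL unless it strictly improves on the screen
# (cheaper, or equally cheap with larger power).
refine_box <- function(cells, cont, scr, target_power, null_value, alpha,
                       overhead, control) {
  r <- control$refine_radius
  lo <- pmax(floor(cont) - r, control$cell_floor)
  hi <- floor(cont) + 1 + r
  grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2],
                                lo[3]:hi[3], lo[4]:hi[4]))
  cost <- overhead + as.vector(grid %*% cells$unit_cost)
  keep <- cost <= scr$cost + 1e-9
  if (!any(keep)) return(NULL)
  sel <- select_best(cells, grid[keep, , drop = FALSE], target_power,
                     null_value, alpha, overhead, control$power_slack)
  improves <- sel$cost < scr$cost - 1e-9 ||
    (abs(sel$cost - scr$cost) <= 1e-9 && sel$power > scr$power + 1e-12)
  if (improves) sel else NULL
}

#' @export
print.ws_allocation <- function(x, ...) {
  cat("Cost-optimal allocation for the Welch-Satterthwaite test (2x2)\n")
  cat(sprintf("  continuous solution {%s}\n",
              paste(round(x$continuous, 3), collapse = ", ")))
  cat(sprintf("  optimal sizes       {%s}  total n %d\n",
              paste(x$sizes, collapse = ", "), x$total_n))
  cat(sprintf("  total cost %.2f, approximate power %.4f (target %.2f)\n",
              x$cost, x$power, x$target_power))
  if (x$screen_suboptimal) {
    cat(sprintf(
      "  note: box refinement improved on the 16-candidate screen ({%s}, cost %.2f)\n",
      paste(x$screen_sizes, collapse = ", "), x$screen_cost))
  }
  invisible(x)
}

#' Tidiers for optimal allocations
#'
#' @param x A `ws_allocation` object from [optimize_allocation()].
#' @param ... Ignored.
#' @return `tidy()` returns one row per cell with the continuous and integer
#'   sizes and unit costs; `glance()` returns a one-row summary with sizes,
#'   attained power, total cost and total n.
#' @export
tidy.ws_allocation <- function(x, ...) {
  tibble(
    factor_a = x$cells$factor_a, factor_b = x$cells$factor_b,
    coef = x$cells$coef, variance = x$cells$variance,
    unit_cost = x$cells$unit_cost,
    n_continuous = x$continuous, n = x$sizes
  )
}

#' @rdname tidy.ws_allocation
#' @export
glance.ws_allocation <- function(x, ...) {
  tibble(
    n11 = x$sizes[1], n12 = x$sizes[2], n21 = x$sizes[3], n22 = x$sizes[4],
    total_cost = x$cost, total_n = x$total_n, power = x$power,
    target_power = x$target_power, alpha = x$alpha,
    screen_suboptimal = x$screen_suboptimal
  )
}

#' @rdname tidy.ws_allocation
#' @param object A `ws_allocation` object.
#' @export
autoplot.ws_allocation <- function(object, ...) {
  cand <- object$candidates
  chosen <- cand$n11 == object$sizes[1] & cand$n12 == object$sizes[2] &
    cand$n21 == object$sizes[3] & cand$n22 == object$sizes[4]
  cand$status <- dplyr::case_when(
    chosen ~ "selected",
    cand$feasible ~ "feasible",
    TRUE ~ "infeasible"
  )
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$cost, y = .data$power,
                                     colour = .data$status,
                                     shape = .data$source)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = object$target_power, linetype = 2) +
    ggplot2::labs(x = "Total cost", y = "Approximate power",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
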
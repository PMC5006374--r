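#' Normal-theory allocation ratios
#'
#' The large-sample optimal cell-size ratios under a known-variance normal
#' approximation: each cell's size is proportional to its standard deviation
#' divided by the square root of its unit cost,
#' \deqn{r_{ij} = N_{ij}/N_{11} =
#'   \sigma_{ij} C_{11}^{1/2} / (\sigma_{11} C_{ij}^{1/2}),}
#' so \eqn{r_{11} = 1}. These ratios drive the two-step comparator of
#' [luh_guo_allocation()] and serve as the starting direction of the
#' continuous optimizer.
#'
#' @inheritParams contrast_effect
#' @return A numeric vector of four positive ratios with first element 1.
#' @export
allocation_ratios <- function(cells) {
  cells <- check_cells(cells)
  sd <- sqrt(cells$variance)
  (sd / sd[1]) * sqrt(cells$unit_cost[1] / cells$unit_cost)
}

#' Two-step normal/t allocation (Luh-Guo comparator)
#'
#' The existing two-step sample-size procedure for the Welch-Satterthwaite
#' test under a cost constraint, implemented for side-by-side comparison
#' with [optimize_allocation()]. Stage one fixes the cell-size ratios at
#' [allocation_ratios()] and sizes the design with standard-normal
#' quantiles:
#' \deqn{N_{Z11} = (z_{\alpha/2} + z_\beta)^2 w^2 / (\psi - \psi_0)^2,
#'   \quad w^2 = \sum L_{ij}^2\sigma_{ij}^2 / r_{ij},}
#' with \eqn{N_{Zij} = N_{Z11} r_{ij}} kept fractional. Stage two computes
#' approximate degrees of freedom \eqn{\upsilon} by the Welch-Satterthwaite
#' formula evaluated at the fractional \eqn{N_{Zij}}, replaces the normal
#' quantiles by \eqn{t(\upsilon)} quantiles to get \eqn{N_{T11}} and
#' \eqn{N_{Tij} = N_{T11} r_{ij}}, and finally rounds each cell up via
#' \eqn{N_{LGij} = \lfloor N_{Tij}\rfloor + 1}. No iteration beyond the two
#' stages is performed and nothing is rounded between them.
#'
#' The literal rounding rule adds one even when \eqn{N_{Tij}} is an exact
#' integer; set `exact_ceiling = TRUE` for a true ceiling instead (not the
#' procedure's stated rule, so off by default).
#'
#' @inheritParams ws_power
#' @param target_power Desired power \eqn{1 - \beta} in (0, 1).
#' @param overhead Fixed overhead cost \eqn{C_O \ge 0}.
#' @param exact_ceiling Use `ceiling(N_T)` instead of `floor(N_T) + 1`.
#' @return An object of class `ws_luh_guo`: a list with the ratios, `w2`,
#'   the fractional normal-stage sizes `n_normal`, stage df `df_stage`, the
#'   fractional t-stage sizes `n_t`, the final integer `sizes`, and the
#'   attained approximate power, total cost and total size of the final
#'   allocation. Use [tidy()] / [glance()] for tabular views.
#' @examples
#' cells <- factorial_cells(c(1, 0, 0, 1), variances = c(1, 4, 9, 16))
#' luh_guo_allocation(cells, target_power = 0.8)
#' @export
luh_guo_allocation <- function(cells, target_power = 0.8, null_value = 0,
                               alpha = 0.05, overhead = 0,
                               exact_ceiling = FALSE) {
  cells <- check_cells(cells)
  check_alpha(alpha)
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must be strictly between 0 and 1.")
  }
  psi <- sum(cells$coef * cells$mean)
  shift <- psi - null_value
  if (shift == 0) {
    abort("Infeasible design: the contrast effect equals the null value.")
  }
  r <- allocation_ratios(cells)
  beta <- 1 - target_power
  w2 <- sum(cells$coef^2 * cells$variance / r)
  n_z11 <- (qnorm(1 - alpha / 2) + qnorm(1 - beta))^2 * w2 / shift^2
  n_z <- n_z11 * r
  l2v <- cells$coef^2 * cells$variance
  l4v2 <- cells$coef^4 * cells$variance^2
  df_stage <- ws_df(n_z, l2v, l4v2)
  n_t11 <- (qt(1 - alpha / 2, df_stage) + qt(1 - beta, df_stage))^2 * w2 / shift^2
  n_t <- n_t11 * r
  sizes <- if (exact_ceiling) ceiling(n_t) else floor(n_t) + 1
  sizes <- pmax(as.integer(sizes), 2L)
  structure(
    list(
      cells = cells, target_power = target_power, alpha = alpha,
      null_value = null_value, overhead = overhead,
      ratios = r, w2 = w2, n_normal = n_z, df_stage = df_stage, n_t = n_t,
      sizes = sizes,
      power = ws_power(cells, sizes, null_value, alpha)$power,
      cost = overhead + sum(cells$unit_cost * sizes),
      total_n = sum(sizes)
    ),
    class = "ws_luh_guo"
  )
}

#' @export
print.ws_luh_guo <- function(x, ...) {
  cat("Two-step normal/t allocation (Luh-Guo)\n")
  cat(sprintf("  ratios      {%s}\n", paste(signif(x$ratios, 5), collapse = ", ")))
  cat(sprintf("  stage sizes {%s} (normal), df %.2f, {%s} (t)\n",
              paste(round(x$n_normal, 2), collapse = ", "), x$df_stage,
              paste(round(x$n_t, 2), collapse = ", ")))
  cat(sprintf("  final sizes {%s}  total n %d\n",
              paste(x$sizes, collapse = ", "), x$total_n))
  cat(sprintf("  total cost %.2f, approximate power %.4f (target %.2f)\n",
              x$cost, x$power, x$target_power))
  invisible(x)
}

#' Tidiers for the two-step comparator
#'
#' @param x A `ws_luh_guo` object.
#' @param ... Ignored.
#' @return `tidy()` returns one row per cell with the ratio, both fractional
#'   stage sizes and the final integer size; `glance()` returns a one-row
#'   design summary.
#' @export
tidy.ws_luh_guo <- function(x, ...) {
  tibble(
    factor_a = x$cells$factor_a, factor_b = x$cells$factor_b,
    ratio = x$ratios, n_normal = x$n_normal, n_t = x$n_t, n = x$sizes,
    unit_cost = x$cells$unit_cost
  )
}

#' @rdname tidy.ws_luh_guo
#' @export
glance.ws_luh_guo <- function(x, ...) {
  tibble(
    n11 = x$sizes[1], n12 = x$sizes[2], n21 = x$sizes[3], n22 = x$sizes[4],
    total_cost = x$cost, total_n = x$total_n, power = x$power,
    df_stage = x$df_stage, w2 = x$w2,
    target_power = x$target_power, alpha = x$alpha
  )
}
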
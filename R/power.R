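#' Effect size of the planned contrast
#'
#' Returns \eqn{\psi = \sum_{ij} L_{ij}\mu_{ij}}, the linear combination of
#' the four cell means defined by the contrast coefficients in `cells`.
#'
#' @param cells A cell table from [factorial_cells()].
#' @return A single number on the response scale.
#' @examples
#' factorial_cells(c(1.23, 0.42, 0.13, 0.38),
#'                 variances = c(0.6889, 0.5184, 0.1156, 0.5929)) |>
#'   contrast_effect()
#' @export
contrast_effect <- function(cells) {
  cells <- check_cells(cells)
  sum(cells$coef * cells$mean)
}

#' Variance of the contrast estimator
#'
#' Returns \eqn{\omega^2 = \mathrm{Var}(\hat\psi) =
#' \sum_{ij} L_{ij}^2 \sigma_{ij}^2 / N_{ij}} for a given allocation.
#' Fractional sizes are allowed; the optimizer evaluates this on continuous
#' allocations.
#'
#' @inheritParams contrast_effect
#' @param n Four per-cell sample sizes in cell order, each at least 2
#'   (fractional values allowed). May instead be an `n` column of `cells`.
#' @return A single positive number (squared response units).
#' @export
estimator_variance <- function(cells, n = NULL) {
  cells <- check_cells(cells)
  n <- resolve_n(cells, n)
  sum(cells$coef^2 * cells$variance / n)
}

#' Welch-Satterthwaite degrees of freedom (population variances)
#'
#' The approximate degrees of freedom of the Welch-Satterthwaite statistic
#' for a contrast of four heteroscedastic normal means,
#' \deqn{\nu = \left(\sum L_{ij}^2\sigma_{ij}^2/N_{ij}\right)^2 \Big/
#'       \sum L_{ij}^4\sigma_{ij}^4 / \left[N_{ij}^2(N_{ij}-1)\right],}
#' evaluated at the planning (population) variances. With equal variances and
#' a balanced allocation of n per cell under unit coefficients this reduces
#' to \eqn{4(n-1)}. In general \eqn{\nu} lies between
#' \eqn{\min_{ij}(N_{ij}-1)} and \eqn{\sum_{ij}(N_{ij}-1)}.
#'
#' @inheritParams estimator_variance
#' @return A single positive number (may be fractional).
#' @export
satterthwaite_df <- function(cells, n = NULL) {
  cells <- check_cells(cells)
  n <- resolve_n(cells, n)
  ws_df(n, cells$coef^2 * cells$variance, cells$coef^4 * cells$variance^2)
}

#' Approximate power of the Welch-Satterthwaite test
#'
#' Computes the noncentral-t approximation to the power of the two-sided
#' level-\eqn{\alpha} Welch-Satterthwaite test of \eqn{H_0: \psi = \psi_0}
#' for a given allocation. The statistic is treated as
#' \eqn{t(\nu, \delta)} with \eqn{\delta = (\psi - \psi_0)/\omega} and
#' population-variance degrees of freedom \eqn{\nu}, giving
#' \deqn{\pi(\delta) = P\{|t(\nu,\delta)| > t_{\nu,\alpha/2}\}.}
#' When \eqn{\delta = 0} the power equals \eqn{\alpha} exactly (the size of
#' the test). Fractional sizes are allowed.
#'
#' @inheritParams estimator_variance
#' @param null_value The null value \eqn{\psi_0} (response-scale units).
#' @param alpha Two-sided significance level in (0, 1).
#' @return A one-row tibble with columns `effect` (\eqn{\psi}), `omega_sq`
#'   (\eqn{\omega^2}), `df` (\eqn{\nu}), `ncp` (\eqn{\delta}) and `power`.
#' @examples
#' cells <- factorial_cells(c(1.23, 0.42, 0.13, 0.38),
#'                          variances = c(0.6889, 0.5184, 0.1156, 0.5929))
#' ws_power(cells, n = c(11, 16, 13, 19))
#' @export
ws_power <- function(cells, n = NULL, null_value = 0, alpha = 0.05) {
  cells <- check_cells(cells)
  n <- resolve_n(cells, n)
  check_alpha(alpha)
  psi <- sum(cells$coef * cells$mean)
  l2v <- cells$coef^2 * cells$variance
  l4v2 <- cells$coef^4 * cells$variance^2
  omega_sq <- sum(l2v / n)
  df <- ws_df(n, l2v, l4v2)
  ncp <- (psi - null_value) / sqrt(omega_sq)
  tibble(
    effect = psi, omega_sq = omega_sq, df = df, ncp = ncp,
    power = power_t(df, ncp, alpha)
  )
}

#' Total cost of an allocation
#'
#' Linear study cost \eqn{C_T = C_O + \sum_{ij} C_{ij} N_{ij}}: fixed
#' overhead plus per-cell unit cost times cell size. With zero overhead and
#' unit costs all 1 this is the total number of subjects.
#'
#' @inheritParams estimator_variance
#' @param overhead Fixed overhead cost \eqn{C_O \ge 0}.
#' @return A single number in the currency units of `unit_cost`.
#' @export
allocation_cost <- function(cells, n = NULL, overhead = 0) {
  cells <- check_cells(cells)
  n <- resolve_n(cells, n)
  if (overhead < 0) abort("`overhead` must be nonnegative.")
  overhead + sum(cells$unit_cost * n)
}

#' Power along a scaled allocation
#'
#' Evaluates the approximate power as every cell of a base allocation is
#' multiplied by a common factor, holding the allocation ratios fixed. Useful
#' for seeing how fast power accrues with overall study size.
#'
#' @inheritParams ws_power
#' @param scale Numeric vector of multipliers applied to `n` (sizes are kept
#'   at or above 2).
#' @return A tibble of class `ws_power_curve` with columns `scale`,
#'   `total_n`, `total_cost` and `power`.
#' @export
power_curve <- function(cells, n = NULL, null_value = 0, alpha = 0.05,
                        overhead = 0, scale = seq(0.4, 2, by = 0.05)) {
  cells <- check_cells(cells)
  n <- resolve_n(cells, n)
  check_alpha(alpha)
  rows <- purrr::map(scale, function(s) {
    ns <- pmax(n * s, 2)
    pw <- ws_power(cells, ns, null_value = null_value, alpha = alpha)
    tibble(scale = s, total_n = sum(ns),
           total_cost = overhead + sum(cells$unit_cost * ns),
           power = pw$power)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ws_power_curve", class(out))
  out
}

#' @rdname power_curve
#' @param object A `ws_power_curve` tibble.
#' @param ... Ignored.
#' @export
autoplot.ws_power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total_n, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Total sample size", y = "Approximate power") +
    ggplot2::theme_minimal()
}

# ---- internal kernels -------------------------------------------------------
# These operate on bare numeric vectors/matrices; `nmat` rows are allocations.
# l2v = L^2 sigma^2, l4v2 = L^4 sigma^4 (both length 4).

ws_df <- function(n, l2v, l4v2) {
  if (any(n <= 1)) abort("Degrees of freedom need every cell size > 1.")
  sum(l2v / n)^2 / sum(l4v2 / (n^2 * (n - 1)))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1.")
  }
}

# Two-sided noncentral-t power; exact alpha when the noncentrality is zero.
power_t <- function(df, ncp, alpha) {
  q <- qt(1 - alpha / 2, df)
  out <- pt(q, df, ncp = ncp, lower.tail = FALSE) + pt(-q, df, ncp = ncp)
  out[ncp == 0] <- alpha
  out
}

# Vectorized power over a matrix of allocations (rows), used by the integer
# screen and the box refinement.
power_matrix <- function(nmat, l2v, l4v2, effect_shift, alpha) {
  omega_sq <- as.vector((1 / nmat) %*% l2v)
  den <- as.vector((1 / (nmat^2 * (nmat - 1))) %*% l4v2)
  df <- omega_sq^2 / den
  ncp <- effect_shift / sqrt(omega_sq)
  power_t(df, ncp, alpha)
}
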
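#' Estimate a contrast of cell means from raw data
#'
#' The unbiased plug-in estimate \eqn{\hat\psi = \sum L_{ij}\bar X_{ij}} of
#' the linear combination of cell means, computed from long-format
#' observations. Unlike [welch_contrast_test()] this needs no variability in
#' the cells, only at least two observations in each.
#'
#' @inheritParams welch_contrast_test
#' @return A single number on the response scale.
#' @export
contrast_estimate <- function(data, contrast = "interaction") {
  coef <- contrast_coefficients(contrast)
  cells <- summarize_cells(data)
  sum(coef * cells$mean)
}

#' Welch-Satterthwaite test for a contrast of four cell means
#'
#' Runs the data-level Welch-Satterthwaite test of
#' \eqn{H_0: \psi = \psi_0} against \eqn{H_1: \psi \ne \psi_0} on raw
#' observations from a 2x2 factorial layout with possibly unequal cell
#' variances. The estimate is \eqn{\hat\psi = \sum L_{ij}\bar X_{ij}}, the
#' statistic \eqn{T^* = (\hat\psi - \psi_0)/\hat\omega} with
#' \eqn{\hat\omega^2 = \sum L_{ij}^2 S_{ij}^2/N_{ij}}, and the degrees of
#' freedom \eqn{\hat\nu} are the Welch-Satterthwaite formula with the sample
#' variances substituted for the population ones. The null hypothesis is
#' rejected at level \eqn{\alpha} when \eqn{|T^*| > t_{\hat\nu,\alpha/2}};
#' the two-sided p-value \eqn{2 P\{t(\hat\nu) > |T^*|\}} is reported as a
#' consistent convenience.
#'
#' With coefficients active in only two cells the procedure reduces to the
#' classical two-sample Welch t test on those cells.
#'
#' @param data A long-format data frame with columns `factor_a`, `factor_b`
#'   (levels 1 and 2) and a numeric `response`; every cell needs at least two
#'   observations. [read_factorial_csv()] produces this layout.
#' @param contrast Preset name or four coefficients, as in
#'   [factorial_cells()].
#' @param null_value The null value \eqn{\psi_0}.
#' @param alpha Two-sided significance level in (0, 1).
#' @return An object of class `welch_contrast_test`: a list with the
#'   estimate, standard error, statistic, estimated df, critical value,
#'   p-value, rejection flag and a per-cell summary tibble. Use [tidy()] or
#'   [glance()] for a tabular view.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   factor_a = rep(c(1, 1, 2, 2), each = 8),
#'   factor_b = rep(c(1, 2, 1, 2), each = 8),
#'   response = rnorm(32, mean = rep(c(1.2, 0.4, 0.1, 0.4), each = 8))
#' )
#' welch_contrast_test(d, contrast = "interaction")
#' @export
welch_contrast_test <- function(data, contrast = "interaction",
                                null_value = 0, alpha = 0.05) {
  check_alpha(alpha)
  coef <- contrast_coefficients(contrast)
  cells <- summarize_cells(data)
  est <- sum(coef * cells$mean)
  omega_sq_hat <- sum(coef^2 * cells$s2 / cells$n)
  if (omega_sq_hat == 0) {
    abort(paste(
      "Degenerate sample: every cell with a nonzero coefficient is constant,",
      "so the estimated standard error is zero."
    ))
  }
  df_hat <- sum(coef^2 * cells$s2 / cells$n)^2 /
    sum(coef^4 * cells$s2^2 / (cells$n^2 * (cells$n - 1)))
  stat <- (est - null_value) / sqrt(omega_sq_hat)
  crit <- qt(1 - alpha / 2, df_hat)
  p <- 2 * pt(abs(stat), df_hat, lower.tail = FALSE)
  structure(
    list(
      estimate = est,
      std_error = sqrt(omega_sq_hat),
      statistic = stat,
      df = df_hat,
      critical_value = crit,
      p.value = p,
      reject = abs(stat) > crit,
      alpha = alpha,
      null_value = null_value,
      coef = coef,
      cells = dplyr::mutate(cells, coef = coef)
    ),
    class = "welch_contrast_test"
  )
}

# Per-cell n, mean, sample variance from long-format data; errors name the
# offending cell.
summarize_cells <- function(data) {
  needed <- c("factor_a", "factor_b", "response")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (!is.numeric(data$response)) abort("`response` must be numeric.")
  bad <- !data$factor_a %in% c(1, 2) | !data$factor_b %in% c(1, 2)
  if (any(bad)) {
    abort(paste0("Factor levels must be 1 or 2; offending row(s): ",
                 paste(utils::head(which(bad), 5), collapse = ", "), "."))
  }
  cells <- data |>
    dplyr::group_by(factor_a = as.integer(.data$factor_a),
                    factor_b = as.integer(.data$factor_b)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$response),
      s2 = stats::var(.data$response),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$factor_a, .data$factor_b)
  full <- tibble(factor_a = c(1L, 1L, 2L, 2L), factor_b = c(1L, 2L, 1L, 2L))
  cells <- dplyr::left_join(full, cells, by = c("factor_a", "factor_b"))
  empty <- is.na(cells$n) | cells$n < 2
  if (any(empty)) {
    lab <- paste0("(", cells$factor_a[empty], ",", cells$factor_b[empty], ")",
                  collapse = ", ")
    abort(paste0("Cell(s) ", lab, " have fewer than 2 observations."))
  }
  cells
}

#' @export
print.welch_contrast_test <- function(x, ...) {
  cat("Welch-Satterthwaite contrast test (2x2 factorial)\n")
  cat(sprintf("  estimate = %.6g  (null value %.6g)\n", x$estimate, x$null_value))
  cat(sprintf("  T* = %.4f on %.2f estimated df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat(sprintf("  H0 %s at alpha = %s (|T*| %s t = %.4f)\n",
              if (x$reject) "rejected" else "not rejected", format(x$alpha),
              if (x$reject) ">" else "<=", x$critical_value))
  invisible(x)
}

#' Tidiers for Welch-Satterthwaite contrast tests
#'
#' @param x A `welch_contrast_test` object.
#' @param ... Ignored.
#' @return `tidy()` returns a one-row tibble with the estimate, standard
#'   error, statistic, estimated df, p-value and rejection flag; `glance()`
#'   adds the significance level and critical value.
#' @export
tidy.welch_contrast_test <- function(x, ...) {
  tibble(
    estimate = x$estimate, std.error = x$std_error,
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    reject = x$reject
  )
}

#' @rdname tidy.welch_contrast_test
#' @export
glance.welch_contrast_test <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p.value, alpha = x$alpha,
    critical.value = x$critical_value, reject = x$reject,
    null.value = x$null_value
  )
}
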
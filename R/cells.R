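#' Specify the four cells of a 2x2 factorial design
#'
#' Builds the tidy cell table that every other function in welch22 consumes.
#' Each row is one treatment cell of a two-factor design with two levels per
#' factor, in the fixed row-major order (1,1), (1,2), (2,1), (2,2): factor A
#' level first, factor B level second. The table carries the planning values
#' of the cell means and variances, the contrast coefficients defining the
#' effect of interest, and the per-subject sampling cost of each cell.
#'
#' The model is \eqn{X_{ijk} \sim N(\mu_{ij}, \sigma_{ij}^2)} with independent
#' observations and no homogeneity assumption: each cell has its own variance.
#' The effect of interest is the linear combination
#' \eqn{\psi = \sum_{ij} L_{ij}\mu_{ij}}. The named presets expand to the
#' classical unit-coefficient contrasts: `"interaction"` is
#' \eqn{\mu_{11}-\mu_{12}-\mu_{21}+\mu_{22}}, `"mainA"` is
#' \eqn{\mu_{11}+\mu_{12}-\mu_{21}-\mu_{22}}, and `"mainB"` is
#' \eqn{\mu_{11}-\mu_{12}+\mu_{21}-\mu_{22}}.
#'
#' Power is not invariant to rescaling the coefficients alone: halving all
#' `L_ij` halves \eqn{\psi}, and the null value must be rescaled with it.
#' welch22 never normalizes coefficients; they are used exactly as given.
#'
#' @param means Numeric vector of four cell means, in cell order
#'   (1,1), (1,2), (2,1), (2,2). Response-scale units.
#' @param sds Numeric vector of four cell standard deviations. Give exactly
#'   one of `sds` or `variances`.
#' @param variances Numeric vector of four cell variances (all strictly
#'   positive).
#' @param contrast Either a preset name (`"interaction"`, `"mainA"`,
#'   `"mainB"`) or a numeric vector of four coefficients, not all zero.
#' @param unit_costs Per-subject sampling cost of each cell, a positive
#'   numeric vector of length four (or one value recycled). Defaults to 1,
#'   under which total cost equals total sample size.
#'
#' @return A tibble with four rows and columns `factor_a`, `factor_b`,
#'   `mean`, `variance`, `coef`, `unit_cost`.
#'
#' @examples
#' # Planning values from an emergency-care asthma study: factor A is attack
#' # recency, factor B is panic-fear level, response is log service cost.
#' cells <- factorial_cells(
#'   means     = c(1.23, 0.42, 0.13, 0.38),
#'   variances = c(0.6889, 0.5184, 0.1156, 0.5929),
#'   contrast  = "interaction",
#'   unit_costs = c(784.74, 267.96, 82.94, 242.44)
#' )
#' contrast_effect(cells)
#' @export
factorial_cells <- function(means, sds = NULL, variances = NULL,
                            contrast = "interaction", unit_costs = 1) {
  if (is.null(variances) == is.null(sds)) {
    abort("Supply exactly one of `sds` or `variances`.")
  }
  if (is.null(variances)) {
    if (length(sds) != 4L || !is.numeric(sds)) {
      abort("`sds` must be a numeric vector of length 4.")
    }
    variances <- sds^2
  }
  coef <- contrast_coefficients(contrast)
  if (length(unit_costs) == 1L) unit_costs <- rep(unit_costs, 4L)
  cells <- tibble(
    factor_a  = c(1L, 1L, 2L, 2L),
    factor_b  = c(1L, 2L, 1L, 2L),
    mean      = as.numeric(means),
    variance  = as.numeric(variances),
    coef      = coef,
    unit_cost = as.numeric(unit_costs)
  )
  check_cells(cells)
}

#' Expand a contrast specification to four coefficients
#'
#' @param contrast A preset name (`"interaction"`, `"mainA"`, `"mainB"`) or a
#'   numeric vector of four coefficients.
#' @return A numeric vector of four coefficients in cell order
#'   (1,1), (1,2), (2,1), (2,2).
#' @examples
#' contrast_coefficients("interaction")
#' @export
contrast_coefficients <- function(contrast) {
  if (is.character(contrast)) {
    if (length(contrast) != 1L) abort("Give a single contrast name.")
    presets <- list(
      interaction = c(1, -1, -1, 1),
      mainA       = c(1, 1, -1, -1),
      mainB       = c(1, -1, 1, -1)
    )
    if (!contrast %in% names(presets)) {
      abort(paste0(
        "Unknown contrast preset '", contrast,
        "'; use \"interaction\", \"mainA\", \"mainB\" or four coefficients."
      ))
    }
    return(presets[[contrast]])
  }
  if (!is.numeric(contrast) || length(contrast) != 4L) {
    abort("`contrast` must be a preset name or a numeric vector of length 4.")
  }
  as.numeric(contrast)
}

# Validate and canonicalize a cells table: required columns, one row per
# cell in row-major order, positive variances and costs, nonzero contrast.
check_cells <- function(cells) {
  needed <- c("factor_a", "factor_b", "mean", "variance", "coef")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    abort(paste0("`cells` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (!"unit_cost" %in% names(cells)) cells$unit_cost <- 1
  if (nrow(cells) != 4L) abort("`cells` must have exactly 4 rows.")
  cells <- dplyr::arrange(as_tibble(cells), .data$factor_a, .data$factor_b)
  key <- paste(cells$factor_a, cells$factor_b)
  if (!identical(key, c("1 1", "1 2", "2 1", "2 2"))) {
    abort("`cells` must contain each of the cells (1,1), (1,2), (2,1), (2,2) once.")
  }
  if (anyNA(cells$mean) || anyNA(cells$variance) || anyNA(cells$coef)) {
    abort("`cells` must not contain missing values.")
  }
  if (any(cells$variance <= 0)) abort("All cell variances must be > 0.")
  if (all(cells$coef == 0)) abort("At least one contrast coefficient must be nonzero.")
  if (any(cells$unit_cost <= 0)) abort("All unit costs must be > 0.")
  cells
}

# Resolve per-cell sample sizes: either an explicit length-4 vector (a single
# value is recycled) or an `n` column already present in `cells`.
resolve_n <- function(cells, n, floor = 2, integer_only = FALSE) {
  if (is.null(n)) {
    if (!"n" %in% names(cells)) {
      abort("Supply `n` (four cell sizes) or include an `n` column in `cells`.")
    }
    n <- cells$n
  }
  if (length(n) == 1L) n <- rep(n, 4L)
  if (length(n) != 4L || !is.numeric(n) || anyNA(n)) {
    abort("`n` must be a numeric vector of length 4 without missing values.")
  }
  n <- as.numeric(n)
  if (any(n < floor)) {
    abort(paste0("Every cell size must be at least ", floor,
                 " (the cell sample variance needs n - 1 >= 1)."))
  }
  if (integer_only && any(n != floor(n))) {
    abort("Cell sizes must be whole numbers here.")
  }
  n
}
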
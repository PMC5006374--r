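#' Read long-format factorial data from CSV
#'
#' Reads a comma-separated file with columns `factor_a`, `factor_b` (levels
#' 1 and 2) and numeric `response`, one row per observation, and returns a
#' tibble suitable for [welch_contrast_test()]. Errors name missing columns,
#' rows with unknown factor levels, non-numeric responses (by row number),
#' and cells with fewer than two observations.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `factor_a`, `factor_b` (integer) and
#'   `response` (double).
#' @export
read_factorial_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("factor_a", "factor_b", "response")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(paste0("File is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  resp <- suppressWarnings(as.numeric(raw$response))
  bad <- which(is.na(resp) & !is.na(raw$response))
  if (length(bad)) {
    abort(paste0("Non-numeric response value in data row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  data <- tibble(
    factor_a = suppressWarnings(as.integer(raw$factor_a)),
    factor_b = suppressWarnings(as.integer(raw$factor_b)),
    response = resp
  )
  summarize_cells(data)  # validates levels and per-cell counts
  data
}

#' Read and validate a design configuration file
#'
#' Reads a YAML run configuration describing a 2x2 design, its cost model
#' and which methods to run, for use with [run_design()]. The layout is:
#'
#' ```yaml
#' design:
#'   means: [1.23, 0.42, 0.13, 0.38]
#'   variances: [0.6889, 0.5184, 0.1156, 0.5929]   # or sds:
#'   contrasts: [interaction, mainA, mainB]         # names or 4 coefficients
#'   null_value: 0
#'   alpha: 0.05
#'   target_power: 0.8
#'   allocation: [11, 16, 13, 19]    # only for the "power" method
#' cost:
#'   overhead: 0
#'   unit_costs:
#'     varied: [784.74, 267.96, 82.94, 242.44]
#'     equal: [1, 1, 1, 1]
#' methods: [proposed, luh_guo]
#' simulation:                        # optional
#'   replications: 10000
#'   seed: 1
#' ```
#'
#' All four-cell vectors are in cell order (1,1), (1,2), (2,1), (2,2).
#' `unit_costs` may be a single vector or a named list of vectors (each name
#' becomes a `cost_set` in the report); omitted costs default to overhead 0
#' and unit costs 1, under which cost equals total sample size.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list, class `ws_config`.
#' @export
read_design_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_design_config
#' @param config A configuration list.
#' @export
write_design_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Collect every problem before failing, so a bad config reports all
# offending fields at once.
validate_config <- function(config) {
  issues <- character()
  need <- function(ok, msg) if (!ok) issues <<- c(issues, msg)

  d <- config$design
  need(!is.null(d), "design: section is required")
  if (!is.null(d)) {
    need(is.numeric(d$means) && length(d$means) == 4,
         "design$means: four numbers required")
    has_var <- !is.null(d$variances)
    has_sd <- !is.null(d$sds)
    need(xor(has_var, has_sd), "design: give exactly one of variances or sds")
    if (has_var) need(is.numeric(d$variances) && length(d$variances) == 4 &&
                        all(d$variances > 0),
                      "design$variances: four positive numbers required")
    if (has_sd) need(is.numeric(d$sds) && length(d$sds) == 4 && all(d$sds > 0),
                     "design$sds: four positive numbers required")
    if (is.null(d$contrasts)) config$design$contrasts <- d$contrasts <- "interaction"
    if (is.null(d$null_value)) config$design$null_value <- 0
    if (is.null(d$alpha)) config$design$alpha <- 0.05
    if (is.null(d$target_power)) config$design$target_power <- 0.8
    a <- config$design$alpha
    need(is.numeric(a) && a > 0 && a < 1, "design$alpha: must be in (0, 1)")
    tp <- config$design$target_power
    need(is.numeric(tp) && tp > 0 && tp < 1,
         "design$target_power: must be in (0, 1)")
  }
  if (is.null(config$cost)) config$cost <- list()
  if (is.null(config$cost$overhead)) config$cost$overhead <- 0
  need(is.numeric(config$cost$overhead) && config$cost$overhead >= 0,
       "cost$overhead: must be a nonnegative number")
  if (is.null(config$cost$unit_costs)) config$cost$unit_costs <- rep(1, 4)
  uc <- config$cost$unit_costs
  if (!is.list(uc)) uc <- list(default = uc)
  for (nm in names(uc)) {
    need(is.numeric(uc[[nm]]) && length(uc[[nm]]) == 4 && all(uc[[nm]] > 0),
         paste0("cost$unit_costs$", nm, ": four positive numbers required"))
  }
  config$cost$unit_costs <- uc
  if (is.null(config$methods)) config$methods <- c("proposed", "luh_guo")
  need(all(config$methods %in% c("proposed", "luh_guo", "power")),
       "methods: must be a subset of {proposed, luh_guo, power}")
  if ("power" %in% config$methods) {
    need(is.numeric(config$design$allocation) &&
           length(config$design$allocation) == 4,
         "design$allocation: four cell sizes required for the power method")
  }
  if (!is.null(config$simulation)) {
    if (is.null(config$simulation$replications)) {
      config$simulation$replications <- 10000
    }
    need(config$simulation$replications >= 1,
         "simulation$replications: must be at least 1")
  }
  if (length(issues)) {
    abort(paste0("Invalid configuration:\n",
                 paste0("  - ", issues, collapse = "\n")))
  }
  structure(config, class = "ws_config")
}

#' Run a configured design analysis
#'
#' Executes every requested method for every contrast and unit-cost set in a
#' configuration (see [read_design_config()]) and returns one report row per
#' combination: the allocation, its total cost and size, the approximate
#' power, and — when a `simulation` section is present — the Monte Carlo
#' power and its difference from the approximation. The `power` method skips
#' optimization and evaluates the supplied allocation as is.
#'
#' @param config A `ws_config` list (or any list with the same layout, which
#'   is validated first).
#' @param verbose Print each row's optimizer audit summary as it completes.
#' @return A tibble with columns `contrast`, `cost_set`, `method`,
#'   `n11`...`n22`, `total_cost`, `total_n`, `power`, and when simulating,
#'   `simulated_power` and `error`.
#' @export
run_design <- function(config, verbose = FALSE) {
  config <- validate_config(config)
  d <- config$design
  contrasts <- d$contrasts
  if (!is.list(contrasts)) {
    contrasts <- if (is.character(contrasts)) as.list(contrasts) else list(contrasts)
  }
  labels <- purrr::map_chr(contrasts, function(ct) {
    if (is.character(ct)) ct else paste(ct, collapse = ",")
  })

  rows <- list()
  for (ci in seq_along(contrasts)) {
    for (cost_set in names(config$cost$unit_costs)) {
      cells <- factorial_cells(
        means = d$means, sds = d$sds, variances = d$variances,
        contrast = if (is.character(contrasts[[ci]])) contrasts[[ci]]
                   else as.numeric(contrasts[[ci]]),
        unit_costs = config$cost$unit_costs[[cost_set]]
      )
      for (method in config$methods) {
        row <- switch(
          method,
          proposed = {
            fit <- optimize_allocation(cells, d$target_power, d$null_value,
                                       d$alpha, config$cost$overhead)
            if (verbose) print(fit)
            n <- fit$sizes
            tibble(n11 = n[1], n12 = n[2], n21 = n[3], n22 = n[4],
                   total_cost = fit$cost, total_n = fit$total_n,
                   power = fit$power)
          },
          luh_guo = {
            fit <- luh_guo_allocation(cells, d$target_power, d$null_value,
                                      d$alpha, config$cost$overhead)
            n <- fit$sizes
            tibble(n11 = n[1], n12 = n[2], n21 = n[3], n22 = n[4],
                   total_cost = fit$cost, total_n = fit$total_n,
                   power = fit$power)
          },
          power = {
            n <- d$allocation
            pw <- ws_power(cells, n, d$null_value, d$alpha)
            tibble(n11 = n[1], n12 = n[2], n21 = n[3], n22 = n[4],
                   total_cost = allocation_cost(cells, n, config$cost$overhead),
                   total_n = sum(n), power = pw$power)
          }
        )
        if (!is.null(config$simulation)) {
          sim <- simulate_power(
            cells, c(row$n11, row$n12, row$n21, row$n22),
            reps = config$simulation$replications,
            null_value = d$null_value, alpha = d$alpha,
            seed = config$simulation$seed
          )
          row$simulated_power <- sim$simulated_power
          row$error <- sim$error
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(contrast = labels[ci], cost_set = cost_set, method = method),
          row
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a design report to CSV or JSON
#'
#' @param report A report tibble from [run_design()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (defaults to the file extension).
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path,
                                format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(report, path)
  } else {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Format a design report the way planning tables are printed
#'
#' Monetary columns are shown with two decimals and powers with four.
#'
#' @param report A report tibble from [run_design()].
#' @return A character vector, one element per line.
#' @export
format_design_report <- function(report) {
  fmt_row <- function(r) {
    out <- sprintf("%-14s %-8s %-10s {%d, %d, %d, %d}  cost %.2f  n %d  power %.4f",
                   r$contrast, r$cost_set, r$method,
                   r$n11, r$n12, r$n21, r$n22, r$total_cost, r$total_n, r$power)
    if ("simulated_power" %in% names(r) && !is.na(r$simulated_power)) {
      out <- sprintf("%s  simulated %.4f  error %+.4f",
                     out, r$simulated_power, r$error)
    }
    out
  }
  purrr::map_chr(seq_len(nrow(report)), function(i) fmt_row(report[i, ]))
}
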
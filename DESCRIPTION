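Package: welch22
Title: Power and Cost-Optimal Sample Size Allocation for Heteroscedastic
    2x2 Factorial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for two-by-two factorial studies with unequal
    cell variances. Computes the approximate power of the
    Welch-Satterthwaite test for any linear combination of the four cell
    means via the noncentral t distribution, runs the data-level test on
    raw samples, and finds the integer sample-size allocation that
    minimizes a linear cost function (overhead plus per-cell unit costs)
    subject to a power constraint, using continuous constrained
    optimization followed by exhaustive screening of the sixteen
    floor/ceiling integer combinations and a local integer refinement.
    Also provides the normal-approximation two-step allocation of Luh and
    Guo for comparison, and a Monte Carlo engine that validates the
    approximate power function by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
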
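# Fixtures, file input/output, analysis driver, and the seeded generator of
# random trial pairs.

#' Published trial summary fixtures
#'
#' Summary statistics of the RESPIRE (ciprofloxacin for non-cystic-fibrosis
#' bronchiectasis; 14-day and 28-day on/off regimens, and the four-estimate
#' set pooling both regimens) and ORBIT (inhaled liposomal ciprofloxacin;
#' time-to-exacerbation primary and exacerbation-frequency secondary
#' endpoints) trial pairs, as published: effect estimate on the log
#' rate-ratio / log hazard-ratio scale, 95% CI, and one-sided p-value
#' (alternative `"less"`, benefit = negative effect). The per-trial standard
#' error `se` is reconstructed from the published 95% CI via [se_from_ci()];
#' the published one-sided p-values are retained in `p_onesided` so combined
#' p-values can be recomputed from them directly with [combine_p()]. The
#' `source` column records which published table cell each row came from.
#'
#' @param name One of `"respire_14d"`, `"respire_28d"`, `"respire_all4"`,
#'   `"orbit_primary"`, `"orbit_secondary"`.
#' @return Tibble with columns `id`, `estimate`, `ci_lower`, `ci_upper`,
#'   `ci_level`, `p_onesided`, `se`, `source`.
#' @export
#' @examples
#' pf_fixture("respire_14d")
pf_fixture <- function(name = c("respire_14d", "respire_28d", "respire_all4",
                                "orbit_primary", "orbit_secondary")) {
  name <- match.arg(name)
  path <- system.file("extdata", "trial_fixtures.csv", package = "pfcomb",
                      mustWork = TRUE)
  all <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  fx <- filter(all, .data$fixture == name)
  fx <- mutate(fx, se = se_from_ci(.data$ci_lower, .data$ci_upper,
                                   level = unique(.data$ci_level)))
  select(fx, "id", "estimate", "ci_lower", "ci_upper", "ci_level",
         "p_onesided", "se", "source")
}

#' Read per-trial summary data from CSV or JSON
#'
#' Expects columns/keys `id`, `estimate`, and any of `se`,
#' (`ci_lower`, `ci_upper`, optional `ci_level`), or `p_onesided`; see
#' [as_trials()] for the reconstruction precedence.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return Tibble of per-trial summaries (not yet standardised).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Run a complete combined-inference analysis
#'
#' End-to-end driver: loads trials from a file or named fixture, runs
#' [pf_inference()] for the requested methods, and optionally writes the
#' results table (CSV/JSON/plain text, full precision) and the p-value
#' function curves ([pf_curve()], CSV). Returns the full-precision results
#' tibble invisibly.
#'
#' @param input Path to a CSV/JSON file of per-trial summaries (see
#'   [read_trials()]), or a data frame. Exactly one of `input`/`fixture`.
#' @param fixture Name of a built-in fixture (see [pf_fixture()]).
#' @param methods Combination methods to run (default all six).
#' @param alternative `"greater"` or `"less"`.
#' @param levels Confidence levels (default 0.95 and 0.99875).
#' @param null_value Null value for the combined p-values (default 0).
#' @param output Optional path for the results table; format from `format`.
#' @param format `"csv"`, `"json"`, or `"text"`.
#' @param curves Optional path: writes the [pf_curve()] grid as CSV.
#' @param wilkinson_r Rank for `method = "wilkinson"`.
#' @return (Invisibly) the tidy results tibble.
#' @export
#' @examples
#' run_analysis(fixture = "respire_14d", alternative = "less")
run_analysis <- function(input = NULL, fixture = NULL,
                         methods = pf_methods(),
                         alternative = c("greater", "less"),
                         levels = c(0.95, 0.99875), null_value = 0,
                         output = NULL, format = c("text", "csv", "json"),
                         curves = NULL, wilkinson_r = NULL) {
  alternative <- match.arg(alternative)
  format <- match.arg(format)
  if (length(methods) < 1L) abort("at least one method is required.")
  if (is.null(input) == is.null(fixture)) {
    abort("supply exactly one of `input` or `fixture`.")
  }
  trials <- if (!is.null(fixture)) {
    pf_fixture(fixture)
  } else if (is.data.frame(input)) {
    input
  } else {
    read_trials(input)
  }
  fit <- pf_inference(trials, methods = methods, alternative = alternative,
                      levels = levels, null_value = null_value,
                      wilkinson_r = wilkinson_r)
  tb <- tidy(fit)
  if (!is.null(output)) {
    switch(format,
      csv = readr::write_csv(tb, output),
      json = jsonlite::write_json(tb, output, digits = NA, pretty = TRUE),
      text = {
        con <- file(output, open = "wt")
        on.exit(close(con))
        sink(con)
        print(fit)
        sink()
      }
    )
  } else if (format == "text" && interactive()) {
    print(fit)
  }
  if (!is.null(curves)) {
    crv <- pf_curve(trials, methods = methods, alternative = alternative,
                    wilkinson_r = wilkinson_r)
    readr::write_csv(as_tibble(crv), curves)
  }
  invisible(tb)
}

#' Generate a reproducible random pair of trial results
#'
#' Draws `theta_hat_i ~ N(theta_i, sigma_i^2)` independently for two trials
#' under the normal summary model; the mandatory seed makes the pair
#' reproducible.
#'
#' @param theta1,theta2 True trial effects.
#' @param sigma1,sigma2 True standard errors (positive).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `estimate`, `se`.
#' @export
#' @examples
#' generate_trial_pair(0, 0, 1, 1, seed = 1)
generate_trial_pair <- function(theta1, theta2, sigma1, sigma2, seed) {
  if (any(!is.finite(c(theta1, theta2, sigma1, sigma2))) ||
      sigma1 <= 0 || sigma2 <= 0) {
    abort("true effects must be finite and standard errors strictly positive.")
  }
  if (missing(seed) || !is.numeric(seed)) abort("an integer `seed` is mandatory.")
  est <- withr::with_seed(as.integer(seed), {
    rnorm(2L, mean = c(theta1, theta2), sd = c(sigma1, sigma2))
  })
  tibble(id = c("trial 1", "trial 2"), estimate = est, se = c(sigma1, sigma2))
}
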
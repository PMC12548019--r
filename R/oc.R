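# Operating characteristics of the median estimates: closed-form expectation
# and standard errors where they are available, asymptotic estimands
# (probability limits as the standard errors shrink), and a seeded Monte
# Carlo engine drawing estimate pairs from the normal model
# theta_hat_i ~ N(theta_i, sigma_i^2).

#' Expected two-trials-rule median estimate (equal standard errors)
#'
#' Closed-form expectation of the two-trials-rule median estimate when both
#' trials share the standard error `sigma`:
#' `theta1 * pnorm(d) + theta2 * pnorm(-d) + sigma * (q - sqrt(2) * dnorm(d))`
#' with `d = (theta2 - theta1) / (sqrt(2) * sigma)` and
#' `q = qnorm(sqrt(1/2))`, i.e. the expectation of the minimum of two
#' independent normals shifted by `sigma * q`. Under homogeneity
#' (`theta1 = theta2`) the estimate is mean-biased by
#' `sigma * (qnorm(sqrt(1/2)) - 1/sqrt(pi)) ~ -0.019 * sigma`. For unequal
#' standard errors no closed form exists (the expectation then also depends
#' on the true effects); use [simulate_oc()].
#'
#' @param theta1,theta2 True trial effects.
#' @param sigma Common standard error of both trials (positive).
#' @param alternative `"greater"` (median = min estimate + sigma * q) or
#'   `"less"` (mirrored).
#' @return Expected median estimate.
#' @export
#' @examples
#' expected_median_2tr(0, 0, 1)    # -0.0193: conservative mean bias
expected_median_2tr <- function(theta1, theta2, sigma,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.finite(theta1) || !is.finite(theta2) ||
      !is.finite(sigma) || sigma <= 0) {
    abort("`theta1`, `theta2` must be finite and `sigma` positive.")
  }
  if (alternative == "less") {
    return(-expected_median_2tr(-theta1, -theta2, sigma, "greater"))
  }
  d <- (theta2 - theta1) / (sqrt(2) * sigma)
  q <- qnorm(sqrt(0.5))
  theta1 * pnorm(d) + theta2 * pnorm(-d) + sigma * (q - sqrt(2) * dnorm(d))
}

#' Analytic standard error of a median estimate
#'
#' Closed-form standard errors of the median estimate:
#' \describe{
#'   \item{`two_trials_rule`}{`sigma * sqrt(1 - 1/pi) ~ 0.83 * sigma`, valid
#'     only under equal true effects and equal standard errors (the standard
#'     error otherwise depends on the unknown true effects; use
#'     [simulate_oc()]).}
#'   \item{`meta_analysis`}{`1 / sqrt(1/sigma1^2 + 1/sigma2^2)`, never larger
#'     than either trial's standard error.}
#'   \item{`edgington`}{`sqrt(2) / (1/sigma1 + 1/sigma2)`; at least as large
#'     as the meta-analytic standard error (equal exactly when
#'     `sigma1 = sigma2`), and larger than `min(sigma1, sigma2)` when the
#'     ratio `sigma2/sigma1` leaves `[sqrt(2) - 1, sqrt(2) + 1]`.}
#' }
#'
#' @param method One of `"two_trials_rule"`, `"meta_analysis"`,
#'   `"edgington"`.
#' @param sigma1,sigma2 Trial standard errors (positive); must be equal for
#'   the two-trials rule.
#' @return Positive standard error of the median estimate.
#' @export
#' @examples
#' analytic_se("edgington", 0.5, 2)   # 0.566, larger than sigma1
analytic_se <- function(method, sigma1, sigma2 = sigma1) {
  method <- match.arg(method, c("two_trials_rule", "meta_analysis", "edgington"))
  if (any(!is.finite(c(sigma1, sigma2))) || sigma1 <= 0 || sigma2 <= 0) {
    abort("standard errors must be finite and positive.")
  }
  switch(
    method,
    two_trials_rule = {
      if (sigma1 != sigma2) {
        abort(paste0(
          "the two-trials-rule standard error is only available in closed form ",
          "for equal true effects and equal standard errors; use simulate_oc() ",
          "for the general case."
        ))
      }
      sigma1 * sqrt(1 - 1 / pi)
    },
    meta_analysis = 1 / sqrt(1 / sigma1^2 + 1 / sigma2^2),
    edgington = sqrt(2) / (1 / sigma1 + 1 / sigma2)
  )
}

#' Asymptotic estimand of a combination method
#'
#' Probability limit of the combined estimation function `mu_hat(a)` as both
#' standard errors shrink to zero with fixed variance ratio
#' `c = sigma1^2 / sigma2^2`. The two-trials rule and Pearson's method
#' converge to the less extreme true effect, Tippett's and Fisher's methods
#' to the more extreme one, meta-analysis to the inverse-variance weighted
#' average `theta1 / (1 + c) + theta2 / (1 + 1/c)`, and Edgington's median
#' (`a = 1/2`) to the inverse-SE weighted average (weights from `sqrt(c)`).
#' For Edgington with `a != 1/2` the limit is `min(theta1, theta2)`
#' (`a < 1/2`) or `max(theta1, theta2)` (`a > 1/2`): its CI limits converge
#' to the two true effects, so the interval never collapses under
#' heterogeneity.
#'
#' @param method One of [pf_methods()].
#' @param theta1,theta2 True trial effects.
#' @param c Variance ratio `sigma1^2 / sigma2^2` (default 1).
#' @param alternative Orientation (flips which effect is the "conservative"
#'   one for the order-statistic and product methods).
#' @param a Probability level being inverted (default 1/2, the median).
#' @return The limiting effect value.
#' @export
#' @examples
#' asymptotic_target("meta_analysis", 0, 1, c = 2)   # 2/3
#' asymptotic_target("edgington", 0, 1, a = 0.975)   # 1 (upper CI limit)
asymptotic_target <- function(method, theta1, theta2, c = 1,
                              alternative = c("greater", "less"), a = 0.5) {
  method <- match.arg(method, pf_methods())
  alternative <- match.arg(alternative)
  if (!is.finite(theta1) || !is.finite(theta2) || !is.finite(c) || c <= 0) {
    abort("`theta1`, `theta2` must be finite and `c` positive.")
  }
  lo <- min(theta1, theta2)
  hi <- max(theta1, theta2)
  conservative <- if (alternative == "greater") lo else hi
  anticons <- if (alternative == "greater") hi else lo
  switch(
    method,
    two_trials_rule = conservative,
    pearson = conservative,
    tippett = anticons,
    fisher = anticons,
    meta_analysis = theta1 / (1 + c) + theta2 / (1 + 1 / c),
    edgington = {
      if (a < 0.5) lo
      else if (a > 0.5) hi
      else theta1 / (1 + sqrt(c)) + theta2 / (1 + 1 / sqrt(c))
    }
  )
}

# vectorised engine ------------------------------------------------------

# median estimates for n x k matrices of estimates/standard errors; closed
# forms where available, otherwise row-wise bisection at a = 1/2
.median_rows <- function(est, se, method, alternative, wilkinson_r = NULL) {
  .mu_rows(est, se, 0.5, method, alternative, wilkinson_r)
}

# row-wise mu_hat(a): closed forms for the order-statistic methods and
# meta-analysis, Edgington's two-trial median; bisection otherwise
.mu_rows <- function(est, se, a, method, alternative, wilkinson_r = NULL) {
  k <- ncol(est)
  s <- if (alternative == "greater") 1 else -1
  m <- method
  if (m == "wilkinson") {
    if (wilkinson_r == k) m <- "two_trials_rule"
    else if (wilkinson_r == 1) m <- "tippett"
  }
  if (m == "two_trials_rule") {
    z <- qnorm(a^(1 / k))
    return(if (s > 0) .rowmin(est + se * z) else .rowmax(est - se * z))
  }
  if (m == "tippett") {
    z <- qnorm((1 - a)^(1 / k))
    return(if (s > 0) .rowmax(est - se * z) else .rowmin(est + se * z))
  }
  if (m == "meta_analysis") {
    w <- 1 / se^2
    return(rowSums(est * w) / rowSums(w) + s * qnorm(a) / sqrt(rowSums(w)))
  }
  if (m == "edgington" && k == 2 && a == 0.5) {
    return(rowSums(est / se) / rowSums(1 / se))
  }
  .bisect_rows(est, se, a, method, alternative, wilkinson_r)
}

# vectorised bracketed bisection on the monotone combined p-value function
.bisect_rows <- function(est, se, a, method, alternative, wilkinson_r = NULL,
                         iter = 90L) {
  s <- if (alternative == "greater") 1 else -1
  f <- function(mu) s * (.p_rows(est, se, mu, method, alternative, wilkinson_r) - a)
  lo <- .rowmin(est) - 10 * .rowmax(se)
  hi <- .rowmax(est) + 10 * .rowmax(se)
  flo <- f(lo)
  fhi <- f(hi)
  for (i in 1:60) {
    bad <- flo > 0 | fhi < 0
    if (!any(bad)) break
    h <- hi - lo
    mid <- (lo + hi) / 2
    lo[bad] <- mid[bad] - h[bad]
    hi[bad] <- mid[bad] + h[bad]
    flo <- f(lo)
    fhi <- f(hi)
  }
  if (any(flo > 0 | fhi < 0)) {
    abort("root not bracketed after 60 bracket doublings.")
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    below <- f(mid) < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Monte Carlo operating characteristics of a median estimate
#'
#' Draws `n_sim` independent estimate vectors from the normal model
#' `theta_hat_i ~ N(theta_i, sigma_i^2)`, computes the method's median
#' estimate and confidence intervals for each replicate, and summarises
#' bias, standard error, and coverage. Under homogeneity
#' (`theta1 = theta2`) bias and coverage are assessed against the common
#' true effect; under heterogeneity against the method's own asymptotic
#' estimand ([asymptotic_target()]), since that is the quantity the method
#' estimates. All randomness is governed by the mandatory `seed`.
#'
#' @param theta1,theta2 True trial effects.
#' @param sigma1,sigma2 True standard errors (positive).
#' @param method One of [pf_methods()] or `"wilkinson"`.
#' @param alternative `"greater"` or `"less"`.
#' @param n_sim Number of replicates (at least 100; default `1e5`).
#' @param seed Integer seed (mandatory: the 3-Monte-Carlo-SE tolerances used
#'   in validation require known precision).
#' @param levels Confidence levels for coverage (default 0.95).
#' @param wilkinson_r Rank for `method = "wilkinson"`.
#' @return One-row tibble with the scenario, the `target` effect, the mean,
#'   bias, and empirical standard error of the median estimate, their Monte
#'   Carlo standard errors, the fraction of medians above the target
#'   (`prop_above_target`, ~1/2 for a median-unbiased estimate), and a
#'   nested `coverage` tibble (`level`, `coverage`, `mc_se`).
#' @export
#' @examples
#' simulate_oc(0, 0, 1, 1, method = "two_trials_rule", n_sim = 1000, seed = 7)
simulate_oc <- function(theta1, theta2, sigma1, sigma2, method,
                        alternative = c("greater", "less"),
                        n_sim = 1e5, seed, levels = 0.95,
                        wilkinson_r = NULL) {
  alternative <- match.arg(alternative)
  method <- .check_method(method, 2L, wilkinson_r)
  if (any(!is.finite(c(theta1, theta2, sigma1, sigma2))) ||
      sigma1 <= 0 || sigma2 <= 0) {
    abort("true effects must be finite and standard errors positive.")
  }
  if (!is.numeric(n_sim) || n_sim < 100) abort("`n_sim` must be at least 100.")
  if (missing(seed) || !is.numeric(seed)) abort("an integer `seed` is mandatory.")
  levels <- .check_levels(levels)
  n_sim <- as.integer(n_sim)

  theta <- c(theta1, theta2)
  sigma <- c(sigma1, sigma2)
  homog <- theta1 == theta2
  target <- if (homog) theta1 else {
    asymptotic_target(if (method == "wilkinson") "two_trials_rule" else method,
                      theta1, theta2, c = sigma1^2 / sigma2^2,
                      alternative = alternative)
  }

  est <- withr::with_seed(seed, {
    matrix(rnorm(2L * n_sim, mean = rep(theta, each = n_sim),
                 sd = rep(sigma, each = n_sim)), n_sim, 2L)
  })
  sem <- matrix(sigma, n_sim, 2L, byrow = TRUE)

  med <- .median_rows(est, sem, method, alternative, wilkinson_r)
  cov <- map_dfr(levels, function(l) {
    lo <- .mu_rows(est, sem, (1 - l) / 2, method, alternative, wilkinson_r)
    hi <- .mu_rows(est, sem, (1 + l) / 2, method, alternative, wilkinson_r)
    lims_lo <- pmin(lo, hi)
    lims_hi <- pmax(lo, hi)
    cv <- mean(lims_lo <= target & target <= lims_hi)
    tibble(level = l, coverage = cv, mc_se = sqrt(cv * (1 - cv) / n_sim))
  })

  tibble(
    method = method, alternative = alternative,
    theta1 = theta1, theta2 = theta2, sigma1 = sigma1, sigma2 = sigma2,
    n_sim = n_sim, seed = as.integer(seed), target = target,
    mean_of_median = mean(med), bias = mean(med) - target,
    se_of_median = sd(med),
    mc_se_mean = sd(med) / sqrt(n_sim),
    mc_se_se = sd(med) / sqrt(2 * (n_sim - 1)),
    prop_above_target = mean(med > target),
    coverage = list(cov)
  )
}

#' Run a grid of Monte Carlo scenarios from a config
#'
#' Evaluates [simulate_oc()] over the cross product of true-effect pairs,
#' standard-error pairs, and methods described by a configuration — either a
#' list or a path to a YAML/JSON file with fields `theta` (list of 2-vectors),
#' `sigma` (list of 2-vectors), `methods`, `alternative`, `levels`, `n_sim`,
#' and `seed`. Each scenario gets a distinct seed derived from the base seed
#' so the grid is reproducible as a whole.
#'
#' @param config List or path to a YAML/JSON configuration file.
#' @return Tidy tibble, one row per scenario x method, with coverage columns
#'   widened per level (`coverage_95` etc.).
#' @export
#' @examples
#' cfg <- list(theta = list(c(0, 0)), sigma = list(c(1, 1)),
#'             methods = c("two_trials_rule", "meta_analysis"),
#'             n_sim = 500, seed = 42)
#' simulate_grid(cfg)
simulate_grid <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    # yaml/json may deliver theta/sigma as a matrix or list of vectors
    for (fld in c("theta", "sigma")) {
      if (is.matrix(config[[fld]])) {
        config[[fld]] <- asplit(config[[fld]], 1L)
      }
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML/JSON file path.")
  theta <- config$theta %||% abort("config needs `theta` (list of pairs).")
  sigma <- config$sigma %||% abort("config needs `sigma` (list of pairs).")
  methods <- config$methods %||% pf_methods()
  alternative <- config$alternative %||% "greater"
  levels <- config$levels %||% 0.95
  n_sim <- config$n_sim %||% 1e5
  seed <- config$seed %||% abort("config needs a `seed`.")
  if (!is.list(theta)) theta <- list(theta)
  if (!is.list(sigma)) sigma <- list(sigma)

  grid <- expand.grid(i_theta = seq_along(theta), i_sigma = seq_along(sigma),
                      method = methods, stringsAsFactors = FALSE)
  out <- map_dfr(seq_len(nrow(grid)), function(i) {
    th <- theta[[grid$i_theta[i]]]
    sg <- sigma[[grid$i_sigma[i]]]
    simulate_oc(th[1], th[2], sg[1], sg[2], method = grid$method[i],
                alternative = alternative, n_sim = n_sim,
                seed = (as.integer(seed) + i - 1L) %% .Machine$integer.max,
                levels = levels)
  })
  cov_wide <- map_dfr(out$coverage, function(cv) {
    vals <- c(cv$coverage, cv$mc_se)
    names(vals) <- c(paste0("coverage_", format(100 * cv$level, trim = TRUE)),
                     paste0("coverage_mc_se_", format(100 * cv$level, trim = TRUE)))
    as_tibble(as.list(vals))
  })
  dplyr::bind_cols(select(out, -"coverage"), cov_wide)
}
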
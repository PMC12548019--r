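# Inversion of combined p-value functions: the combined estimation function
# mu_hat(a) = {mu : p(mu) = a} yields the median estimate at a = 1/2 and the
# limits of a (1 - alpha) CI at a = alpha/2 and a = 1 - alpha/2. Closed forms
# are used where they exist; otherwise monotone bracketed root-finding.

# closed-form mu_hat(a); returns NULL when no closed form applies
.mu_closed <- function(est, se, a, method, alternative, wilkinson_r = NULL) {
  k <- length(est)
  s <- if (alternative == "greater") 1 else -1
  equal_results <- all(est == est[1]) && all(se == se[1])

  if (method == "wilkinson") {
    if (wilkinson_r == k) method <- "two_trials_rule"
    else if (wilkinson_r == 1) method <- "tippett"
    else return(NULL)
  }

  switch(
    method,
    two_trials_rule = {
      z <- qnorm(a^(1 / k))
      if (s > 0) min(est + se * z) else max(est - se * z)
    },
    tippett = {
      z <- qnorm((1 - a)^(1 / k))
      if (s > 0) max(est - se * z) else min(est + se * z)
    },
    meta_analysis = {
      w <- 1 / se^2
      th <- sum(est * w) / sum(w)
      th + s * qnorm(a) / sqrt(sum(w))
    },
    edgington = {
      if (k == 2 && a == 0.5) {
        sum(est / se) / sum(1 / se)
      } else if (k == 2 && equal_results) {
        z <- if (a <= 0.5) qnorm(sqrt(a / 2)) else -qnorm(sqrt((1 - a) / 2))
        est[1] + s * se[1] * z
      } else NULL
    },
    fisher = {
      if (k == 2 && equal_results) {
        est[1] + s * se[1] * qnorm(exp(-qchisq(1 - a, df = 4) / 4))
      } else NULL
    },
    pearson = {
      if (k == 2 && equal_results) {
        est[1] - s * se[1] * qnorm(exp(-qchisq(a, df = 4) / 4))
      } else NULL
    }
  )
}

# scalar numeric inversion by bracket doubling + Brent (stats::uniroot);
# p(mu) is strictly monotone so the root is unique
.mu_numeric <- function(est, se, a, method, alternative, wilkinson_r = NULL) {
  f <- function(m) {
    .p_rows(matrix(est, 1L), matrix(se, 1L), m, method, alternative,
            wilkinson_r) - a
  }
  lo <- min(est) - 10 * max(se)
  hi <- max(est) + 10 * max(se)
  flo <- f(lo)
  fhi <- f(hi)
  ok <- FALSE
  for (i in 1:60) {
    if (flo * fhi <= 0) {
      ok <- TRUE
      break
    }
    mid <- (lo + hi) / 2
    h <- hi - lo
    lo <- mid - h
    hi <- mid + h
    flo <- f(lo)
    fhi <- f(hi)
  }
  if (!ok) {
    abort("root not bracketed after 60 bracket doublings; p-value function may be degenerate.")
  }
  uniroot(f, lower = lo, upper = hi, f.lower = flo, f.upper = fhi,
          tol = 1e-12 * max(max(se), 1))$root
}

#' Combined estimation function (inverse p-value function)
#'
#' Returns the null value `mu` at which the combined p-value function equals
#' `a`: the median estimate for `a = 1/2`, the limits of a `(1 - alpha)` CI
#' for `a = alpha/2` and `a = 1 - alpha/2`. Closed forms are used where they
#' exist (two-trials rule, Tippett, meta-analysis at every `a`; Wilkinson
#' with r = 1 or r = k; Edgington's two-trial median; and the equal-results
#' special cases of Fisher, Pearson, and Edgington); the remaining cases are
#' solved by monotone bracketed root-finding with absolute tolerance
#' `1e-12 * max(se, 1)` in `mu`.
#'
#' @inheritParams combined_p
#' @param a Probability level(s) in (0, 1) at which to invert.
#' @param inversion `"auto"` (closed form where available, else numeric),
#'   `"closed"` (error if unavailable), or `"numeric"` (always root-find).
#' @return Effect value(s) `mu` with `combined_p(trials, mu) = a`.
#' @export
#' @examples
#' trials <- pf_fixture("respire_14d")
#' estimation_fun(trials, a = 0.5, method = "two_trials_rule",
#'                alternative = "less")   # Table-style median estimate
estimation_fun <- function(trials, a, method,
                           alternative = c("greater", "less"),
                           wilkinson_r = NULL,
                           inversion = c("auto", "closed", "numeric")) {
  tr <- as_trials(trials)
  alternative <- match.arg(alternative)
  inversion <- match.arg(inversion)
  method <- .check_method(method, nrow(tr), wilkinson_r)
  a <- .check_levels(a, "a")

  vapply(a, function(ai) {
    cf <- if (inversion != "numeric") {
      .mu_closed(tr$estimate, tr$se, ai, method, alternative, wilkinson_r)
    }
    if (!is.null(cf)) return(cf)
    if (inversion == "closed") {
      abort(sprintf("no closed-form estimation function for method \"%s\" in this configuration.", method))
    }
    .mu_numeric(tr$estimate, tr$se, ai, method, alternative, wilkinson_r)
  }, numeric(1))
}

#' Confidence interval from a combined p-value function
#'
#' The two-sided `(1 - alpha)` CI collects the null values at which the
#' combined p-value function equals `alpha/2` and `1 - alpha/2`; limits are
#' reported sorted so the same interval is returned for either alternative
#' ordering. By construction the interval is compatible with the combined
#' test: the centrality-transformed p-value at a null value is below `alpha`
#' exactly when that value falls outside the interval.
#'
#' @inheritParams estimation_fun
#' @param level Confidence level(s) in (0, 1).
#' @return Tibble with columns `level`, `lower`, `upper`, `width`.
#' @export
#' @examples
#' pf_confint(pf_fixture("respire_14d"), level = 0.95,
#'            method = "meta_analysis", alternative = "less")
pf_confint <- function(trials, level = 0.95, method,
                       alternative = c("greater", "less"),
                       wilkinson_r = NULL,
                       inversion = c("auto", "closed", "numeric")) {
  alternative <- match.arg(alternative)
  inversion <- match.arg(inversion)
  level <- .check_levels(level, "level")
  map_dfr(level, function(l) {
    lims <- estimation_fun(trials, a = c((1 - l) / 2, (1 + l) / 2),
                           method = method, alternative = alternative,
                           wilkinson_r = wilkinson_r, inversion = inversion)
    lims <- sort(lims)
    tibble(level = l, lower = lims[1], upper = lims[2],
           width = lims[2] - lims[1])
  })
}

#' Implicit weight of the first trial in a two-trial median estimate
#'
#' Writes a two-trial median estimate as the weighted average
#' `w * estimate_1 + (1 - w) * estimate_2` and returns `w`. For
#' meta-analysis `w = se_2^2 / (se_1^2 + se_2^2)` (inverse-variance) and for
#' Edgington's method `w = se_2 / (se_1 + se_2)` (inverse-SE); for the other
#' methods the weight falls outside `[0, 1]` when the median lies outside
#' the two estimates.
#'
#' @param trials Two-trial data frame (estimates must differ).
#' @param median Median estimate to decompose.
#' @return Weight of trial 1.
#' @export
implicit_weight <- function(trials, median) {
  tr <- as_trials(trials)
  if (nrow(tr) != 2L) abort("implicit weights are defined for exactly two trials.")
  if (tr$estimate[1] == tr$estimate[2]) {
    abort("implicit weight is undefined when the two estimates coincide.")
  }
  (median - tr$estimate[2]) / (tr$estimate[1] - tr$estimate[2])
}

#' Full combined p-value function inference
#'
#' Assembles, for each requested combination method, the median estimate,
#' confidence intervals at all requested levels (by default 95% and the
#' regulatory `1 - 2 * 0.025^2 = 99.875%` level matching a two-trials-rule
#' decision at one-sided 0.025), the combined one-sided p-value at the null
#' value, and — for two trials — the implicit weight of the first trial.
#'
#' @inheritParams combined_p
#' @param methods Character vector of combination methods.
#' @param levels Confidence levels in (0, 1).
#' @param null_value Null value at which the combined p-value is reported.
#' @return Object of class `pf_inference`; use [tidy()] for the full-precision
#'   results table (one row per method and level), [glance()] for a one-row
#'   summary, `print()` for a Table-style display, and [autoplot()] for a
#'   forest-style plot with telescope CIs.
#' @export
#' @examples
#' fit <- pf_inference(pf_fixture("respire_14d"), alternative = "less")
#' fit
#' tidy(fit)
pf_inference <- function(trials, methods = pf_methods(),
                         alternative = c("greater", "less"),
                         levels = c(0.95, 0.99875), null_value = 0,
                         wilkinson_r = NULL) {
  tr <- as_trials(trials)
  alternative <- match.arg(alternative)
  if (length(methods) < 1L) abort("at least one method is required.")
  levels <- .check_levels(levels)
  if (length(null_value) != 1L || !is.finite(null_value)) {
    abort("`null_value` must be a single finite number.")
  }

  res <- map_dfr(methods, function(m) {
    med <- estimation_fun(tr, a = 0.5, method = m, alternative = alternative,
                          wilkinson_r = wilkinson_r)
    w <- if (nrow(tr) == 2L && tr$estimate[1] != tr$estimate[2]) {
      implicit_weight(tr, med)
    } else NA_real_
    p0 <- combined_p(tr, null_value, method = m, alternative = alternative,
                     wilkinson_r = wilkinson_r)
    ci <- pf_confint(tr, level = levels, method = m,
                     alternative = alternative, wilkinson_r = wilkinson_r)
    mutate(ci, method = m, estimate = med, weight_trial1 = w,
           p_onesided = p0, .before = 1)
  })
  res <- select(res, "method", "estimate", "weight_trial1", "level",
                ci_lower = "lower", ci_upper = "upper", ci_width = "width",
                "p_onesided")

  structure(
    list(table = res, trials = tr, alternative = alternative,
         null_value = null_value, levels = levels, methods = methods),
    class = "pf_inference"
  )
}

#' @describeIn pf_inference Full-precision results, one row per method and
#'   confidence level.
#' @param x A `pf_inference` object.
#' @param ... Unused.
#' @export
tidy.pf_inference <- function(x, ...) x$table

#' @describeIn pf_inference One-row summary of the inference setup.
#' @export
glance.pf_inference <- function(x, ...) {
  tibble(
    n_trials = nrow(x$trials),
    n_methods = length(x$methods),
    alternative = x$alternative,
    null_value = x$null_value,
    levels = paste(format(x$levels, trim = TRUE), collapse = ", ")
  )
}

#' @export
print.pf_inference <- function(x, digits = NULL, ...) {
  cat(sprintf(
    "Combined p-value function inference (%d trials, alternative \"%s\", null value %g)\n\n",
    nrow(x$trials), x$alternative, x$null_value
  ))
  lev <- min(x$levels)
  tb <- filter(x$table, .data$level == lev)
  # paper-style precision: 2 dp on the effect scale, 5 dp on p-values;
  # pass digits to print at full precision instead
  fmt_e <- function(v) if (is.null(digits)) sprintf("%.2f", v) else format(v, digits = digits)
  fmt_p <- function(v) if (is.null(digits)) sprintf("%.5f", v) else format(v, digits = digits)
  out <- data.frame(
    method = tb$method,
    estimate = fmt_e(tb$estimate),
    weight_trial1 = ifelse(is.na(tb$weight_trial1), "", fmt_e(tb$weight_trial1)),
    CI = sprintf("%s to %s", fmt_e(tb$ci_lower), fmt_e(tb$ci_upper)),
    width = fmt_e(tb$ci_width),
    p_onesided = fmt_p(tb$p_onesided),
    check.names = FALSE
  )
  names(out)[4] <- sprintf("%g%% CI", 100 * lev)
  print(out, row.names = FALSE, right = FALSE)
  if (length(x$levels) > 1L) {
    cat(sprintf("\n(additional levels computed: %s; see tidy())\n",
                paste(format(x$levels[-1], trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Forest-style plot of combined inference with telescope CIs
#'
#' One row per method (plus the individual trials), point at the median
#' estimate, a thick segment for the lowest confidence level and thinner
#' segments for the higher (telescope display).
#'
#' @param object A [pf_inference()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_inference <- function(object, ...) {
  tb <- object$table
  tr <- object$trials
  lev <- sort(unique(tb$level))
  trial_tb <- tibble(
    method = tr$id, estimate = tr$estimate, level = lev[1],
    ci_lower = tr$estimate - qnorm((1 + lev[1]) / 2) * tr$se,
    ci_upper = tr$estimate + qnorm((1 + lev[1]) / 2) * tr$se
  )
  tb$method <- factor(tb$method, levels = rev(c(tr$id, object$methods)))
  trial_tb$method <- factor(trial_tb$method, levels = levels(tb$method))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$method, x = .data$estimate)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ci_lower, xend = .data$ci_upper,
                   yend = .data$method,
                   linewidth = factor(-.data$level))
    ) +
    ggplot2::geom_segment(
      data = trial_tb,
      ggplot2::aes(x = .data$ci_lower, xend = .data$ci_upper,
                   yend = .data$method),
      linewidth = 0.5, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = trial_tb, size = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$null_value, linetype = "dotted") +
    ggplot2::scale_linewidth_manual(
      values = stats::setNames(seq(1.2, 0.4, length.out = length(lev)),
                               as.character(-lev)),
      labels = paste0(100 * lev, "%"), name = "CI level"
    ) +
    ggplot2::labs(x = "effect (additive scale)", y = NULL) +
    ggplot2::theme_minimal()
}
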
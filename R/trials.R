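# Per-trial summary statistics: effect estimate on an additive scale
# (log rate ratio, log hazard ratio, mean difference, ...) plus a positive
# standard error. Whatever uncertainty summary a publication reports (SE,
# Wald CI, one-sided p-value) is converted back to the standard error under
# the normal model  theta_hat | theta ~ N(theta, sigma^2).

#' Reconstruct a standard error from a Wald confidence interval
#'
#' Assumes the interval is a symmetric normal (Wald) interval on an additive
#' effect scale, so that `upper - lower = 2 * z * se` with
#' `z = qnorm((1 + level) / 2)`.
#'
#' @param lower,upper Interval limits (finite, `lower < upper`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Positive standard error(s).
#' @export
#' @examples
#' se_from_ci(-0.85, -0.13)            # RESPIRE 1, 14-day group
#' se_from_ci(-1.959964, 1.959964)     # unit standard normal interval
se_from_ci <- function(lower, upper, level = 0.95) {
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("CI limits must be finite.")
  }
  if (any(lower >= upper)) {
    abort("`lower` must be strictly below `upper` (inverted or degenerate CI).")
  }
  level <- .check_levels(level, "level")
  (upper - lower) / (2 * qnorm((1 + level) / 2))
}

#' Reconstruct a standard error from a one-sided p-value
#'
#' Inverts the one-sided normal p-value so that [one_sided_p()] evaluated at
#' the returned standard error reproduces `p` exactly. The orientation of
#' `estimate - null` must be consistent with the p-value: under alternative
#' `"less"`, `p < 0.5` requires `estimate < null` (and conversely); `p = 0.5`
#' carries no information about the standard error and is rejected.
#'
#' @param estimate Effect estimate (additive scale).
#' @param p One-sided p-value strictly inside (0, 1), not equal to 0.5.
#' @param null Null value the p-value refers to (default 0).
#' @param alternative `"greater"` or `"less"`.
#' @return Positive standard error.
#' @export
#' @examples
#' se_from_p(-0.49, 0.00351, alternative = "less")   # RESPIRE 1, 14-day group
se_from_p <- function(estimate, p, null = 0,
                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(!is.finite(estimate)) || any(!is.finite(null))) {
    abort("`estimate` and `null` must be finite.")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must be strictly between 0 and 1.")
  }
  if (any(p == 0.5)) {
    abort("p = 0.5 puts the estimate exactly at the null and does not identify the standard error.")
  }
  z <- if (alternative == "greater") qnorm(1 - p) else qnorm(p)
  se <- (estimate - null) / z
  if (any(se <= 0)) {
    abort(paste0(
      "inconsistent orientation: under alternative \"", alternative,
      "\" the sign of (estimate - null) contradicts the supplied p-value."
    ))
  }
  se
}

#' Standardise per-trial summary data
#'
#' Takes a data frame with one row per trial and returns a validated tibble
#' with columns `id`, `estimate`, `se`. The standard error may be supplied
#' directly (`se`), as a Wald CI (`ci_lower`, `ci_upper`, optional
#' `ci_level`, default 0.95), or as a one-sided p-value (`p_onesided`,
#' interpreted with `alternative` and `null`). When several summaries are
#' present the precedence is se > CI > p — the standard error is the
#' primitive of the normal model, CIs and p-values are rounded derivatives —
#' and a warning is raised if an unused summary disagrees with the used one
#' by more than 1% relative.
#'
#' @param x Data frame with columns `estimate` and at least one uncertainty
#'   summary; optionally `id`.
#' @param alternative Orientation of `p_onesided`, if that route is used.
#' @param null Null value `p_onesided` refers to (default 0).
#' @return Tibble with columns `id`, `estimate`, `se`.
#' @export
#' @examples
#' as_trials(data.frame(id = c("RESPIRE 1", "RESPIRE 2"),
#'                      estimate = c(-0.49, -0.18),
#'                      ci_lower = c(-0.85, -0.53),
#'                      ci_upper = c(-0.13, 0.16)))
as_trials <- function(x, alternative = c("greater", "less"), null = 0) {
  alternative <- match.arg(alternative)
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame of per-trial summaries.")
  }
  x <- as_tibble(x)
  if (!"estimate" %in% names(x)) {
    abort("`x` must have an `estimate` column.")
  }
  if (nrow(x) < 1L) abort("`x` must contain at least one trial.")
  if (any(!is.finite(x$estimate))) abort("`estimate` must be finite.")

  id <- if ("id" %in% names(x)) as.character(x$id) else paste0("trial ", seq_len(nrow(x)))

  has_se <- "se" %in% names(x) && all(is.finite(x$se))
  has_ci <- all(c("ci_lower", "ci_upper") %in% names(x)) &&
    all(is.finite(x$ci_lower)) && all(is.finite(x$ci_upper))
  has_p <- "p_onesided" %in% names(x) && all(is.finite(x$p_onesided))

  se_ci <- if (has_ci) {
    level <- if ("ci_level" %in% names(x)) x$ci_level else 0.95
    se_from_ci(x$ci_lower, x$ci_upper, level = unique(level))
  }
  # p-based reconstruction is only a cross-check when a higher-precedence
  # summary exists; an orientation error then just disables the check
  se_p <- if (has_p) {
    if (has_se || has_ci) {
      tryCatch(
        se_from_p(x$estimate, x$p_onesided, null = null, alternative = alternative),
        error = function(e) NULL
      )
    } else {
      se_from_p(x$estimate, x$p_onesided, null = null, alternative = alternative)
    }
  }

  if (has_se) {
    if (any(x$se <= 0)) abort("`se` must be strictly positive.")
    se <- x$se
    .warn_se_disagreement(se, se_ci, "CI-derived")
    .warn_se_disagreement(se, se_p, "p-value-derived")
  } else if (has_ci) {
    se <- se_ci
    .warn_se_disagreement(se, se_p, "p-value-derived")
  } else if (has_p) {
    se <- se_p
  } else {
    abort("each trial needs `se`, a (`ci_lower`, `ci_upper`) pair, or `p_onesided`.")
  }

  tibble(id = id, estimate = x$estimate, se = se)
}

.warn_se_disagreement <- function(used, other, label) {
  if (is.null(other)) return(invisible())
  rel <- abs(other - used) / used
  if (any(rel > 0.01)) {
    warn(sprintf(
      "%s standard error disagrees with the one used by more than 1%% relative (max %.1f%%); using the higher-precedence summary.",
      label, 100 * max(rel)
    ))
  }
  invisible()
}

#' One-sided p-value function of a single trial
#'
#' Under the normal model, the one-sided p-value for the null value `mu` is
#' `1 - pnorm((estimate - mu) / se)` for alternative `"greater"` and
#' `pnorm((estimate - mu) / se)` for `"less"`. As a function of `mu` it is
#' strictly increasing (`"greater"`) or decreasing (`"less"`).
#'
#' @param estimate Effect estimate.
#' @param se Positive standard error.
#' @param mu Null value(s) at which to evaluate.
#' @param alternative `"greater"` or `"less"`.
#' @return p-value(s) in (0, 1).
#' @export
#' @examples
#' one_sided_p(0.5, 1, mu = 0.5, alternative = "greater")  # 0.5 at the estimate
one_sided_p <- function(estimate, se, mu = 0,
                        alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(!is.finite(estimate)) || any(!is.finite(se)) || any(se <= 0)) {
    abort("`estimate` must be finite and `se` finite and positive.")
  }
  z <- (estimate - mu) / se
  pnorm(z, lower.tail = (alternative == "less"))
}
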
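# Combined p-value functions: evaluate g(p1(mu), ..., pk(mu)) for the six
# combiners (plus general Wilkinson r-of-k) at arbitrary null values mu.
# All combiners are symmetric in the trials, valid (uniform under the null
# when the per-trial p-values are uniform), and strictly monotone in mu.

# row-wise helpers over an n x k matrix -----------------------------------
.rowmax <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
.rowmin <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
.row_kth <- function(m, r) apply(m, 1L, function(x) sort(x, partial = r)[r])

# clip p away from {0, 1} before logs / normal quantiles; the lower clip is
# 1e-300 (Fisher's log), the upper clip the largest double below 1. Internal
# root-finding evaluates the tails routinely, so the warning is only emitted
# from user-facing entry points (see .warn_clip()).
.clip_p <- function(p) {
  pmin(pmax(p, 1e-300), 1 - .Machine$double.eps / 2)
}

.warn_clip <- function(p, method) {
  if (method %in% c("fisher", "pearson", "meta_analysis") &&
      (any(p <= 0) || any(p >= 1))) {
    warn("p-values at 0 or 1 were clipped to [1e-300, 1 - eps] before taking logs/quantiles.")
  }
  invisible()
}

# core combiner on an n x k matrix of one-sided p-values; `weights` (n x k or
# NULL, only used by meta_analysis/Stouffer) defaults to equal weights
.g_combine <- function(p, method, weights = NULL, wilkinson_r = NULL) {
  k <- ncol(p)
  switch(
    method,
    two_trials_rule = .rowmax(p)^k,
    tippett = 1 - (1 - .rowmin(p))^k,
    wilkinson = {
      pr <- .row_kth(p, wilkinson_r)
      pbinom(wilkinson_r - 1L, size = k, prob = pr, lower.tail = FALSE)
    },
    meta_analysis = {
      w <- weights %||% matrix(1, nrow(p), k)
      z <- qnorm(.clip_p(p), lower.tail = FALSE)
      zc <- rowSums(w * z) / sqrt(rowSums(w^2))
      pnorm(zc, lower.tail = FALSE)
    },
    fisher = {
      f <- -2 * rowSums(log(.clip_p(p)))
      pchisq(f, df = 2 * k, lower.tail = FALSE)
    },
    pearson = {
      kk <- -2 * rowSums(log1p(-.clip_p(p)))
      pchisq(kk, df = 2 * k, lower.tail = TRUE)
    },
    edgington = pirwinhall(rowSums(p), k)
  )
}

# evaluate the combined p-value function row-wise: est/se are n x k matrices,
# mu a length-n vector (row i is evaluated at mu[i])
.p_rows <- function(est, se, mu, method, alternative, wilkinson_r = NULL) {
  z <- (est - mu) / se
  p <- pnorm(z, lower.tail = (alternative == "less"))
  w <- if (method == "meta_analysis") 1 / se else NULL
  .g_combine(p, method, weights = w, wilkinson_r = wilkinson_r)
}

.trial_matrices <- function(tr, n) {
  k <- nrow(tr)
  list(est = matrix(tr$estimate, n, k, byrow = TRUE),
       se = matrix(tr$se, n, k, byrow = TRUE))
}

#' Combined p-value function of two or more trials
#'
#' Evaluates the combined one-sided p-value function at null value(s) `mu`
#' for a set of trials. The per-trial p-value functions [one_sided_p()] are
#' combined with the requested method:
#' \describe{
#'   \item{`two_trials_rule`}{`max(p_i)^k`, the squared maximum for k = 2;
#'     Wilkinson's method with r = k.}
#'   \item{`meta_analysis`}{weighted Stouffer / inverse-normal with weights
#'     `1/se_i`, identical to the fixed-effect meta-analysis z-statistic.}
#'   \item{`tippett`}{`1 - (1 - min(p_i))^k`; Wilkinson with r = 1.}
#'   \item{`fisher`}{upper chi-squared(2k) tail of `-2 * sum(log p_i)`.}
#'   \item{`pearson`}{lower chi-squared(2k) tail of `-2 * sum(log(1 - p_i))`.}
#'   \item{`edgington`}{Irwin–Hall CDF of order k at `sum(p_i)`.}
#'   \item{`wilkinson`}{binomial upper tail `P(Bin(k, p_(r)) >= r)` at the
#'     r-th smallest p-value.}
#' }
#'
#' @param trials Data frame of per-trial summaries; passed to [as_trials()].
#' @param mu Null value(s) at which to evaluate the combined p-value function.
#' @param method One of [pf_methods()] or `"wilkinson"`.
#' @param alternative `"greater"` or `"less"` (orientation of the per-trial
#'   one-sided p-values).
#' @param wilkinson_r Order-statistic rank for `method = "wilkinson"`.
#' @return Vector of combined p-values in `[0, 1]`, monotone in `mu`
#'   (nondecreasing for `"greater"`, nonincreasing for `"less"`).
#' @seealso [combine_p()] to combine already-computed p-values directly,
#'   [estimation_fun()] for the inverse.
#' @export
#' @examples
#' trials <- pf_fixture("respire_14d")
#' combined_p(trials, mu = 0, method = "two_trials_rule", alternative = "less")
combined_p <- function(trials, mu, method = "meta_analysis",
                       alternative = c("greater", "less"),
                       wilkinson_r = NULL) {
  tr <- as_trials(trials)
  alternative <- match.arg(alternative)
  method <- .check_method(method, nrow(tr), wilkinson_r)
  if (any(!is.finite(mu))) abort("`mu` must be finite.")
  m <- .trial_matrices(tr, length(mu))
  .p_rows(m$est, m$se, mu, method, alternative, wilkinson_r)
}

#' Combine one-sided p-values directly
#'
#' Applies a combination method to already-computed one-sided p-values
#' (all oriented toward the same alternative), without reference to effect
#' estimates. This is the entry point for reproducing published combined
#' p-values exactly from printed per-trial p-values. For
#' `method = "meta_analysis"` (weighted Stouffer) the `weights` are the
#' inverse standard errors `1/se_i`; equal weights are used when omitted.
#'
#' @param p Vector of k >= 2 one-sided p-values, or an n x k matrix (one
#'   combination per row).
#' @param method,wilkinson_r As in [combined_p()].
#' @param weights Optional positive weights (length k or n x k matrix), used
#'   by `meta_analysis` only.
#' @return Combined p-value(s).
#' @export
#' @examples
#' combine_p(c(0.00351, 0.14400), method = "two_trials_rule")  # 0.02073
#' combine_p(c(0.00351, 0.14400), method = "tippett")          # 0.00701
combine_p <- function(p, method, weights = NULL, wilkinson_r = NULL) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  k <- ncol(p)
  method <- .check_method(method, k, wilkinson_r)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must be probabilities in [0, 1].")
  }
  if (!is.null(weights)) {
    if (is.null(dim(weights))) weights <- matrix(weights, nrow(p), k, byrow = TRUE)
    if (any(weights <= 0)) abort("`weights` must be positive.")
  }
  .warn_clip(p, method)
  out <- .g_combine(p, method, weights = weights, wilkinson_r = wilkinson_r)
  unname(out)
}

#' Two-sided centrality transform
#'
#' Converts a one-sided p-value function into its two-sided counterpart
#' `2 * min(p, 1 - p)`, which peaks at 1 where the one-sided function
#' crosses 1/2 (the median estimate) and can be thresholded at `alpha` to
#' read off the (1 - alpha) confidence interval.
#'
#' @param p One-sided p-value(s) in `[0, 1]`.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' centrality(0.5)    # 1
#' centrality(0.975)  # 0.05
centrality <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must be probabilities in [0, 1].")
  }
  2 * pmin(p, 1 - p)
}

#' Irwin–Hall cumulative distribution function
#'
#' Distribution function of the sum of `k` independent Uniform(0, 1)
#' variables — the null distribution of Edgington's sum statistic. Uses the
#' exact alternating-sum formula with Kahan-compensated summation and the
#' symmetry `F(x) = 1 - F(k - x)` to control cancellation; exact evaluation
#' is supported for `k <= 30` and refused beyond that rather than silently
#' switching to an approximation.
#'
#' @param q Quantile(s), clamped to `[0, k]`.
#' @param k Order (number of uniforms), a positive integer `<= 30`.
#' @return `P(U_1 + ... + U_k <= q)`.
#' @export
#' @examples
#' pirwinhall(1, 2)   # 0.5
#' pirwinhall(1, 4)   # 1/24
pirwinhall <- function(q, k) {
  if (length(k) != 1L || !is.numeric(k) || k != round(k) || k < 1) {
    abort("`k` must be a single positive integer.")
  }
  if (k > 30) {
    abort("exact Irwin-Hall evaluation is limited to k <= 30.")
  }
  x <- pmin(pmax(q, 0), k)
  refl <- x > k / 2
  xs <- ifelse(refl, k - x, x)
  s <- numeric(length(xs))
  comp <- numeric(length(xs))
  for (j in 0:k) {
    term <- (-1)^j * choose(k, j) * pmax(xs - j, 0)^k
    y <- term - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  f <- s / factorial(k)
  out <- ifelse(refl, 1 - f, f)
  pmin(pmax(out, 0), 1)
}

#' Evaluate p-value function curves on a grid of null values
#'
#' Computes one- and two-sided (centrality-transformed) p-value function
#' curves for a set of combination methods, optionally together with the
#' individual trials' own p-value functions, on a grid of null values. The
#' default grid is centred at the meta-analytic median and spans plus/minus
#' 5 times the largest trial standard error at 1001 points, wide enough to
#' cover every method's support of interest. The result is a tidy tibble
#' ready for CSV export or plotting (see [autoplot.pf_curve()]).
#'
#' @inheritParams combined_p
#' @param methods Character vector of combination methods.
#' @param mu Optional explicit grid of null values.
#' @param points Grid size when `mu` is not supplied.
#' @param include_trials Also return each trial's single-trial p-value
#'   function (labelled by trial id)?
#' @return Tibble of class `pf_curve` with columns `source` (method or trial
#'   id), `mu`, `p_onesided`, `p_twosided`.
#' @export
#' @examples
#' crv <- pf_curve(pf_fixture("respire_14d"), alternative = "less")
#' head(crv)
pf_curve <- function(trials, methods = pf_methods(),
                     alternative = c("greater", "less"),
                     mu = NULL, points = 1001L, include_trials = TRUE,
                     wilkinson_r = NULL) {
  tr <- as_trials(trials)
  alternative <- match.arg(alternative)
  if (length(methods) < 1L) abort("at least one method is required.")
  if (is.null(mu)) {
    centre <- estimation_fun(tr, a = 0.5, method = "meta_analysis",
                             alternative = alternative)
    half <- 5 * max(tr$se)
    mu <- seq(centre - half, centre + half, length.out = points)
  }
  curves <- map_dfr(methods, function(m) {
    p1 <- combined_p(tr, mu, method = m, alternative = alternative,
                     wilkinson_r = wilkinson_r)
    tibble(source = m, mu = mu, p_onesided = p1, p_twosided = centrality(p1))
  })
  if (include_trials) {
    trial_curves <- map_dfr(seq_len(nrow(tr)), function(i) {
      p1 <- one_sided_p(tr$estimate[i], tr$se[i], mu, alternative = alternative)
      tibble(source = tr$id[i], mu = mu, p_onesided = p1,
             p_twosided = centrality(p1))
    })
    curves <- bind_rows(trial_curves, curves)
  }
  class(curves) <- c("pf_curve", class(curves))
  curves
}

#' Plot p-value function curves
#'
#' Two-sided (centrality) p-value function curves against the null value,
#' one line per method (solid) and per trial (dashed).
#'
#' @param object A [pf_curve()] tibble.
#' @param alpha Optional significance threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_curve <- function(object, alpha = 0.05, ...) {
  is_method <- object$source %in% .all_methods()
  object$role <- ifelse(is_method, "combined", "trial")
  gg <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$mu, y = .data$p_twosided,
    colour = .data$source, linetype = .data$role
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(combined = "solid", trial = "dashed")) +
    ggplot2::labs(x = expression(mu), y = "two-sided p-value function",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(alpha)) {
    gg <- gg + ggplot2::geom_hline(yintercept = alpha, linetype = "dotted")
  }
  gg
}

#' @importFrom rlang .data
NULL
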
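# Inversion of combined p-value functions: medians, confidence intervals,
# implicit weights, compatibility, and asymptotic behaviour.

test_that("closed-form medians match their derivations", {
  # two identical trials: the 2TR median sits 0.5449 SEs above the estimate
  eq <- equal_trials(estimate = 0.3, se = 1)
  q <- qnorm(sqrt(0.5))
  expect_equal(q, 0.54495213561736)
  expect_equal(estimation_fun(eq, 0.5, "two_trials_rule", "greater"), 0.3 + q)
  expect_equal(estimation_fun(eq, 0.5, "tippett", "greater"), 0.3 - q)
  # Fisher/Pearson equal-results median shift: about -0.17 SEs
  shift <- qnorm(exp(-qchisq(0.5, 4) / 4))
  expect_equal(shift, -0.171112936990766)
  expect_equal(estimation_fun(eq, 0.5, "fisher", "greater"), 0.3 + shift)
  expect_equal(estimation_fun(eq, 0.5, "pearson", "greater"), 0.3 - shift)
  # meta-analysis and Edgington medians equal the observed common estimate
  expect_equal(estimation_fun(eq, 0.5, "meta_analysis", "greater"), 0.3)
  expect_equal(estimation_fun(eq, 0.5, "edgington", "greater"), 0.3)

  # unequal trials: MA median is the inverse-variance mean, Edgington's the
  # inverse-SE mean
  tr <- make_trials(c(-0.49, -0.18), c(0.3, 0.5))
  w <- 1 / tr$se^2
  expect_equal(estimation_fun(tr, 0.5, "meta_analysis", "less"),
               sum(tr$estimate * w) / sum(w))
  expect_equal(estimation_fun(tr, 0.5, "edgington", "less"),
               sum(tr$estimate / tr$se) / sum(1 / tr$se))
})

test_that("RESPIRE 14-day medians and CIs reproduce the published table at 2 dp", {
  tr <- respire14()
  med_2tr <- estimation_fun(tr, 0.5, "two_trials_rule", "less")
  expect_equal(round(med_2tr, 2), -0.28)
  expect_equal(round(implicit_weight(tr, med_2tr), 2), 0.31)
  med_ma <- estimation_fun(tr, 0.5, "meta_analysis", "less")
  expect_equal(round(med_ma, 2), -0.33)
  ci_ma <- pf_confint(tr, 0.95, "meta_analysis", "less")
  expect_equal(round(c(ci_ma$lower, ci_ma$upper), 2), c(-0.58, -0.08))
  med_e <- estimation_fun(tr, 0.5, "edgington", "less")
  expect_equal(round(implicit_weight(tr, med_e), 2), 0.49)
  expect_equal(round(estimation_fun(tr, 0.5, "tippett", "less"), 2), -0.39)
})

test_that("equal-trials confidence intervals use the restored quantile orders", {
  eq <- equal_trials(estimate = 0, se = 1)
  ci_2tr <- pf_confint(eq, 0.95, "two_trials_rule", "greater")
  # frozen qnorm(sqrt(0.025)) and qnorm(sqrt(0.975)): the published -1 / 2.24
  expect_equal(ci_2tr$lower, -1.00223984904763)
  expect_equal(ci_2tr$upper, 2.23896437565297)
  ci_e <- pf_confint(eq, 0.95, "edgington", "greater")
  expect_equal(ci_e$upper, 1.21699321405315)
  expect_equal(ci_e$lower, -1.21699321405315)
  # Edgington's equal-trials 95% CI is ~12.2% narrower than meta-analysis
  ci_ma <- pf_confint(eq, 0.95, "meta_analysis", "greater")
  expect_equal(round(100 * (1 - ci_e$width / ci_ma$width), 1), 12.2)
  # only meta-analysis and Edgington give symmetric CIs around the estimate
  for (m in c("meta_analysis", "edgington")) {
    ci <- pf_confint(eq, 0.95, m, "greater")
    expect_equal(ci$lower + ci$upper, 0, tolerance = 1e-9)
  }
  for (m in c("two_trials_rule", "tippett", "fisher", "pearson")) {
    ci <- pf_confint(eq, 0.95, m, "greater")
    expect_gt(abs(ci$lower + ci$upper), 0.1)
  }
})

test_that("closed-form and numeric inversion agree to 1e-8 * max(se)", {
  a_grid <- c(0.001, 0.025, 0.2, 0.5, 0.8, 0.975, 0.999)
  tr <- make_trials(c(-0.49, -0.18), c(0.3, 0.5))
  tol <- 1e-8 * max(tr$se)
  for (m in c("two_trials_rule", "tippett", "meta_analysis")) {
    for (alt in c("greater", "less")) {
      cf <- estimation_fun(tr, a_grid, m, alt, inversion = "closed")
      nm <- estimation_fun(tr, a_grid, m, alt, inversion = "numeric")
      expect_lt(max(abs(cf - nm)), tol)
    }
  }
  # equal-results special cases for the product/sum methods
  eq <- equal_trials(estimate = -0.2, se = 0.7)
  for (m in c("fisher", "pearson", "edgington")) {
    cf <- estimation_fun(eq, a_grid, m, "greater", inversion = "closed")
    nm <- estimation_fun(eq, a_grid, m, "greater", inversion = "numeric")
    expect_lt(max(abs(cf - nm)), 1e-8 * 0.7)
  }
  # Edgington's two-trial median closed form against the numeric root
  tr2 <- make_trials(c(0.1, 0.9), c(0.25, 0.8))
  expect_lt(abs(estimation_fun(tr2, 0.5, "edgington", "greater", inversion = "closed") -
                estimation_fun(tr2, 0.5, "edgington", "greater", inversion = "numeric")),
            1e-8 * 0.8)
  expect_error(estimation_fun(tr2, 0.4, "edgington", "greater", inversion = "closed"),
               "no closed-form")
})

test_that("p-values, CIs, and estimates are mutually compatible", {
  tr_list <- list(respire14(), pf_fixture("orbit_primary"))
  alphas <- c(0.001, 0.01, 0.05, 0.1, 0.2)
  for (tr in tr_list) {
    for (m in methods_all()) {
      med <- estimation_fun(tr, 0.5, m, "less")
      for (al in alphas) {
        ci <- pf_confint(tr, 1 - al, m, "less")
        # median estimate inside every CI
        expect_true(ci$lower <= med && med <= ci$upper)
        # two-sided p < alpha exactly when the null value is outside the CI
        for (mu0 in c(ci$lower - 0.05, (ci$lower + ci$upper) / 2, ci$upper + 0.05)) {
          p2 <- centrality(combined_p(tr, mu0, m, "less"))
          outside <- mu0 < ci$lower || mu0 > ci$upper
          expect_identical(p2 < al, outside)
        }
      }
    }
  }
})

test_that("CIs are nested across confidence levels and contain the median", {
  tr <- pf_fixture("orbit_secondary")
  fit <- pf_inference(tr, alternative = "less",
                      levels = c(0.5, 0.8, 0.95, 0.99875))
  tb <- tidy(fit)
  for (m in unique(tb$method)) {
    sub <- tb[tb$method == m, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$ci_lower) <= 1e-12))
    expect_true(all(diff(sub$ci_upper) >= -1e-12))
    expect_true(all(sub$ci_lower <= sub$estimate & sub$estimate <= sub$ci_upper))
  }
})

test_that("Edgington's two-sided CI is orientation invariant; medians obey the 2TR/Tippett duality", {
  tr <- make_trials(c(-0.6, 0.2), c(0.35, 0.6))
  for (lev in c(0.9, 0.95, 0.99)) {
    ci_g <- pf_confint(tr, lev, "edgington", "greater")
    ci_l <- pf_confint(tr, lev, "edgington", "less")
    expect_equal(ci_g$lower, ci_l$lower, tolerance = 1e-9)
    expect_equal(ci_g$upper, ci_l$upper, tolerance = 1e-9)
  }
  # the same median under opposite alternatives for the dual pairs
  expect_equal(estimation_fun(tr, 0.5, "two_trials_rule", "greater"),
               estimation_fun(tr, 0.5, "tippett", "less"))
  expect_equal(estimation_fun(tr, 0.5, "fisher", "greater"),
               estimation_fun(tr, 0.5, "pearson", "less"), tolerance = 1e-9)
})

test_that("medians converge to each method's asymptotic estimand as standard errors shrink", {
  th <- c(0.0, 1.0)
  s0 <- c(0.8, 0.8 / sqrt(2))  # variance ratio c = 2
  cc <- s0[1]^2 / s0[2]^2
  for (m in methods_all()) {
    target <- asymptotic_target(m, th[1], th[2], c = cc, alternative = "greater")
    err <- sapply(c(1, 0.1, 0.01), function(t) {
      tr <- make_trials(th, s0 * t)
      abs(estimation_fun(tr, 0.5, m, "greater") - target)
    })
    # monotone approach (MA/Edgington medians hit the weighted-average
    # estimand exactly at every scale, so allow zero error throughout)
    expect_true(all(diff(err) <= 1e-12))
    expect_lt(err[3], 0.05)                # close at t = 0.01
  }
  # Edgington's CI limits converge to the two true effects: the interval
  # never collapses under heterogeneity
  tr_small <- make_trials(th, s0 * 0.01)
  ci <- pf_confint(tr_small, 0.95, "edgington", "greater")
  expect_equal(ci$lower, min(th), tolerance = 0.05)
  expect_equal(ci$upper, max(th), tolerance = 0.05)
  expect_gt(ci$width, 0.9)
})

test_that("implicit weights decompose two-trial medians", {
  tr <- make_trials(c(-0.49, -0.18), c(0.3, 0.5))
  med_ma <- estimation_fun(tr, 0.5, "meta_analysis", "less")
  expect_equal(implicit_weight(tr, med_ma),
               tr$se[2]^2 / (tr$se[1]^2 + tr$se[2]^2))
  med_e <- estimation_fun(tr, 0.5, "edgington", "less")
  expect_equal(implicit_weight(tr, med_e), tr$se[2] / (tr$se[1] + tr$se[2]))
  # reconstruction: median = w * est1 + (1 - w) * est2
  w <- implicit_weight(tr, med_ma)
  expect_equal(w * tr$estimate[1] + (1 - w) * tr$estimate[2], med_ma)
  expect_error(implicit_weight(equal_trials(), 0.3), "undefined")
})

test_that("pf_inference assembles a tidy, printable result object", {
  tr <- respire14()
  fit <- pf_inference(tr, alternative = "less")
  tb <- tidy(fit)
  expect_s3_class(tb, "tbl_df")
  expect_equal(nrow(tb), 6 * 2)   # six methods x two default levels
  expect_named(tb, c("method", "estimate", "weight_trial1", "level",
                     "ci_lower", "ci_upper", "ci_width", "p_onesided"))
  expect_true(all(tb$ci_width > 0))
  g <- glance(fit)
  expect_equal(g$n_trials, 2L)
  expect_equal(g$alternative, "less")
  expect_output(print(fit), "two_trials_rule")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_error(pf_inference(tr, methods = character(0)), "at least one")
  expect_error(pf_inference(tr, levels = c(0.95, 1)), "inside")
})

test_that("inference generalises to four trials with the k-trial closed forms", {
  tr <- pf_fixture("respire_all4")
  expect_equal(nrow(tr), 4L)
  k <- 4
  # order-statistic closed forms vs numeric inversion at several a
  for (a in c(0.025, 0.5, 0.975)) {
    cf <- estimation_fun(tr, a, "two_trials_rule", "less", inversion = "closed")
    nm <- estimation_fun(tr, a, "two_trials_rule", "less", inversion = "numeric")
    expect_lt(abs(cf - nm), 1e-8 * max(tr$se))
    expect_equal(cf, max(tr$estimate - tr$se * qnorm(a^(1 / k))))
  }
  # the inverse-SE weighted mean is NOT Edgington's median beyond two trials
  med_e <- estimation_fun(tr, 0.5, "edgington", "less")
  wmean <- sum(tr$estimate / tr$se) / sum(1 / tr$se)
  expect_gt(abs(med_e - wmean), 1e-4)
  # but the median still lies between the extreme estimates
  expect_true(med_e > min(tr$estimate) && med_e < max(tr$estimate))
  fit <- pf_inference(tr, alternative = "less")
  expect_true(all(is.na(tidy(fit)$weight_trial1)))
})
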
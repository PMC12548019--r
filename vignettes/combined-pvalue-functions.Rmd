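---
title: "Combined p-value functions: compatible estimation and testing for pairs of pivotal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined p-value functions: compatible estimation and testing for pairs of pivotal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcomb)
```

## The problem

Drug regulators conventionally require two pivotal trials, each significant
on its own at one-sided $\alpha = 0.025$ — the "two-trials rule". The rule is
a test, not an estimator: it says nothing about what the combined effect is,
and the usual fallback, a fixed-effect meta-analysis, can produce a 95% CI
that excludes no-effect even when one of the trials clearly failed. The two
summaries then disagree, and the disagreement is structural, not a fluke of
one dataset.

pfcomb resolves this by treating both procedures — and four classical
alternatives — as *combined p-value functions*. Each trial $i$ reports an
effect estimate $\hat\theta_i$ on an additive scale (log rate ratio, log
hazard ratio, mean difference) with standard error $\sigma_i$, modelled as
$\hat\theta_i \mid \theta_i \sim N(\theta_i, \sigma_i^2)$. The one-sided
p-value function of trial $i$ is

$$p_i(\mu) = \begin{cases}
1 - \Phi\{(\hat\theta_i - \mu)/\sigma_i\} & \text{alternative "greater"}\\
\Phi\{(\hat\theta_i - \mu)/\sigma_i\} & \text{alternative "less"}
\end{cases}$$

and a combination function $g$ turns the $k$ per-trial functions into one
combined function $p(\mu) = g\{p_1(\mu), \dots, p_k(\mu)\}$. Because each
$g$ implemented here is valid (uniform under the null when its arguments
are) and strictly monotone in $\mu$, the single curve $p(\mu)$ carries the
complete inference:

* the **median estimate** is the $\mu$ where $p(\mu) = 1/2$;
* a $(1-\alpha)$ **confidence interval** collects the $\mu$ where
  $p(\mu) = \alpha/2$ and $1 - \alpha/2$;
* the **combined p-value** at a null value $\mu_0$ is $p(\mu_0)$, made
  two-sided by the centrality transform $2\min\{p, 1-p\}$.

These three are *compatible by construction*: the two-sided p-value at
$\mu_0$ is below $\alpha$ exactly when $\mu_0$ falls outside the
$(1-\alpha)$ CI, at every $\alpha$, and the median estimate lies inside
every CI. `test-acceptance.R` verifies this equivalence on a grid of
$\alpha$ values for all six methods.

## The six combiners

For two trials (generalisations to $k$ trials in parentheses):

| method | combined p-value function | estimand under heterogeneity |
|---|---|---|
| `two_trials_rule` | $\max\{p_1,p_2\}^2$ ($\max^k$; Wilkinson $r=k$) | less extreme effect (conservative) |
| `meta_analysis` | $1-\Phi(Z_{MA})$, Stouffer with weights $1/\sigma_i$ | inverse-variance weighted average |
| `tippett` | $1-(1-\min\{p_1,p_2\})^2$ (Wilkinson $r=1$) | more extreme effect (anti-conservative) |
| `fisher` | $P(\chi^2_{2k} > -2\sum\log p_i)$ | more extreme effect |
| `pearson` | $P(\chi^2_{2k} \le -2\sum\log(1-p_i))$ | less extreme effect |
| `edgington` | Irwin–Hall$_k$ CDF at $\sum p_i$ | inverse-SE weighted average |

The two-trials rule *is* the squared-maximum combiner: requiring both
one-sided p-values below $\alpha$ is the same as requiring
$\max\{p_1,p_2\}^2 \le \alpha^2$, which embeds the regulatory decision in a
valid p-value that can be inverted like any other. The general Wilkinson
$r$-of-$k$ combiner (binomial upper tail at the $r$-th smallest p-value) is
also provided, so intermediate decision rules for $k > 2$ trials ("at least
$r$ convincing trials") inherit the same machinery.

Two exact dualities tie the family together and are asserted at machine
precision in the tests: Tippett under "greater" equals one minus the
two-trials rule under "less" (and vice versa), and the same relation holds
between Fisher and Pearson.

## Closed forms and the restored quantile orders

Inverting $p(\mu) = a$ gives the estimation function $\hat\mu(a)$. Closed
forms exist for:

* two-trials rule: $\hat\mu(a) = \min_i\{\hat\theta_i + \sigma_i z_{a^{1/k}}\}$
  ("greater"; mirrored for "less"),
* Tippett: $\max_i\{\hat\theta_i - \sigma_i z_{(1-a)^{1/k}}\}$,
* meta-analysis: $\hat\theta_{MA} + \sigma_{MA} z_a$,
* Edgington's two-trial median:
  $(\hat\theta_1/\sigma_1 + \hat\theta_2/\sigma_2)/(1/\sigma_1 + 1/\sigma_2)$,
* the equal-results special cases ($\hat\theta_1=\hat\theta_2$,
  $\sigma_1=\sigma_2$) of Fisher
  ($z$ at $\exp\{-\chi^2_4(1-a)/4\}$), Pearson ($-z$ at
  $\exp\{-\chi^2_4(a)/4\}$), and Edgington ($z$ at $\sqrt{a/2}$ for
  $a \le 1/2$, $-z$ at $\sqrt{(1-a)/2}$ above).

The fractional quantile orders ($\sqrt{a}$, $\sqrt{a/2}$, …) are each fixed
by direct algebraic inversion of the combiner and validated against the
numeric anchors they imply — the $0.54\sigma$ two-trials-rule median shift
($z_{\sqrt{1/2}} = 0.5449$), the $-1$ and $2.24$ CI constants, the
$-0.17\sigma$ Fisher/Pearson shift, and Edgington's 12.2% CI narrowing —
and against blind root-finding (agreement to $10^{-8}\max\sigma_i$ across an
$a$-grid, a standing test).

Everything else is solved numerically. The combined p-value function is
strictly monotone, so the root is unique: the initial bracket is
$[\min_i\hat\theta_i - 10\max_i\sigma_i,\; \max_i\hat\theta_i +
10\max_i\sigma_i]$, doubled (up to 60 times) until it straddles the root,
then handed to Brent's method (`stats::uniroot`) with absolute tolerance
$10^{-12}\max(\sigma_i, 1)$ in $\mu$. An error is raised if the bracket
never closes — unreachable for finite inputs, but better loud than wrong.
Note that beyond two trials Edgington's median is *not* the inverse-SE
weighted mean (a comparison with the numeric root shows this analytically
tempting generalisation fails), so all $k>2$ Edgington/Fisher/Pearson
inversions are numeric.

Two numerical guards are worth stating. First, Fisher's and Pearson's
combiners take logs: p-values are clipped into $[10^{-300}, 1-2^{-53}]$
first, with a warning at the user-facing entry points (internal
root-finding visits the extreme tails routinely and stays silent). Second,
Edgington's null law is the Irwin–Hall distribution, computed by the exact
alternating sum with Kahan-compensated summation and the symmetry
$F(x) = 1 - F(k-x)$; cancellation grows with $k$, so evaluation is refused
for $k > 30$ rather than silently switching to a normal approximation — far
beyond the two-to-four-trial regime the package targets.

## What the different estimands mean

Under homogeneity ($\theta_1 = \theta_2$) every method consistently
estimates the common effect, with exact coverage and median-unbiasedness;
meta-analysis is the efficient choice. Under heterogeneity the methods
genuinely target different quantities, and the choice is a scientific one:

* **conservative** (two-trials rule, Pearson): the less extreme true
  effect — sensible when a treatment must prove itself in the weaker trial;
* **anti-conservative** (Tippett, Fisher): the more extreme effect — the
  maximum achievable benefit;
* **balanced** (meta-analysis, Edgington): weighted averages, with
  inverse-variance vs inverse-SE weights (Edgington leans more on the
  smaller trial).

Edgington's method has two practical distinctions, both tested: its
two-sided CIs are orientation invariant (identical for either alternative),
and under heterogeneity its CI limits converge to the two individual true
effects rather than to a point — it reacts to disagreement between trials by
refusing to narrow. The price is efficiency: its median SE
$\sqrt{2}/(1/\sigma_1 + 1/\sigma_2)$ is never below the meta-analytic SE
(equality exactly at $\sigma_1 = \sigma_2$), and exceeds even the smaller
trial SE once $\sigma_2/\sigma_1$ leaves $[\sqrt2 - 1, \sqrt2 + 1]$.

The order-statistic and product methods pay for their estimands with finite
sample bias when the trials agree: the two-trials-rule median sits
$0.54\sigma$ beyond the common estimate (mean bias $-0.019\sigma$ under
homogeneity, SE $\sigma\sqrt{1-1/\pi} \approx 0.83\sigma$), Fisher's and
Pearson's $0.17\sigma$ to either side. `expected_median_2tr()` gives the
exact expectation of the two-trials-rule median for equal standard errors
(the expectation of a minimum of two normals plus the $z_{\sqrt{1/2}}$
shift); for unequal standard errors the expectation depends on the unknown
true effects and the function deliberately refuses, pointing to the Monte
Carlo engine instead.

## The simulation engine and what it does (not) show

`simulate_oc()` draws $\hat\theta_i \sim N(\theta_i, \sigma_i^2)$ — exactly
the model the inference assumes — with a mandatory seed, and summarises
bias, empirical SE, median-unbiasedness, and CI coverage of each method's
median estimate, with Monte Carlo standard errors attached. Under
heterogeneity the summaries are computed against the method's *own*
asymptotic estimand (`asymptotic_target()`), because that is the quantity
the method estimates; coverage of someone else's estimand is not a defect.
Closed-form medians and CI limits are vectorised; Fisher/Pearson/Edgington
limits fall back to a vectorised bracketed bisection (90 iterations, the
same bracket-doubling rule as above). `simulate_grid()` expands a YAML/JSON
scenario grid into one tidy row per scenario and method, deriving one seed
per scenario from the base seed.

The default replication count is $10^5$, which makes a 3-Monte-Carlo-SE
tolerance sharp enough to detect the $-0.019\sigma$ bias anchor; the test
suite uses $10^4$–$10^5$ replicates depending on how expensive each
method's inversion is. Because the generator *is* the model, passing
simulations validate the internal consistency of the formulas — they say
nothing about non-normal likelihoods, exact small-count p-values,
within-trial dependence, or selection effects in which trials get run.
Published-table reproduction (the RESPIRE and ORBIT fixtures) is the only
contact with real data, and it inherits the rounding of the published
inputs: per-trial standard errors are reconstructed from the printed 95%
CIs, which reproduces the published estimates and CIs to 2 decimals, while
published combined p-values are reproduced to 5 decimals by combining the
printed per-trial p-values directly — two deliberately separated rounding
pathways.

## Defaults worth knowing

* `alternative` is always explicit — the fixtures' beneficial direction is
  "less" (negative log rate/hazard ratios).
* Confidence levels default to $\{0.95, 0.99875\}$: the conventional level
  plus the $(1 - 2\alpha^2)$ level that makes a two-sided CI decision agree
  with the two-trials rule at one-sided $\alpha = 0.025$ ("telescope"
  display).
* `null_value` defaults to 0, the no-effect point on every log scale.
* When several uncertainty summaries are supplied for one trial the
  precedence is se > CI > p (the SE is the model primitive; the others are
  rounded derivatives), warning when an unused summary disagrees by more
  than 1% relative.
* Curve export (`pf_curve()`) evaluates 1001 grid points centred at the
  meta-analytic median, spanning $\pm 5 \max_i \sigma_i$.

## Limitations

Summary-level normal inference only: no patient-level data, no count or
survival likelihoods, no exact or mid-p p-value functions, no
random-effects heterogeneity model (with two trials the heterogeneity
variance is essentially unidentifiable), no dependence between trials, and
no weighted variants of the order-statistic/product combiners. One-sided
building blocks are deliberate: combined functions of two-sided p-values
can be non-monotone and yield disjoint confidence regions.

## A worked example

```{r, eval = FALSE}
fit <- pf_inference(pf_fixture("respire_14d"), alternative = "less")
fit
tidy(fit)
autoplot(fit)
autoplot(pf_curve(pf_fixture("respire_14d"), alternative = "less"))
```
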
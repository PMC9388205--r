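---
title: "Interrupted time-series analysis of weekly utilization counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted time-series analysis of weekly utilization counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countits)
```

## The design

`countits` implements a quasi-experimental interrupted time-series (ITS)
analysis for weekly event-count surveillance series — the archetypal
application being emergency-department (ED) visit counts around an abrupt
external shock such as a pandemic stay-at-home order. The design compares a
dependent weekly count series against its own modeled pre-event expectation,
with a contemporaneous *control series* absorbing whatever the two
populations share: seasonality, secular trend, changes in catchment
population, and system-wide shocks (such as the pandemic-wide collapse in
care-seeking). What remains attributable to the intervention is the
*differential* departure of the dependent group.

The model is a transfer-function regression with ARMA-structured errors:

$$y_t = \alpha + \beta x_t + \omega I_t + N_t, \qquad
  \Big(1 - \sum_{j \in L_{\mathrm{AR}}} \phi_j B^j\Big)(1-B)^d N_t =
  \Big(1 + \sum_{k \in L_{\mathrm{MA}}} \theta_k B^k\Big)\varepsilon_t,
  \quad \varepsilon_t \sim \mathcal N(0, \sigma^2),$$

where $y_t$ is the dependent weekly count, $x_t$ the control count in the
same week (a synchronous, order-0 input), $I_t$ a coded intervention
indicator, and $B$ the backshift operator. The noise model is *subset* ARMA:
only the configured lags carry free coefficients and all intermediate lags
are pinned at zero. The default is AR at lags 1 and 5 with $d = 0$ — weekly
"memory" of last week and of five weeks back (a plausible calendar-month
echo in weekly data), with no differencing because the control regressor
already absorbs shared trend.

Weeks are 7-day bins anchored on a Friday: week $w$ covers the half-open
interval $[\mathrm{anchor} + 7(w-1), \mathrm{anchor} + 7w)$, so a Friday
opens each week and the following Thursday closes it, and week indices are
1-based. This convention lets an intervention that begins on a Friday (as a
national emergency declaration did) open its own exposed week exactly.

## Estimation

The likelihood is the exact Gaussian likelihood, evaluated by a Kalman
filter on the Harvey state-space form of the ARMA noise (`method = "exact"`).
Regression coefficients are profiled out by generalized least squares on the
whitened design at each candidate ARMA point, and the innovation variance is
concentrated out analytically, so numerical optimization runs only over the
free ARMA coefficients (Nelder-Mead, refined by BFGS when more than one
coefficient is free; convergence tolerance $10^{-10}$ on the
log-likelihood; regression starts are the OLS solution and ARMA starts are
zero). Standard errors come from the observed information — the numerical
Hessian of the profile log-likelihood at the optimum — with closed-form
information in the pure-regression case; intervals are
$\hat\vartheta \pm 1.96\,\mathrm{SE}$ and tests are two-tailed $z$ tests.

A conditional-sum-of-squares likelihood (`method = "css"`), conditioning on
the first max-lag observations, is available as the standard faster
alternative. On the default synthetic fixture the two agree to two decimal
places on the control and AR coefficients; coefficients on the count scale
(intercept, intervention), whose standard errors are in the tens of counts,
agree to well within a few percent of one standard error — the difference
is the five conditioning observations. With no ARMA terms and $d = 0$ both
methods reduce *exactly* to ordinary least squares, which the test suite
asserts at $10^{-6}$.

Non-stationary AR candidates are rejected inside the optimizer (roots of
$\phi(B)$ must lie outside the unit circle), and an optimum with roots
within 0.001 of the circle raises a warning flag on the result. Degenerate
designs (collinear regressors) error out at the GLS step.

## The five analysis steps

`run_pipeline()` executes the canonical Box-Jenkins sequence:

1. regress the dependent series on the control series alone;
2. identify residual autocorrelation — `identify_noise()` flags the lags
   whose partial autocorrelation exceeds the Bartlett
   $\pm 1.96/\sqrt{T}$ band and suggests them as a subset-AR set. The
   suggestion is advisory: the pipeline adopts it only when it matches the
   configured noise model and otherwise logs the discrepancy and uses the
   configuration, because Box-Jenkins identification is analyst-guided
   (at $T = 142$ a 5%-level band falsely flags about half a lag per clean
   series, so a mechanical rule would over-fit);
3. re-estimate with the intervention indicator added — a *pulse* coded 1
   over a fixed window of exposed weeks, or a *step* coded 1 from the onset
   through the end of the series (the sustained-switch sensitivity);
4. check the residuals with the Ljung-Box portmanteau test (12 lags,
   degrees of freedom reduced by the number of fitted ARMA parameters),
   surfacing failure as a warning rather than an error;
5. detect and jointly adjust for outliers (below), when an outlier
   configuration is present.

Reported residuals are the innovation (one-step whitened) residuals with the
first `burn_in_weeks` (default 6) dropped, mirroring the usual loss of the
initial weeks to lagged-model conditioning; the burn-in is configurable
rather than tied to the max AR lag.

## Outlier detection and adjustment

Three canonical aberration types are scanned, each a deterministic
regressor: an additive outlier (AO, unit pulse), a level shift (LS, unit
step), and a temporary change (TC, pulse decaying geometrically at rate
$\delta$, default 0.7 — the conventional value in the outlier-detection
literature; the innovational-outlier type is deliberately out of scope).
The screening statistic for a candidate (type, week) is the $t$ statistic
of that regressor's coefficient estimated on the current structural
residuals after whitening both through the fitted ARMA polynomial, with all
other parameters held at their current estimates; under a white-noise model
the AO statistic at week $w$ reduces to the standardized residual at $w$.
The innovation scale in the denominator carries the standard small-sample
degrees-of-freedom correction ($\hat\sigma^2_{\mathrm{ML}}\, n/(n-k)$),
since the ML scale is biased low by the fitted parameters and would inflate
every statistic. A robust MAD-based scale is available
(`robust_sigma = TRUE`) as a guard against inflation by very large additive
outliers. Candidates collinear with the existing design (a level shift at
week 1 versus the intercept, or a duplicate of an accepted regressor) are
skipped.

Detection is greedy: the globally largest screening $|t|$ across all types
and weeks is accepted if it exceeds the threshold (default 3.5, a
per-candidate two-sided tail of about $4.7\times10^{-4}$ chosen to control
the family-wise rate over $\sim 3T$ candidates), the model is re-estimated
*jointly* — all regression and ARMA parameters free, warm-started at the
current optimum so the maximized log-likelihood never decreases — and the
scan repeats under the updated model. Ties break deterministically by
earlier week, then LS > TC > AO.

One subtlety drives the pass structure: an outlier that has not yet been
adjusted for biases the subset-AR estimates toward spurious persistence
(a level shift looks like a near-unit root), which both *deflates* its own
screening statistic (masking) and *smears* it across neighbouring weeks
(poor localization). The procedure therefore first runs a bootstrap pass at
a provisional threshold (default 3.0) whose only purpose is to produce
de-biased ARMA and scale estimates, then re-runs detection from scratch at
the full threshold with those refined estimates driving the screening,
repeating until the detected set stabilizes (at most three refinement
passes). Only final-pass detections are reported. Accepted outliers are
never deleted; whether the original methodology's software rescans or
deletes earlier candidates is not knowable, so this package documents its
own rule. Outliers detected inside the intervention window are reported
with a flag, because they compete with $\omega$ for the same variation —
indeed a level shift starting at the window's first week is *exactly*
collinear with the pulse plus a level shift at the week after the window
ends, so onset weeks adjacent to the window are only weakly identified when
the pulse coefficient is free. The package's recovery experiments for the
outlier machinery therefore inject events into series without a concurrent
intervention effect; with the pulse present, the correct behaviour to
verify is interval shrinkage and magnitude correction of $\omega$, not
exact-week placement at the boundary.

## Effect translation

A fitted intervention coefficient $\omega$ (counts per week) is translated
two ways: events avoided over the exposed window,
$|\omega| \times \mathrm{duration}$, and percent below expected weekly
levels, $100\,|\omega| / \bar y$. Both an 8- and a 9-week duration are
printed with labels, because the two conventions (the coded window length
versus the narrower window used in some summaries) differ in the source
tradition and the package surfaces both rather than silently picking one.
`magnitude_change()` reports how much outlier adjustment moved the point
estimate, as a percent of the initial magnitude.

## The synthetic generator

Because encounter-level hospital records are confidential, the package
ships a calibrated generator that emulates the study conditions and records
full ground truth. The control series is
$\mathrm{round}(\max(0, \mathrm{level}_t + \mathrm{seasonal}_t + u_t))$
with iid Gaussian $u_t$; its level drops by a configurable fraction
(default 0.35, loosely motivated by the reported ~40% pandemic-era declines
in ED visits; a free parameter, not an estimate) from the intervention
start onward, emulating the system-wide collapse that the control series
exists to absorb. The dependent series is
$\mathrm{round}(\max(0, \alpha + \beta x_t + \omega I_t +
\textstyle\sum \mathrm{outliers}_t + N_t))$ with subset-AR noise $N_t$,
the intercept chosen so the pre-intervention expectation hits the
configured mean. Defaults are the study conditions: $T = 142$ Friday-anchored
weeks from 2018-01-05; means 544.25 and 571.08 with SDs 107.19 and 91.14;
$\beta = 0.97$; $\phi_1 = 0.09$, $\phi_5 = 0.06$; a 9-week pulse from
2020-03-13 with $\omega = -54.33$. The innovation SD defaults to 60 so that
the dependent SD *emerges* near its target
($\beta^2\,\mathrm{SD}_x^2 + \sigma^2 \approx 107^2$); it is checked, not
enforced. Noise is Gaussian-rounded-to-integer rather than Poisson or
negative-binomial because the inference model is Gaussian and the recovery
experiments should test the estimator under its own assumptions;
count-model misspecification is a separate robustness question. Within-week
visit dates are uniform (the within-week distribution is otherwise
unconstrained), and a configurable fraction of decoy records — minors,
non-Latino patients, other payers, inpatient dispositions — exercises the
inclusion filters; decoys are labeled in the truth record.

What the generator deliberately does not emulate: diagnosis-category
structure, repeat visits by the same patient, over-dispersed counts, or
serially correlated noise in the control series. Passing recovery tests
therefore demonstrate that the machinery is correct *under the stated
model*, not that the model is adequate for any particular hospital's data.

## Numerical and design choices

* All randomness flows from one seed; each generator stage draws from a
  named substream derived from it, so outputs are byte-identical across
  runs and platforms with the same R version.
* Rounding to integer counts biases each week by at most 0.5 and is
  ignored by the fitter (it is well below the innovation SD).
* Monte-Carlo problem sizes in the test suite — 200 replicates for
  coverage, 50 seeds for the outlier operating characteristics, 100
  replicates in the acceptance script — were chosen so that binomial
  Monte-Carlo error is small relative to the margins being asserted while a
  full run stays comfortable on a single CPU.
* Cohort age bands are half-open ($[45,55)$, $[55,65)$, printed with the
  conventional labels), so the bands partition ages without overlap.
* An intercept is included throughout, because weekly counts sit far from
  zero; with the control regressor present the intercept absorbs the level
  offset between the two payer groups.
* Unknown-sex records are retained; unknown-ethnicity records are excluded
  by the default filter, since the cohort is defined by self-reported
  ethnicity. Both choices are configuration, not hard-coded.

## Known limitations

* The Gaussian likelihood treats counts as continuous; for very low-count
  series (weekly means near zero) a count likelihood would be preferable.
* Level shifts with onset adjacent to a free intervention-pulse window are
  only weakly identified (see above); the reported onset week there should
  be read with the window flag, not as a sharp calendar claim.
* The step-switch sensitivity changes the estimand (sustained versus
  windowed effect); its coefficient is not comparable to the pulse
  coefficient without the effect-translation layer.
* No seasonal ARMA terms are offered; strong annual seasonality must be
  absorbed by the control series or handled upstream.
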
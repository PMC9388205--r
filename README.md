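# countits

Interrupted time-series analysis of weekly health-care utilization counts.

## The problem

When an abrupt external shock — a pandemic emergency declaration, a policy
change, a stay-at-home order — hits a health-care system, the question
"did utilization in *this* group fall more than expected?" cannot be
answered by comparing raw counts to the same weeks a year earlier: weekly
visit counts carry seasonality, trend, and autocorrelated "memory" that
make the expected value of the series something other than its mean.
`countits` implements the quasi-experimental design used in ED-surveillance
research for exactly this situation:

* **weekly binning** of encounter-level records into Friday-anchored 7-day
  periods (week *w* covers `[anchor + 7(w−1), anchor + 7w)`), so an
  intervention that begins on a Friday opens its own exposed week;
* a **transfer-function model**: the dependent weekly count is regressed on
  a *contemporaneous control series* (a comparison population that absorbs
  shared seasonality, trend, and system-wide shocks) and on a coded
  intervention indicator, with subset-AR ARMA errors removing what
  autocorrelation remains,

  y_t = α + β·x_t + ω·I_t + N_t,   (1 − Σ_j φ_j B^j)(1−B)^d N_t = (1 + Σ_k θ_k B^k)ε_t,  ε_t ~ N(0, σ²);

* **exact Gaussian maximum likelihood** (Kalman filter; GLS-profiled
  regression coefficients; observed-information standard errors; two-tailed
  z tests), with a conditional-sum-of-squares alternative;
* **Box-Jenkins diagnostics** — ACF/PACF with Bartlett bands for noise
  identification, Ljung-Box portmanteau residual checks;
* **iterative outlier detection** over additive outliers (AO), temporary
  changes (TC) and level shifts (LS) at |t| > 3.5, with the whole model
  jointly re-estimated as each outlier is adjusted for;
* **effect translation** of the fitted ω into "visits avoided" and
  "percent below expected weekly levels";
* a calibrated **synthetic-data generator** (weekly series and
  encounter-level records with decoys, with a full ground-truth record),
  since real hospital encounter data are confidential;
* **sensitivity variants**: include inpatient dispositions, a sustained
  step ("switch") intervention, and an alternate dependent/control pairing.

The intended users are epidemiologists and health-services researchers
analyzing utilization surveillance counts around a known interruption.

## Worked example

Generate a synthetic study — 142 Friday-anchored weeks from 2018-01-05, a
control series with a sustained pandemic-era drop, a 9-week intervention
pulse with true effect −54.33 visits/week, plus an injected temporary
change at week 81 and a level shift of −300 at week 124 — and run the full
five-step analysis:

```r
library(countits)

cfg <- synthetic_config(injected_outliers = list(
  list(type = "TC", week = 81,  magnitude = 240),
  list(type = "LS", week = 124, magnitude = -300)))
ge <- gen_encounter_records(cfg, seed = 7)
report <- run_pipeline(ge$records, pipeline_config())
print(report)
```

```
Initial model:
Transfer model fit (exact likelihood), T = 142, loglik = -825.295
             estimate      se  ci_lower ci_upper       z      p
(Intercept)  -91.8240 47.8513 -185.6126   1.9645 -1.9189 0.0550
control        1.0328  0.0604    0.9144   1.1511 17.0967 0.0000
intervention  34.2750 51.1448  -65.9688 134.5187  0.6702 0.5028
AR(1)          0.6033  0.0758    0.4547   0.7519  7.9560 0.0000
AR(5)          0.2186  0.0786    0.0645   0.3727  2.7797 0.0054

Outlier-adjusted model:
Transfer model fit (exact likelihood), T = 142, loglik = -789.983
              estimate      se  ci_lower  ci_upper        z      p
(Intercept)   -11.7817 31.9258  -74.3562   50.7928  -0.3690 0.7121
control         0.9725  0.0554    0.8640    1.0810  17.5681 0.0000
intervention  -70.8204 28.0393 -125.7773  -15.8634  -2.5258 0.0115
LS_124       -295.4666 20.0808 -334.8249 -256.1083 -14.7139 0.0000
TC_81         250.3180 51.2123  149.9418  350.6941   4.8878 0.0000
AR(1)           0.1593  0.0840   -0.0054    0.3240   1.8963 0.0579
AR(5)          -0.0481  0.0855   -0.2156    0.1194  -0.5628 0.5736

Detected outliers:
  iteration type week magnitude     t_stat
1         1   LS  124 -295.4666 -14.383197
2         2   TC   81  250.3180   4.152474

Ljung-Box (12 lags), initial model: Q = 31.83, p = 0.0004
Ljung-Box (12 lags), adjusted model: Q = 10.01, p = 0.4394
```

The example shows the machinery doing its job. In the initial model the
unadjusted level shift masquerades as AR persistence (AR(1) ≈ 0.60), the
intervention coefficient is badly biased (+34, n.s.), and the residuals
fail the Ljung-Box check. After the scan detects the level shift at week
124 and the temporary change at week 81 and re-estimates everything
jointly, the AR coefficients fall back toward their generating values
(0.09/0.06), the intervention estimate is negative with its 95% interval
(−125.8, −15.9) covering the generating −54.33, and the residuals are
clean (p = 0.44). The effect-translation block converts the final ω into
visits avoided over the exposed window and percent below expected weekly
levels, under both the 8- and 9-week duration conventions.

`plot(report)` draws the observed and residual series with the
intervention window marked; `write_report_json()`, `write_outliers_csv()`
and `write_series_pair()` export the artifacts. A thin CLI with
`simulate` / `fit` / `scan` / `describe` / `report` subcommands lives at
`inst/cli/countits.R`.

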
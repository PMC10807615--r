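# mrkit

Two-sample Mendelian randomisation (MR) for GWAS summary statistics, built
for analyses of the kind run when asking whether a behavioural exposure
(e.g. hours of leisure television watching or computer use, per 1 SD)
causally affects disease risk (e.g. breast, colorectal or prostate cancer)
using only published per-SNP association tables from non-overlapping
studies.

It is aimed at genetic epidemiologists who have instrument-grade summary
statistics in hand and want the full analysis surface — harmonisation,
estimation, sensitivity analysis, confounder adjustment, subgroup
heterogeneity, power — as composable, pipe-friendly R functions returning
tibbles, with broom-style `tidy()`/`glance()` methods and ggplot2
diagnostics.

## What it computes

For a harmonised set of $k$ instruments with SNP-exposure effects
$\hat\gamma_j$ (SE $\sigma_{Xj}$) and SNP-outcome effects $\hat\Gamma_j$
(SE $\sigma_{Yj}$):

* **Wald ratios** $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ and the
  **IVW** estimate $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
  $w_j = 1/\mathrm{se}(\hat\theta_j)^2$, with fixed or multiplicative
  random-effects SEs and **Cochran's Q / I²** heterogeneity;
* **MR-Egger** regression (intercept = directional pleiotropy test, slope =
  causal estimate under InSIDE);
* the **weighted median** with parametric-bootstrap SE (valid with up to
  50% invalid weight);
* **MR-PRESSO** (simulation-based global heterogeneity, per-SNP outlier and
  distortion tests, with outlier-corrected re-estimation);
* **multivariable MR** with conditional F-statistics, for adjusting a
  sedentary-behaviour-type exposure for BMI, education, smoking or alcohol;
* fixed-effect **subgroup meta-analysis** (cancer subtypes/subsites/sexes),
  **bidirectional MR**, and a priori **power / minimum-detectable-OR**
  for binary outcomes:
  power = Φ(|ln OR|·√(N·R²·K(1−K)) − z₀.₉₇₅).

A summary-level simulator with known causal structure
(`simulate_pair()`, `simulate_mv_pair()`, `inject_outliers()`) makes every
estimator and pipeline path testable without downloading any GWAS.

## Worked example

Simulate a colorectal-cancer-scale analysis (200 instruments explaining 2%
of exposure variance; outcome GWAS of 98,715 with 52,775 cases) with a true
OR per 1-SD of 1.32, then run the full sensitivity suite:

```r
library(mrkit)

sim <- simulate_pair(J = 200, theta = log(1.32), h2x = 0.02,
                     n_out = 98715, case_fraction = 52775 / 98715,
                     outcome_type = "binary", seed = 42,
                     exposure_label = "television watching",
                     outcome_label = "colorectal cancer")

h <- harmonise(sim$exposure, sim$outcome)
mr_ivw(h, model = "auto")
#> <mr_estimate> method: ivw_fixed, k = 200
#>   beta = 0.2924 (se 0.0454), 95% CI [0.2035, 0.3813], p = 1.15e-10
#>   OR per 1-SD = 1.34 [1.23, 1.46]
#>   Q = 187.48 (df 199, p = 0.711), I2 = 0.0%

mr_suite(h, n_boot = 200, presso_nsim = 1000, seed = 7) |>
  dplyr::select(method, or, or_low, or_high, pval, k)
#> # A tibble: 4 × 6
#>   method              or or_low or_high     pval     k
#>   <chr>            <dbl>  <dbl>   <dbl>    <dbl> <int>
#> 1 ivw_fixed         1.34   1.23    1.46 1.15e-10   200
#> 2 egger_slope       1.42   1.23    1.65 3.61e- 6   200
#> 3 weighted_median   1.40   1.21    1.61 3.29e- 6   200
#> 4 presso_corrected  1.34   1.23    1.46 1.15e-10   200
```

The IVW odds ratio per 1-SD recovers the simulated 1.32 (up to sampling
noise and the small first-order weak-instrument dilution); the Egger
intercept p-value (0.33 here, via `tidy(mr_egger(h))`) shows no directional
pleiotropy, as simulated; the MR-PRESSO row equals the raw IVW because no
outliers were injected. Instrument diagnostics:

```r
f_statistics(h)$mean_f      #> 40.4   (mean per-SNP F; > 10 = strong)
variance_explained(h)       #> 0.0198 (estimated instrument R^2)
min_detectable_or(98715, 52775, r2 = 0.02)$or   #> 1.14
```

so at this sample size only ORs of 1.14 or beyond per 1-SD are detectable
with 80% power — the simulated 1.32 comfortably is.

Multi-outcome grids, multivariable adjustment and bidirectional analyses
run from one config (`run_univariable()`, `run_mvmr()`,
`run_bidirectional()`, serialised by `write_results()`); diagnostics come
from `plot_mr_scatter()`, `plot_mr_funnel()` and
`plot_mvmr_attenuation()`. A thin command-line wrapper with `run`,
`simulate`, `power` and `bidirectional` subcommands ships in
`inst/cli/mr.R`.

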
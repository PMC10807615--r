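---
title: "Methods: two-sample Mendelian randomisation with mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ from GWAS summary statistics measured in two
non-overlapping samples. For SNP $j$, let $\hat\gamma_j$ (SE
$\sigma_{Xj}$) be its association with the exposure, standardised so effects
are per 1 SD of $X$, and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its association
with the outcome (log-odds for binary outcomes). If SNP $j$ is a valid
instrument — associated with $X$, independent of confounders, and affecting
$Y$ only through $X$ — then $\Gamma_j = \theta\,\gamma_j$ and the Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal effect
$\theta$, with first-order standard error
$\sigma_{Yj}/|\hat\gamma_j|$. All estimators in the package operate on a
*harmonised set*: per-SNP $(\hat\gamma_j, \sigma_{Xj}, \hat\Gamma_j,
\sigma_{Yj})$ aligned to a common effect allele.

### Estimators

* **IVW.** Inverse-variance weighting of the Wald ratios with
  $w_j = 1/\mathrm{se}(\hat\theta_j)^2$, algebraically identical to weighted
  least squares of $\hat\Gamma$ on $\hat\gamma$ through the origin with
  weights $1/\sigma_{Yj}^2$. The fixed-effect SE is $(\sum w_j)^{-1/2}$;
  the multiplicative random-effects model scales it by
  $\max(1, \sqrt{Q/(k-1)})$, where $Q$ is Cochran's statistic. `model =
  "auto"` uses the fixed model unless the $Q$ p-value is at or below 0.05,
  the conventional heterogeneity trigger. Second-order terms of the ratio
  variance (the exposure-side measurement error) are ignored in the
  weights, the standard first-order convention.
* **Cochran's $Q$ and $I^2$.** $Q = \sum_j w_j(\hat\theta_j -
  \hat\theta)^2$ on $\chi^2_{k-1}$;
  $I^2 = \max(0, (Q - \mathrm{df})/Q)\times 100$.
* **MR-Egger.** Weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with*
  an intercept, after orienting every SNP so $\hat\gamma_j \ge 0$. The
  intercept is the average directional pleiotropic effect; the slope is a
  consistent causal estimate when instrument strength is independent of the
  direct effects (InSIDE). Both SEs carry a multiplicative overdispersion
  factor $\max(1, \sqrt{\mathrm{RSS}_w/(k-2)})$. We refer the intercept to
  $t_{k-2}$ and the slope to the normal; the reference distributions are a
  documented convention, as the literature uses both.
* **Weighted median.** The ratio at the 50th percentile of the
  weight-ordered Wald ratios, interpolated linearly under the midpoint
  cumulative-weight convention $s_j' = S_j - w_j/2$. It is consistent while
  valid instruments carry more than half the total weight. Its SE is a
  parametric bootstrap (default 1000 resamples, mandatory seed): each
  resample redraws every SNP's two betas from normals centred on the
  observed values.
* **MR-PRESSO.** Leave-one-out residuals $r_j = \hat\Gamma_j -
  \hat\theta_{(-j)}\hat\gamma_j$, weighted by $1/\sigma_{Yj}^2$, give an
  observed residual sum of squares. Its null distribution is simulated
  (default 1000 replicates) by redrawing exposure betas about their
  observed values and outcome betas about the leave-one-out predictions.
  Empirical p-values use the add-one estimator $(1 + \#\{\cdot\})/(n_{sim} +
  1)$ so they are never zero and have resolution $1/(n_{sim}+1)$; per-SNP
  outlier p-values are Bonferroni-adjusted by $k$. With default settings
  ($k \le 50$, significance 0.05) flagging a SNP requires its residual to
  exceed all 1000 simulated ones, so `n_sim` below ~1000 makes flagging
  impossible at $k = 50$. When outliers are flagged the IVW estimate is
  recomputed without them, and a distortion test compares the
  raw-minus-corrected displacement with displacements from removing random
  subsets of the same size; the distortion p is reported but never used for
  gating.

### Multivariable MR

With $L$ exposures, the per-SNP exposure betas form a $k \times L$ design
and the direct effects are estimated by weighted least squares of
$\hat\Gamma$ on all columns jointly, no intercept, weights
$1/\sigma_{Yj}^2$ — outcome precision only, the standard MV-IVW weighting.
Residual heterogeneity $Q_A$ (df $k - L$) triggers the same multiplicative
SE scaling. A column of exactly zero betas would make the normal equations
singular; it is excluded from the design (its coefficient is undefined) so
the remaining coefficients are exactly what they would be without it.

Instrument strength *conditional on the other exposures* is summarised by
regressing each exposure's beta column on the others (weights
$1/\sigma^2$ of that exposure) and dividing the weighted residual sum of
squares by $k - L + 1$. The df convention varies across the literature; the
divisor is stated in every output. Values above 10 are the conventional
adequacy bar. Strongly correlated exposure effects (genetically correlated
traits) drive the conditional F toward zero even when each exposure's
unconditional mean F is large: with effect correlation $\rho$ the
conditional F scales roughly as $(1-\rho^2)$ times the unconditional F plus
noise terms. Because the joint instrument panel is *selected* (only
genome-wide significant SNPs enter), its mean F is high (~40 under the
default generator), and an instrument-level effect correlation around 0.9
is needed before the conditional F drops below 10 — consistent with the
observation that traits with genome-wide correlation near 0.8 can still be
indistinguishable at their instruments, where shared pathways concentrate.

The joint instrument set is the union of per-exposure genome-wide
significant SNPs ($p < 5\times10^{-8}$ by default), each required to be
present in every exposure table and the outcome, cross-clumped greedily at
$r^2 < 0.001$ by the best p-value across exposures, and harmonised to the
first exposure's orientation.

## Harmonisation rules

Alleles are aligned to the exposure's effect allele: identical pairs are
kept, swapped pairs flip the outcome beta, and strand complements
(A$\leftrightarrow$T, C$\leftrightarrow$G, applied per base) are tried
before a pair is declared mismatched, because consortium files mix strands.
Palindromic SNPs (A/T, C/G) carry no strand information in their alleles;
they are kept only when both allele frequencies are outside $0.5 \pm 0.08$
and fall on the same side of 0.5 after label alignment, otherwise dropped
as ambiguous — the conservative default of standard harmonisation practice.
A frequency missing on either side drops the SNP. Duplicate outcome records
resolve to the smallest SE (a deterministic tie-break); every drop is
logged with its reason, and retained plus dropped SNPs always account for
the full submitted instrument list.

## Instrument selection

Clumping is greedy: rank SNPs passing the significance threshold by
ascending p (rsid breaks ties, making the result order-invariant), accept
the best, discard correlated neighbours ($r^2 \ge$ 0.005 by default within
5 Mb when positions are available), repeat. LD is supplied as an explicit
$r^2$ matrix; without one the table is assumed pre-clumped (flagged in the
output), which matches the common situation where instruments arrive
already pruned from the source GWAS. Per-SNP strength is
$F_j = (\hat\gamma_j/\sigma_{Xj})^2$ and the variance explained by the
panel is $R^2 = \sum_j 2 f_j (1-f_j) \hat\gamma_j^2$ for a standardised
exposure.

## Power

For a binary outcome with case fraction $K$ and instruments explaining
$R^2$ of the exposure variance, the normal-approximation power at odds
ratio $\mathrm{OR}$ per 1 SD is

$$\mathrm{power} = \Phi\!\left(|\ln \mathrm{OR}|\sqrt{N R^2 K(1-K)} -
z_{1-\alpha/2}\right),$$

and the minimum detectable OR is found by a 0.01-step grid search upward
from 1.00 (the closed form
$\exp[(z_{1-\alpha/2}+z_{\mathrm{power}})/\sqrt{N R^2 K(1-K)}]$ is reported
alongside and always agrees to within one grid step). With $R^2 = 0.02$,
$\alpha = 0.05$ and 80% target power this gives 1.09 for a breast-cancer
scale outcome GWAS (247,173 with 133,384 cases) and 1.14 at colorectal
scale (98,715 with 52,775 cases). At prostate scale (140,254 with 79,148
cases) the same convention gives 1.12; published analyses using online
calculators sometimes print 1.11 for this design, a discrepancy that
cannot be resolved without the exact $R^2$ they entered, so the package
documents rather than matches it.

## The synthetic-data generator

`simulate_pair()` emulates the summary-level structure the estimators
assume, not individual genotypes:

* allele frequencies $f_j \sim U(0.05, 0.5)$; independent instruments
  (real instruments are LD-clumped, so independence is the post-selection
  state);
* SNP-exposure effects drawn normal and rescaled so
  $\sum 2f(1-f)\gamma^2$ equals the requested $h^2_X$ *exactly* (default
  0.02, the scale of a ~200-SNP television-watching instrument; 0.005
  matches a ~50-SNP computer-use instrument). Effect alleles are oriented
  to be exposure-increasing, the convention under which a *directional*
  pleiotropy offset actually biases ratio-based estimators; with
  sign-symmetric effects the offset cancels in expectation;
* direct effects $\alpha_j = \mathrm{Bern}(\pi)(\mu_\alpha +
  \sigma_\alpha Z_j) + \psi\gamma_j$, where $\psi \ne 0$ breaks InSIDE;
* standard errors $1/\sqrt{2f(1-f)n}$ (continuous) or
  $1/\sqrt{2f(1-f)nK(1-K)}$ (binary, log-odds scale — a documented
  approximation consistent with the power formula, in place of liability
  simulation);
* observed betas drawn independently in the two samples (no sample
  overlap); seeds are mandatory and embedded in the truth record.

Defaults mirror the study conditions of a large sedentary-behaviour
exposure GWAS ($n$ = 408,815) read against cancer consortium outcomes. The
generator does not emulate residual LD, sample overlap, population
stratification, or non-collapsibility of the odds ratio, so calibration
results here speak to estimator correctness, not to immunity from those
real-data complications. `simulate_mv_pair()` adds a second exposure whose
effects are bivariate normal with correlation `rg`; these stay *signed*,
because the joint estimator is orientation-free and flipping would distort
the correlation.

## Numerical and design choices

* Problem sizes used by the shipped statistical checks: 1000 random
  instances for the estimator-vs-WLS oracle equivalence (tolerance 1e-10
  relative); 1000 null replicates at $J = 200$ for 5%-level calibration of
  IVW, the Egger intercept and $Q$ (acceptance band: three binomial SDs);
  500 replicates for effect recovery at colorectal scale; 100 replicates
  for the outlier spike test at $k = 50$ with `n_sim = 1000`.
* Clean recovery of $\theta = \ln 1.32$ allows, besides 3 Monte-Carlo SEs,
  the first-order regression-dilution term $\theta J/(n_X h^2_X)$
  (~2.4% of the effect at the defaults): sampling error in
  $\hat\gamma$ attenuates ratio estimators by $\approx 1/(1 + 1/\bar F)$,
  a property of the method, not a bug.
* The weighted median's robustness claim is checked at secondary-trait
  GWAS precision (continuous outcome, $n = 1.1$M). Under one-sided 30%
  contamination the weighted median retains a finite-sample quantile-shift
  bias of roughly $z_{0.71}$ times the effective weighted ratio SD; at
  cancer-consortium precision that floor (~0.2 on the log-odds scale) is
  irreducible for *any* median-type estimator, while at $n = 1.1$M it is
  an order of magnitude below the IVW's contamination bias. The check
  therefore asserts the comparative property: the weighted median stays
  within twice its own replicate SD of the truth while IVW is at least
  three times further away.
* Ties in clump ranking break by rsid; weighted-median interpolation uses
  `approx(..., rule = 2)` so a median outside the midpoint range clamps to
  the extreme ratio; `n_boot = 0` skips the bootstrap and returns the
  point estimate.
* No multiple-testing adjustment is applied across outcomes in pipeline
  reports; p-values are reported as computed.
* Sex-specific outcomes are analysed with sex-combined exposure
  instruments, mirrored from the design this package operationalises, and
  flagged in output metadata only by the outcome label.

## Limitations

Degenerate inputs are refused loudly: zero exposure betas (undefined
ratios), fewer than 3 instruments for Egger/weighted median, fewer than 4
for MR-PRESSO, under-identified multivariable sets, collinear designs. LD
matrices are taken at face value (no PSD projection). The package performs
no proxy-SNP lookup, liftover, Steiger filtering or external-database
queries; instruments and LD arrive as data.
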
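---
title: "Methods: educational gradients in regional cohort fertility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: educational gradients in regional cohort fertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regfert)
```

## The estimand and the data structure

The cohort fertility rate (CFR) of a group of women is the mean number of
children ever born per woman, measured at the end of the reproductive
lifespan. This package studies how the *educational gradient* in the CFR —
the difference in CFR between two educational attainment groups (low,
medium, high) — varies across sub-national regions and with regional
economic development, measured as GDP per capita.

All estimation works from cell counts: for each (country, region,
education) cell, the number of women with known parity $N$ and their total
number of children $B$. These are sufficient for everything downstream.
Woman-level microdata enter only through `aggregate_microdata()`; women who
report unknown parity are carried as a separate count and folded in by
`redistribute_unknown()`, which assigns them the mean parity of their
country-by-education group (the most conservative reference group that
preserves the educational gradient; a per-cell reference is available as an
option). The national CFR of an education group is the women-weighted pooled
rate $\sum_r B_{re} / \sum_r N_{re}$ — the CFR of the national population,
not an unweighted mean of regional rates. Gradients are always differenced
from unrounded rates; rounding to two decimals happens only at display time,
so a displayed pair of rates can disagree with the displayed gradient by a
rounding residual. The packaged reference table (`load_country_table()`)
follows the same convention.

## Empirical Bayes smoothing

Raw cell rates $\hat\theta_{re} = B_{re}/N_{re}$ are noisy when cells are
small (regional samples range from full registers down to 1% surveys). We
shrink them with a conjugate Poisson–Gamma model: parity is Poisson with
cell rate $\theta_{re}$, and the prior is

$$\theta_{re} \sim \mathrm{Gamma}(\nu\, m_{re},\ \nu),$$

so the posterior is $\mathrm{Gamma}(B_{re} + \nu m_{re},\ N_{re} + \nu)$
with mean

$$\tilde\theta_{re} = \frac{N_{re}}{N_{re}+\nu}\,\hat\theta_{re}
  + \frac{\nu}{N_{re}+\nu}\, m_{re},$$

a convex combination of the raw rate and a reference rate $m_{re}$. The
prior strength $\nu$ acts as a pseudo-count of women: cells with
$N_{re} \gg \nu$ are essentially untouched, empty cells fall back entirely
on $m_{re}$, and $|\tilde\theta - \hat\theta|$ is non-increasing in
$N_{re}$ by construction. Credible intervals for cell rates come from Gamma
quantiles; intervals for derived quantities (differences of rates) have no
closed form and are computed by Monte-Carlo draws from the two Gamma
posteriors under a fixed seed.

### The reference rate

$m_{re}$ encodes where strength is borrowed from, always within the same
country:

* **Cross-region** ($m^{reg}$): the raw rates of the same education group
  in the country's other regions, weighted by both cell size and GDP
  similarity: $m^{reg}_{re} = \sum_{r'} w(r,r') N_{r'e} \hat\theta_{r'e} /
  \sum_{r'} w(r,r') N_{r'e}$, with a Gaussian kernel on log GDP,
  $w(r,r') = \exp\{-(\log g_r - \log g_{r'})^2 / 2h^2\}$. A region never
  informs its own prior ($w(r,r)=0$) and weights never cross country
  borders.
* **Cross-education** ($m^{edu}$): the pooled raw rate of the region's
  other education groups, rescaled by the country-level ratio of the
  education group's rate to the other groups' pooled rate — the
  country-wide regularity of education-specific fertility levels.

The two are mixed as $m = \lambda_{reg} m^{reg} + \lambda_{edu} m^{edu}$
with default $\lambda = (0.7, 0.3)$: the same education group elsewhere is
the more direct analogue of the target cell, so it dominates, but both
weights are exposed in `eb_params()`. If one source has no data its weight
moves to the other; a cell with no source anywhere in its country cannot be
smoothed and is flagged.

### Tunable parameters

* `bandwidth_h` (log-GDP units): kernel scale. Default: the pooled
  within-country standard deviation of log GDP of the data at hand — the
  natural scale of the similarity covariate; smaller values localise
  borrowing, `h` $\to\infty$ gives size-only weighting.
* `prior_strength_nu` (pseudo-women): default `"auto"`, a per-country
  method-of-moments estimate. The between-cell variance of raw rates in
  excess of the average Poisson sampling variance $\overline{\hat\theta/N}$
  is attributed to true heterogeneity, and $\nu = \bar{\hat\theta} /
  \max(\varepsilon, \text{excess})$, capped to $[1, 10^6]$. Homogeneous
  countries therefore shrink hard, heterogeneous ones barely. Estimating
  $\nu$ once per country rather than per cell stabilises the moment
  estimator.
* `mix_weights`, `ci_level` (default 0.95), `n_draws` (default 4000),
  `seed`.

The borrowing *structure* (sources, within-country restriction, GDP-based
similarity, size-proportional weighting, Poisson likelihood) is fixed; the
constants above are the package's own design decisions, config-exposed, and
no claim is made that any particular published regional estimate is
reproduced digit-for-digit.

## Gradient regressions

`gradient_table()` forms one point per region: the CFR difference of an
education pair (raw with raw or EB with EB, never mixed) against the
natural log of GDP per capita. Two models are fitted, each unweighted (one
region = one observation):

* `fit_pooled()`: OLS of the difference on log GDP across all countries
  and regions, with intercept.
* `fit_fixed_effects()`: the within estimator — both variables demeaned
  within country, slope through the origin — algebraically identical to
  OLS with country dummies (asserted in the tests to $10^{-10}$), with
  residual degrees of freedom $n - C - 1$. It averages the within-country
  associations and is invariant to country-level shifts.

Slopes are in children per woman per unit of log GDP; since only the
covariate is logged, multiplying every GDP by a constant shifts intercepts
but leaves slopes unchanged. Default outcome is the EB-smoothed rates, with
`raw` available as a flag. `hgdp_compare()` contrasts each country's
highest-GDP region (ties broken by region code order, with a warning)
against the pooled remaining regions — cells summed before rates are
formed — with posterior Monte-Carlo intervals; the pooled "rest" posterior
uses the country's $\nu$ and a prior centred at the country-level rate of
the education group.

No causal claim is attached to any of these associations, and no
standard-error clustering or spatial correlation adjustment is attempted.

## The synthetic generator

`synthetic_config()` + `generate_regions()` + `generate_microdata()`
produce register-style microdata with known ground truth:

* Regional GDP per capita is log-normal (`gdp_log_mean` 10, `gdp_log_sd`
  0.3 by default — a realistic within-Europe spread of regional
  development).
* Education shares tilt toward high attainment in richer regions via a
  multinomial-logit tilt of the high category (default base shares 0.16 /
  0.53 / 0.31 for low / medium / high, the typical composition of recent
  European female cohorts; tilt 0.5).
* Completed parity is Poisson with mean $\mu_e + \beta_e(\log g_r -
  \bar g) + u_c$, clipped at $10^{-6}$ if non-positive (with a warning).
  Default base rates 2.03 / 1.78 / 1.62 children per woman mirror observed
  national education-specific CFR levels. The mean structure is additive on
  the rate scale, not log-linear, because the analysis studies *differences*
  of CFRs on the natural scale: the ground-truth gradient slope must live
  on that scale. Per-education slopes $\beta_e$ imply the pair slopes; the
  convenience scalar `gradient_slope` (default 0.3) is placed on the high
  group, since three independent pair slopes are not representable in a
  per-education mean structure.
* Country effects $u_c$ are additive normal draws (`country_effect_sd`
  0.1), the simplest heterogeneity consistent with country fixed effects;
  they cancel from every educational difference.
* Bernoulli thinning (`sampling_fraction`) emulates survey/census sampling;
  `unknown_fraction` (default 0) masks parities to exercise redistribution.

All randomness flows from one master seed through deterministic per-region
sub-streams, so identical configs give byte-identical output. The generator
deliberately omits age/period structure, parity progression, migration and
household composition: passing recovery tests therefore demonstrates that
the *estimators* are correct and calibrated under the assumed data
structure, not that real register data satisfy that structure.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` re-run four simulation studies,
sized so that Monte-Carlo error is small relative to the tolerances they
check:

* **Slope recovery**: 200 replications of 5 countries × 6 regions × 5,000
  women at ground-truth slopes 0.3 and 0; checks fixed-effects bias below
  0.03 and coverage of ±1.96·SE intervals within [0.90, 0.99]. A small
  attenuation (about 0.01) is expected and observed, because shrinkage
  pulls extreme-GDP cells slightly toward their donors.
* **HGDP interval calibration**: 500 replications of 3 countries × 5
  regions × 2,000 women; checks that nominal 95% credible intervals for
  the highest-GDP region's gradient cover the truth 93–97% of the time.
* **MSE improvement**: 100 replications at a 1% sampling fraction (20,000
  women per region before thinning), country effects off so the cell truth
  is closed-form; checks that EB estimates beat raw rates in mean squared
  error.
* **Oracle equivalence**: the full smoother on a 3 × 4 × 3 toy against an
  independent brute-force reimplementation ($10^{-10}$), and Gamma interval
  endpoints against numerical quadrature ($10^{-6}$).

## Numerical choices and degenerate inputs

Division guards return `NA` (never 0) for rates of empty cells; a
zero-women reference group during redistribution imputes parity 0 with a
warning; a single-region country gets a zero kernel row and borrows only
across education groups; `estimate_nu()` returns the upper cap for
degenerate variance. The moment estimator's excess variance is floored at
$10^{-12}$ before division and $\nu$ capped to $[1, 10^6]$ to keep
posteriors proper. HGDP ties are resolved lexicographically and logged.

## Limitations

Cells, not women, are the modelling unit: overdispersion of parity within a
cell (relative to Poisson) would make credible intervals anticonservative
on real data. The GDP-similarity kernel is the only spatial structure —
no adjacency or distance — matching the design of the analysis it
implements. The moment estimator of $\nu$ assumes cells within a country
share a prior; strong education-specific heterogeneity is absorbed only
through the reference rate, not through education-specific $\nu$.
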
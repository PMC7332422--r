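---
title: "Methods: hierarchical estimation of population cholesterol trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical estimation of population cholesterol trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

National surveillance of blood lipids rests on surveys that differ in
coverage (national, subnational, community), sampling frame, measurement
technology and calendar year. `choltrends` estimates mean **total**,
**non-HDL** and **HDL cholesterol** (mmol/l) by country, year, sex and age
band from such heterogeneous inputs, and propagates the estimates into
age-standardized series, regional and global aggregates, trend summaries and
cardiovascular deaths attributable to non-optimal non-HDL cholesterol.
Non-HDL cholesterol is defined throughout as total minus HDL, computed per
person before summarization.

The observational unit is the **stratum summary**: one study's
survey-weighted mean, standard error and sample size for one sex and one age
band (18–19, 20–29, then 10-year bands to 70–79, and 80+).

# Record cleaning

Individual records are filtered, in a fixed order that makes the exclusion
log reconcile exactly: under-18; pregnant; total cholesterol outside
(1.75, 20) mmol/l; HDL outside (0.4, 5) mmol/l; total below HDL; and, when
LDL is measured, the CRMLN cross-metric rule. The bounds are strict
inequalities: a value exactly at a bound is retained.

The CRMLN rule deserves a flag. The allowable relative measurement errors
(8.9% total, 13% HDL, 12% LDL) are standard, but the combining inequality is
not; we adopt the most permissive reading — remove only when
`LDL*(1-0.12) + HDL*(1-0.13) > TC*(1+0.089)`, i.e. when the fraction sum
exceeds total cholesterol even after shifting every component to its
error-limit extreme. Any stricter combination would remove more records;
users can tighten the error limits via `plausibility_rules()`.

Source-level eligibility mirrors frame-specific rules: school-based frames
require ≥70% secondary enrolment, insurance frames ≥80% insured,
primary-care frames a universal-insurance system; a frame whose required
context is missing returns an explicit *undeterminable* status rather than
passing silently.

Weighted stratum SEs use the design-based ratio-estimator variance of a
weighted mean. Design effects beyond weights (clustering, stratification)
are out of scope for the synthetic data, which is generated with independent
individuals.

# Portable-device adjustment

Some portable analyzers report only within an analytical range; out-of-range
readings are coded "low"/"high" and unusable. We drop readings below-or-at
the range minimum and at-or-above the maximum, then adjust the resulting
restricted-range stratum means to laboratory-equivalent means via conversion
regressions trained on laboratory studies (where both the full-range and the
artificially truncated mean can be computed). The response is the full-range
mean; predictors are the restricted mean, age-band midpoint and sex, with
candidate interactions (restricted mean × age, restricted mean × sex, and
for non-HDL the restricted total/HDL means and their sex interactions)
selected by exhaustive BIC search, ties broken toward fewer terms. Strata
with fewer than 25 individuals are excluded from training. Adjustment
uncertainty combines the input mean's sampling noise, the coefficient
covariance and the residual SD via Monte-Carlo draws.

The shipped analytical ranges (`device_ranges_example()`) are synthetic and
illustrative — chosen to clip roughly 10–20% of a realistic population
distribution — because real device ranges are instrument-specific. Supply
your own table for real analyses.

# The hierarchical trend model

Per sex and metric, the stratum mean \(y_i\) for country \(c\), year \(t\),
band \(a\) is modelled as

\[
y_i \sim N(\mu_{c,t,a} + \text{study terms}_i,\; \mathrm{SE}_i^2 + \kappa_{g(i)}^2)
\]

\[
\mu_{c,t,a} = \sum_{\ell \in \{\text{world, super-region, region, country}\}}
  \big( \alpha_\ell + \beta_\ell t^\* + u_{\ell}(t) \big)
  + s(a) + s_c(a) + \gamma\,\mathrm{urb}_{c,t} \;[+\; \delta\,\mathrm{TC}_{c,t}]
\]

* \(t^\*\) is the year centred and scaled to decades, so slopes are
  per-decade changes.
* \(u_\ell(t)\) is a **second-order random walk** (RW2) on annual knots at
  each hierarchy level, parameterized in the spectral basis of the
  second-difference penalty. Because that basis is exactly orthogonal to the
  null space \(\{1, t\}\), every draw satisfies the sum-to-zero and
  detrending constraints by construction and the linear slope stays
  identified; this is checked to 1e-8 in the tests.
* \(s(a)\) is a natural cubic spline with knots at the band midpoints
  25–75 and boundary knots at 19 and 85 — evaluated at the eight band
  midpoints this basis is saturated, so the age model imposes no
  approximation error at band level; \(s_c(a)\) are hierarchically shrunk
  country-level perturbations of its coefficients.
* Study terms: fixed effects for subnational and community studies; fixed
  effects for rural-only and urban-only studies weighted by the country's
  urban proportion (a rural-only study in a country that is fraction \(p\)
  urban enters with weight \(p\), an urban-only study with \(1-p\), so the
  effect scales with how unrepresentative the study is); and study-level
  random effects shared by all strata of a subnational or community study,
  which down-weight such studies relative to national ones of equal size.
* \(\mathrm{urb}_{c,t}\) is the centred urban-population proportion; the
  non-HDL and HDL models additionally take the centred age-standardized
  total-cholesterol estimate as covariate, fed forward as posterior means
  from the total-cholesterol fit (full joint propagation across metrics is
  out of scope).
* \(\kappa_g\) is a coverage-class overdispersion SD (national,
  subnational, community), so non-national data carry extra variance.

**Priors.** The source analyses defer exact priors to a companion
statistical literature; this package's own choices are diffuse normal
(SD 10) on fixed effects and half-normal priors on every random-effect and
overdispersion SD, with scales (0.5 intercepts, 0.3 slopes, 0.1 RW2, 0.3
spline perturbations and study effects, 0.3 overdispersion) documented in
`model_spec()` and overridable. The RW2 penalty is rescaled so its marginal
variance averages one at unit SD, keeping the prior scale comparable across
year-range lengths.

**Sampling.** A blocked Gibbs sampler draws the full coefficient vector
jointly from its Gaussian conditional via a sparse Cholesky factorization
(the design typically has 300–3,500 columns), then slice-samples each SD.
This is exact MCMC for this model family; correctness is established by a
conjugate normal-normal oracle (single country, flat truth, posterior within
0.05 mmol/l of the closed form) and by coverage experiments rather than by
trusting the algorithm. Default 5,000 post-burn-in draws; the experiments in
the test suite use 250–2,000 draws, sized so the whole suite runs on one
CPU in minutes. Split-chain R-hat above 1.05 flags (but does not fail) a
run; a non-finite sampler state is a hard error naming the iteration.

**Estimand.** Predictions exclude all study-type terms: the target is the
general national population. For a country with no data the country-level
terms are drawn from their shrinkage prior, so its posterior tracks the
region curve with appropriately wider intervals — a property the tests check
explicitly.

# Post-processing

Age-standardization uses the WHO world standard population collapsed onto
the analysis bands; the 18–19 band takes two fifths of the 15–19 weight and
80+ pools everything above 80 (the named standard does not prescribe this
band mapping; it is our interpretation, renormalized to sum to one).
Regional and global aggregates are population-weighted at band level first,
then standardized — in that order aggregation is associative, which the
tests verify to 1e-10.

Change per decade divides the 2018−1980 (or configured endpoint) difference
by **elapsed decades** (3.8 for 1980–2018). Analyses sometimes quote the
inclusive year count (39 years); we treat change-per-time as change over
elapsed time but expose the divisor, so 3.9 is one argument away. Posterior
probabilities of decline/increase are the fractions of draws below/above
zero.

# Attributable mortality

For each cell the population attributable fraction compares a normal
exposure distribution (posterior mean draw, user-supplied SD — the trend
model estimates means, not dispersions) against a counterfactual centred in
the optimal band 1.8–2.2 mmol/l. Relative risk is log-linear above the band
midpoint and 1 below it. The counterfactual default is normal at the
midpoint with the observed SD; drawing the counterfactual mean uniformly
over the band is supported (`counterfactual = "uniform"`) and differs by
< 0.02 in PAF in the tested range. Expectations use adaptive quadrature,
cross-validated against 10^6-draw Monte Carlo on a 3×3×3 grid of
(mean, SD, log-RR slope). Attributable deaths are PAF × cause-specific
deaths, summed with credible intervals over posterior draws. The shipped RR
curves are illustrative shapes, not published meta-analysis values; supply
real curves as CSV.

# Hold-out validation

Two tests: hold out all data from 10% of countries with data, or hold out
10% of sources (per selected country, either a random half of its sources
or all its post-2000 sources, alternating). Richness strata: data rich (≥5
sources with one after 2000), data poor (1), average (2–4); ≥5 sources with
none after 2000 lacks the recency the rich class requires and is classified
average. Five repetitions per test; errors are held-out value minus
estimate (over-estimation is negative); overall medians pool individual
errors rather than averaging stratum medians. The no-leakage property — a
held-out unit contributes nothing to its repetition's fit — is audited on
the training-study sets.

# What the synthetic world does and does not emulate

The generator draws a country–region–super-region hierarchy, smooth true
surfaces built from the same components the model estimates (linear trends,
centred-and-detrended RW2 deviations, cubic-polynomial age curves with
country perturbations), study mixtures matching the observed composition of
multi-country lipid databases (36.3% national / 22.2% subnational / 41.5%
community; 10% portable-device studies; roughly one country in five without
data), study-level offsets for non-national studies, and individual records
with survey weights, pregnancy flags, under-18 records and implausible-value
injection. Individual lipids are normal within strata (truncated to the
plausibility windows, so injected values are the only filter targets) with a
configurable total–HDL correlation, since the within-person joint
distribution of the fractions is not pinned down by published summaries.

Deliberately *not* emulated: realistic country names and populations, survey
nonresponse, duplicate sources, cluster/stratified design effects, and
device biases other than range truncation. Passing tests therefore
demonstrate correct recovery *within this model family* — they cannot attest
to structural misspecification present in real data (e.g. non-normal lipid
distributions or informative survey placement).

# Experiment sizes and numerical choices

The test-suite experiments use: 10^5 records for cleaning fidelity; 200
device strata for bias reduction; a 30-country / 3-region / 10-year world
with 2,000 post-burn-in draws for coverage (≥85% of country-year
age-standardized cells) and borrowing; 60 countries over 1985–2018 with ~10
sources each for slope recovery (r ≥ 0.8); and five repetitions of both
hold-out tests at the 30-country scale. These sizes were chosen as the
smallest at which the properties are statistically meaningful.

Numerical details: observation SEs enter as known variances; strata of size
one (no SE) are dropped; slice sampling is bounded to log-SD ∈ [−11, 4] to
keep precisions finite; the PAF is evaluated on an 80-point spline
interpolant of the quadrature (monotone Hyman interpolation, falling back to
linear when the grid is flat); BIC ties within 1e-6 go to the smaller
model; rank-deficient conversion designs drop aliased terms with a warning.

# Reproducibility

Every stochastic function takes an explicit seed and the pipeline derives
per-stage seeds from a master seed; two runs with the same configuration
produce byte-identical estimate tables. `scripts/acceptance.R` re-runs the
whole chain from scratch and writes the headline quantities as JSON.
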
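---
title: "Methods: ambient pesticide exposure and gene-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ambient pesticide exposure and gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambientgxe)
```

# Overview

`ambientgxe` implements a complete gene-environment (GxE) interaction
analysis for a population-based case-control design in which environmental
exposure is not measured directly but modelled from records of commercial
pesticide applications near each subject's addresses. The package has five
coupled parts: a synthetic study generator, the exposure-assessment engine,
genotype/Hardy-Weinberg machinery, the interaction models, and
simulation-based power. This vignette records the modelling assumptions,
the defaults and why they were chosen, the numerical decisions, and what
the synthetic tests do and do not demonstrate about real data.

# The exposure model

## Annual buffer sums

The primitive quantity is the annual buffer sum: for one pesticide, one
calendar year, and one address, the sum of `pounds / acres` over all
application records of that pesticide in that year whose location lies
within `radius_m` (default 500 m) of the address. Distances are planar
Euclidean on projected metre coordinates; the synthetic landscape needs no
datum, and at a 500 m scale the distinction from geodesic distance is
irrelevant. The disc is **closed**: a record at exactly 500 m counts. Each
record contributes its own pounds-per-acre ratio (a point-mass
simplification of area-weighted parcel intersection; the downstream
statistics are invariant to this substitution since thresholds are
determined from the same quantity in controls).

## Window averaging and imputation

Per subject, setting (residential/occupational) and pesticide, yearly
values are averaged over the exposure window `[start_year, index_year -
lag_years]`, both endpoints **inclusive** (defaults 1974 and lag 10; the
window endpoint's inclusivity is a genuinely open convention and was fixed
once, inclusively). Years whose address could not be geocoded are imputed
with the mean of the subject's recorded years for that pesticide and
setting, restricted to the window so that imputation is self-contained.
Two useful identities follow, and are asserted by property tests:
imputation never changes the mean of recorded years, and imputing at the
recorded mean and then averaging over the whole window equals the mean
over recorded window years. The vectorized pipeline
(`compute_exposure_profiles()`) exploits the second identity; the literal
per-year operations (`impute_missing_years()`, `window_average()`) exist
independently, and a dual-route test checks they agree with the vectorized
path exactly. A subject with **no** recorded window year at either setting
has undefined exposure and is excluded, with the exclusion and its reason
carried into the run manifest.

## Dichotomization and class rollup

"Exposed controls" for threshold construction are controls with strictly
positive window average — including zeros would collapse the median.
Thresholds are the sample median (even-sized samples: midpoint of the two
central order statistics), applied inclusively ("at or above"). Thresholds
are computed per pesticide **and setting**, mirroring assessment at each
location; a subject counts as exposed to a pesticide if at/above threshold
at either setting by default (`combine_settings = "either"`, with `both`,
`residential_only`, `occupational_only` available). Class-level categories
follow the field's convention: organophosphates and dithiocarbamates are
`high` when the count of at-threshold pesticides reaches the median count
among controls with at least one; pyrethroids are `any` versus `none`
(one or more pesticide); paraquat, a single agent, is `exposed` iff its
own label is high. Whether per-pesticide "exposed to" should mean
at/above-median or any non-zero contact is not uniquely determined by the
design; the at/above reading is the default and a `pesticide_rule = "any"`
switch provides the other.

# Genetics

Hardy-Weinberg equilibrium in controls is checked two ways: the plain
Pearson chi-square on the three genotype cells against expectations from
the sample allele frequency (1 df, no continuity correction — the
continuity-corrected variant is deliberately not offered, the exact test
being the appropriate robustness companion), and the exact conditional
test, whose p-value sums the probabilities of all heterozygote counts no
more probable than the one observed, given the allele counts. The exact
distribution is evaluated in closed form via log-factorials, which is an
exact enumeration at any realistic sample size; a recurrence-based
enumeration oracle confirms it in tests for totals up to 200. Genotype
coding: additive 0/1/2 copies of G, recessive GG=1, homozygote contrast
AA=0/GG=1 with heterozygotes excluded. G is fixed as the risk allele.

# Association models

`fit_logistic()` is a self-contained iteratively-reweighted-least-squares
maximum-likelihood fitter. Numerical decisions:

* start at zero coefficients; step-halving guards the likelihood ascent;
* convergence requires relative log-likelihood change < 1e-10 **and**
  maximum absolute score < 1e-8, within 100 iterations;
* the covariance is the inverse observed information at the optimum;
* any coefficient exceeding 15 in absolute value triggers a separation
  error naming the term (log-odds of ±15 are beyond anything estimable at
  these sample sizes and indicate complete or quasi-complete separation);
* rank-deficient designs raise a collinearity error naming the dropped
  columns rather than silently aliasing them.

On saturated 2x2 designs the fit reproduces Woolf's closed-form log odds
ratio and standard error to 1e-8, and on general designs it matches
`glm()` — used in tests only, as an independent cross-check — to near
machine precision.

Effect estimates are Wald: `OR = exp(c'β)` with a fixed 1.96 normal
multiplier (not t; standard practice for logistic intervals at hundreds of
observations). The interaction p-value defaults to the two-sided Wald test
on the product term, since the originating analyses do not state the test
variant; the likelihood-ratio p is always reported alongside, and a sanity
test keeps the two within a factor of 1.5 of each other for small effects
at n >= 1000. The GxE table lays out joint effects against the
unexposed-reference-genotype cell: `exp(β_e + k·β_g + k·β_ge)` for k risk
alleles, so the additive model's exposed-GG cell equals
(exposed-AG OR)² / (exposed-AA OR) identically. Subjects with missing
genotype, undefined exposure, or missing covariates are dropped listwise
with counts recorded. Age enters untransformed in years; sex and
ever-smoking as indicators.

`demographics_compare()` uses the pooled-variance two-sided t-test for
continuous variables and the Pearson chi-square without continuity
correction for categorical ones. `spearman_eqtl()` reports the
tie-corrected Spearman correlation between additive genotype code and an
expression measure with the t-approximation p-value (an optional
permutation p is available); note that with tied genotype codes the tie
correction keeps |rho| below 1 even for perfectly monotone expression
unless the tie patterns align.

# The synthetic study generator

The generator emulates the whole observational design, with defaults
chosen to mirror a population-based case-control study of ambient
pesticide exposure:

* **Cohort**: 465 cases, 497 controls, sampled without replacement from an
  oversized source population (default 8x the target) whose disease status
  is drawn from the logistic model — preserving the retrospective design's
  outcome-dependent sampling. Requesting more cases than the source
  yields is an explicit error suggesting a larger source.
* **Genotypes**: Hardy-Weinberg proportions at risk-allele frequency 0.42,
  which reproduces a control distribution near 0.35/0.46/0.19.
* **Applications**: a homogeneous Poisson process per chemical class
  (events/year over the whole zone), uniform locations within an
  agricultural zone occupying the western 7 km of a 20 km square region,
  log-normal pounds (median 50) and acres (median 20). Pyrethroid events
  carry the thirteen named active ingredients (fenvalerate, permethrin,
  ...); other classes use generated names.
* **Addresses**: one residential point per subject — rural subjects
  (default 30%) uniform inside the agricultural zone, the rest outside —
  and a workplace displaced by isotropic normal noise (sd 1 km). The 30%
  rural share makes roughly a third of subjects ambient-exposed, matching
  the exposure prevalence typical of such cohorts. Address histories are
  written year by year with independent Bernoulli missingness (default
  0.10) per (subject, year, setting), the simplest mechanism consistent
  with un-geocodable years.
* **Index years** 2000-2007, so exposure windows span 17-24 years;
  age ~ N(66, 10) truncated to [35, 95]; 55% male; 45% ever-smokers.
* **Disease model** defaults: β_g = ln 1.03, β_e = ln 0.83,
  β_ge = ln 1.65 (per-allele interaction), β_sex = 0.3, β_smoke = -0.3,
  intercept -2.2 — marginal genotype and exposure effects near null with a
  positive interaction, the configuration of scientific interest.

The generator's **true exposure** indicator applies the same
classification rules as the analysis, but with full information: no
address missingness and thresholds computed from the whole source
population (case/control labels do not exist at generation time). It is
recorded per subject precisely so that parameter-recovery and calibration
experiments can isolate the estimation machinery from
exposure-misclassification noise; the observed pipeline (missingness,
control-based thresholds) is exercised separately.

Because status depends on exposure only through the binary indicator,
exposure *levels* are conditionally independent of status among the
exposed, and control-based thresholds consistently estimate the
generation-time thresholds — the design reason the observed pipeline's
dichotomization is unbiased at scale.

All randomness flows from one master seed; each stage draws from its own
stream derived by hashing a fixed stage label and scrambling with a few
Lehmer steps, so numbered replicate labels cannot produce additively
structured seeds, and changing one stage's parameters leaves other
stages' randomness untouched.

What the generator does **not** emulate: real land-use geometry or crop
rotation, address changes over a lifetime (locations are constant;
the table format supports moving addresses but the generator does not
produce them), informative geocoding failure, genotyping error, control
selection bias, or population stratification. Passing tests therefore
demonstrate the correctness and calibration of the estimation machinery
under the stated design, not robustness to those real-data pathologies.
One realistic artefact is present: all classes are applied in the same
agricultural zone, so class-level exposures are spatially correlated and
a true pyrethroid interaction can echo in other classes — as in real
co-exposure data.

# Power and calibration

`estimate_power()` estimates the interaction test's rejection probability
by full simulation — generate, assess exposure, fit — rather than by
closed-form approximation, so every module is exercised jointly.
Replicates failing with separation or inestimable cells are counted and
reported; more than 20% failures marks the design unstable. The estimate
carries an exact binomial confidence interval. Setting β_ge = 0 gives the
type-I error rate; diagnostics on 4000 null replicates at study scale
show uniform interaction p-values with no overdispersion across batches.

# Problem sizes in the test suite

The long-run statistical checks use sizes chosen to give decisive
error bars while keeping the default suite quick on one CPU: parameter
recovery uses 200 cohorts of 2500 + 2500 with a true interaction OR of
2.5 (mean recovered within ±0.05 on the log scale, 95% CI coverage at
least 91%); null calibration uses 2000 replicates at study scale
(465 + 497), with the rejection rate required to stay within
[0.035, 0.065] at α = 0.05; Hardy-Weinberg calibration uses 2000
samples of 500 genotypes. Exact oracles (brute-force buffer sums over
10,000 records, exhaustive Hardy-Weinberg enumeration, Woolf closed
forms, exhaustive Spearman permutations) are deterministic.

# Known limitations

* Wald interaction tests are mildly anti-conservative when joint cells
  hold only a few dozen subjects; the likelihood-ratio p is reported for
  exactly this reason, and no small-sample (Firth-type) correction is
  offered.
* The exposure engine assumes point applications and closed-disc buffers;
  no parcel polygons, crop weighting, or drift modelling.
* No matched or conditional logistic variants; adjustment is by
  covariates only.
* Single biallelic locus; no haplotypes, no genotype uncertainty.
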
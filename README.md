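# ambientgxe

Gene–environment interaction analysis for population-based case-control
studies of ambient pesticide exposure, built as a tested, fully synthetic,
reproducible pipeline.

## The scientific problem

Common noncoding variants in the HLA region (e.g. the intronic *HLA-DRA*
SNP rs3129882, alleles A/G with G the risk allele) show weak marginal
association with Parkinson's disease, but may act synergistically with
immunomodulatory pesticide exposure. Testing that hypothesis requires three
pieces of machinery:

1. **Ambient exposure assessment.** Subjects are not measured for body
   burden; exposure is modelled from commercial pesticide-application
   records. For each pesticide, the pounds-per-acre applied within a 500 m
   buffer of a subject's residential and occupational addresses are summed
   per year, averaged over the window from 1974 to ten years before the
   subject's index year (diagnosis for cases, interview for controls), with
   un-geocoded years imputed at the subject's recorded-year mean. Exposure
   is then dichotomized at the pesticide-specific median among exposed
   controls ("at or above"), and rolled up to chemical classes
   (organophosphates, dithiocarbamates, pyrethroids, paraquat) by counting
   pesticides at/above threshold — pyrethroid exposure is "one or more
   pesticide", the others use the median count in exposed controls.

2. **Genetics.** Hardy–Weinberg equilibrium checks in controls (Pearson
   χ² and an exact conditional test), allele frequencies, and genotype
   coding under additive (0/1/2 copies of G), recessive (GG vs AA+AG), and
   homozygote-contrast (AA vs GG, AG dropped) models.

3. **Association.** Covariate-adjusted logistic regression
   (age continuous, sex, ever-smoking) with a multiplicative interaction
   term,

   `logit P(case) = β₀ + β_g·G + β_e·E + β_ge·G·E + β_age·age + β_sex + β_smoke`

   reported as a stratified table: genotype odds ratios among the
   unexposed, the exposure OR in the reference genotype, joint-effect
   ORs `exp(β_e + k·β_g + k·β_ge)` for k risk alleles against the
   unexposed-AA reference cell, and the interaction p-value (Wald on
   β_ge, likelihood-ratio alongside). Fitting is by iteratively
   reweighted least squares with explicit separation and collinearity
   diagnostics.

Because individual-level study data are not deposited, the package ships a
**synthetic cohort generator** that emulates the whole study design —
pesticide-use-report application records, geocoded address histories with
missing years, genotypes in Hardy–Weinberg equilibrium, covariates, and
disease status drawn from the logistic model above — so every stage is
testable end to end, including simulation-based power for the interaction
test (`estimate_power()`).

## Worked example

Arithmetic on a published control genotype distribution and the crude
joint-effect fit from printed homozygote cell counts:

```r
library(ambientgxe)

counts <- genotype_counts(175, 227, 95)      # control AA/AG/GG
counts
#> Genotype counts (n = 497): AA 175 (0.35) / AG 227 (0.46) / GG 95 (0.19)
allele_freq(counts)
#> [1] 0.4195171
hwe_chisq(counts)
#> Hardy-Weinberg chi-square test: chi2 = 1.9241, df = 1, p = 0.1654

# crude 2x2: unexposed-AA 95 cases/117 controls vs exposed-GG 30/14
y <- c(rep(1, 30), rep(0, 14), rep(1, 95), rep(0, 117))
e <- c(rep(1, 44), rep(0, 212))
fit <- fit_logistic(cbind(intercept = 1, exposed_gg = e), y)
wald_or(fit, c(0, 1))
#> OR = 2.639 (95% CI 1.324, 5.260), p = 0.005821
```

The control genotype distribution is compatible with Hardy–Weinberg
equilibrium (p = 0.165), and subjects carrying both the GG genotype and
pyrethroid exposure have 2.6-fold crude odds of disease relative to
unexposed AA subjects.

A full synthetic study — simulate, assess exposure, fit every class × model
combination — runs in seconds:

```r
res <- run_pipeline(sim_config(seed = 42L))
res
#> Pipeline run 1e809ba8 (seed 42 )
#>   9836 applications; 962 subjects in, 962 analysed, 0 excluded
#>   controls HWE: chi-square p = 0.070, exact p = 0.080
#>   organophosphate.additive: interaction p (Wald) = 0.1136, (LRT) = 0.1106
#>   ...
#>   pyrethroid.additive: interaction p (Wald) = 0.007735, (LRT) = 0.007274
#>   pyrethroid.homozygote_contrast: interaction p (Wald) = 0.01694, (LRT) = 0.01611
#>   ...
```

The generator's default configuration plants a per-allele interaction OR of
1.65 for pyrethroids, which this run's additive model detects (Wald
p = 0.008); co-application of the other classes in the same agricultural
zone makes their exposures correlated with pyrethroids, so they can echo
the signal, as dithiocarbamates do here.

A shell front end over the same functions is installed as
`exec/ambient-gxe` with subcommands `simulate`, `exposure`, `associate`,
`power`, and `run-all`.

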
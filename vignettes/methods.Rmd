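---
title: "Methods: scores, classification, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scores, classification, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsgdm)
```

This vignette documents the statistical machinery behind `grsgdm`: the
weighted genetic score, the WHO 2013 subgroup classification, the QC and
inference conventions, and — in most detail — the synthetic cohort
generator, including what it deliberately does *not* emulate.

## The weighted genetic score

For a panel of $N$ SNPs with positive per-allele weights $\beta_i$ and
effect-allele dosages $a_i \in \{0, 1, 2\}$,

$$GS = N \, \frac{\sum_i a_i \beta_i}{\sum_i \beta_i}.$$

The rescaling by $N / \sum\beta$ makes scores comparable across panels of
different units (mmol/L per allele for the FPG panel, log-odds per allele
for T2D): the range is $[0, 2N]$ and the all-heterozygous individual
scores exactly $N$. Two consequences matter downstream:

* **Slope identity.** If each allele contributes exactly its weight to a
  trait, the population regression slope of the trait on the score is
  $\sum\beta / N$ — for the shipped FPG panel $0.452/15 \approx 0.0301$
  mmol/L per score unit. The generator is constructed so this holds
  exactly (see below).
* **Closed-form moments.** Under Hardy–Weinberg equilibrium (HWE) and
  linkage equilibrium at effect-allele frequencies $p_i$, the score has
  mean $2N\sum p_i\beta_i / \sum\beta_i$ and variance
  $(N/\sum\beta)^2 \sum 2p_i(1-p_i)\beta_i^2$; `score_moments()` computes
  these and the test suite checks simulated cohorts against them.

Scores obey a strict complete-data rule: any missing dosage at a panel SNP
nulls the individual's score for that panel. There is no imputation, and
no partial-panel rescaling — partial scores would silently change the
score's scale per individual.

## Classification

`assign_category()` maps each OGTT triplet to exactly one of six labels
using the WHO 2013 thresholds (inclusive): fasting $\ge 5.1$, 1-hour
$\ge 10.0$, 2-hour $\ge 8.5$ mmol/L. Cases split by which thresholds are
met: `fasting_only`, `one_hour_only`, `two_hour_only`, and `combined`
(fasting plus at least one post-load criterion). Controls must be below
every case threshold *and* below the `control_2h_bound`, which defaults
to 7.8 mmol/L — the conventional normal-glucose-tolerance bound, stricter
than the 8.5 case threshold. Setting `control_2h_bound = 8.5` reproduces
the permissive alternative in which any non-case is a control; under the
default, records between 7.8 and 8.5 at 2 hours (meeting no case
criterion) are `unclassified`. A second `unclassified` corner is the
fasting-normal record with *both* post-load values elevated, which
belongs to no "only" subgroup and, under the strict reading, not to
`combined` either (that requires fasting elevation);
`merge_combined = TRUE` folds it into a broadened combined group. The
partition property — every complete triplet gets exactly one label under
every option combination — is enforced by tests.

## QC conventions

* **HWE screen** (`hwe_screen()`): per-SNP 1-df Pearson chi-square against
  the genotype proportions expected at the sample allele frequency,
  Bonferroni-corrected over the number of SNPs screened; SNPs below the
  corrected threshold become `hwe_failure` exclusion rules. An exact test
  conditioning on allele counts is available for small samples.
  Monomorphic SNPs are flagged but never excluded: the test is undefined
  there, and silent exclusion would change the panel size.
* **Effect-allele alignment** (`read_genotypes()`): VCF REF/ALT pairs are
  matched to the panel alleles as written first, then as reverse
  complements. Palindromic (A/T, C/G) SNPs cannot be strand-resolved from
  alleles alone, so the default `palindrome_policy = "fail"` refuses them
  with an error naming the SNP. `"freq"` resolves the strand by comparing
  the observed allele frequency with the panel frequency (reasonable away
  from 0.5), and `"trust"` accepts the file orientation as written.
  Dosage-TSV input is effect-allele-coded by definition and bypasses
  alignment entirely.
* **Call rates and duplicate concordance** are descriptive QC outputs
  (`call_rates()`, `duplicate_concordance()`); the package does not
  auto-exclude on them.

## Inference conventions

Case subgroups are compared with controls by Wilcoxon rank-sum tests for
clinical variables and pooled-variance t-tests for the scores (Welch by
option). Each glucose measure is regressed on each score by OLS, with and
without adjustment for the other two glucose measures; ANCOVA of score on
case status adjusting for BMI and age is run as a sensitivity analysis.
Bonferroni multipliers are *reporting conventions, not inferred
quantities*: the defaults (24 for clinical comparisons, 16 for score-mean
comparisons, 24 for regression coefficients) reflect the comparison
counts of the reporting layout and are user-visible arguments of
`gdm_gs_fit()` and `run_config()`. `power_variance_explained(n, r2,
alpha)` gives the power of detecting a predictor explaining a fraction
`r2` of outcome variance via the noncentral F distribution with
noncentrality $n\,r^2/(1-r^2)$; at $n = 2628$, $r^2 = 0.06$,
$\alpha = 0.002$ it is 1 to machine precision.

## The synthetic generator

`simulate_cohort()` draws genotype–phenotype cohorts with the structure
the analysis assumes, with full generative truth written alongside
(`truth.csv`, never read back by the pipeline).

**Genotypes.** Independent $\mathrm{Binomial}(2, p_i)$ dosages per SNP at
the panel effect-allele frequencies — HWE and linkage equilibrium. The
five rsids shared between the FPG and T2D panels are drawn *once* and
reused, so the two scores have their theoretical genetic covariance.

**Fasting glucose.** With $g_F$ the centred FPG genetic value
($\sum a_i\beta_i - E[\cdot]$),

$$\mathrm{FPG} = \mu_F + g_F + e_{T,f}\, GS_T^{\perp} + \varepsilon_f,$$

where $GS_T^{\perp}$ is the component of the T2D score orthogonal to
$g_F$ (computed from the closed-form covariance over the shared SNPs).
The orthogonalisation is the key design decision: it lets the T2D score
influence glucose without biasing the FPG-on-$GS_F$ slope, which remains
exactly $\sum\beta/N$ at the population level. The residual variance is
solved so the FPG score explains exactly `gs_variance_explained` of total
fasting variance (default 0.06, implying total SD
$\sqrt{\mathrm{var}(g_F)/0.06} \approx 0.36$ mmol/L around a mean of 4.5).

**Post-load glucose.** 1-hour and 2-hour values load linearly on $g_F$
(marginal effects 0.060 and 0.032 mmol/L per FPG-score unit) and on
$GS_T^{\perp}$ (0.051 and 0.034; 0.008 on fasting), around means 7.1 and
5.8 with total SDs 1.7 and 1.3 mmol/L; residuals across the three
measures are jointly Gaussian with pairwise correlation 0.5. Residual
variances are again solved from the totals, and configurations demanding
more genetic variance than the configured totals allow are refused, not
clipped.

**Null model.** `gs_variance_explained = 0` zeroes *every* genetic
loading, giving glucose independent of both scores at the configured
total SDs — the right null for calibration tests.
`gs_variance_explained = NULL` keeps the loadings and fixes the total
fasting SD at `fpg_sd` instead.

**Covariates and missingness.** BMI is log-normal around 24 kg/m² plus
3 kg/m² per mmol/L of fasting glucose above the mean; age is a truncated
normal (31 ± 5, clamped to 18–45); SBP is normal (108 ± 8) with a small
fasting-glucose loading. Genotype missingness (default rate 0.008) is
injected *after* phenotype generation, so missing calls thin the scored
sample without touching the generative truth. `sample_cohort()` converts
a representative cohort to a case-control design: every WHO 2013 case is
kept and exactly three controls per case are drawn from the
low-glucose screen pool, with a hard error on deficit.

### What the generator does and does not emulate

It reproduces: the HWE score moments, the construction slope, the
configured variance-explained fraction, the total glucose moments, and
qualitative subgroup ordering of scores (fasting-involved subgroups carry
higher FPG scores).

It does **not** reproduce real-cohort case fractions. Glucose margins are
Gaussian at representative means and SDs, and real OGTT distributions are
right-skewed; the thresholds sit 2–4 SDs out, so simulated case subgroups
are several-fold smaller than clinical ones (a few percent of the cohort
each). Clinical medians per subgroup, case-control subgroup sizes, and
anything driven by the shape of the upper glucose tail are therefore out
of the generator's scope, and the tests treat them accordingly. One
quantitative consequence is asserted honestly in the acceptance suite:
per-replicate OLS slopes at $n = 2628$ have sampling SD $\approx 0.0023$,
so a single replicate lands inside the reference interval
$[0.023, 0.032]$ (centred at 0.0275, not at the construction value
0.0301) only ~75–80% of the time; the test demanding $\ge 90\%$
per-replicate coverage fails by design, while the aggregate-slope
criterion passes.

## Problem sizes used by the tests

The suite exercises small exact fixtures (3-SNP panels, 6+6 permutation
enumeration, single-record VCFs), calibration runs at $n$ = 20,000–100,000
(moment and $R^2$ recovery within 3–4 Monte-Carlo SEs), and the
analysis-scale design of $n = 2628$ with 100 seeded replicates for the
slope aggregation. All randomness is seeded; the pipeline writes no
timestamps, so identical configurations reproduce identical artifacts
byte for byte.

## A minimal session

```{r, eval = FALSE}
cohort <- simulate_cohort(sim_config(n_samples = 2628, seed = 42))
fit <- gdm_gs_fit(cohort$phenotypes, cohort$genotypes)
summary(fit)
plot(fit)

# or, file-backed and fully logged:
run_pipeline(run_config(out_dir = "run1", seed = 515,
                        sim = sim_config(n_samples = 2628, seed = 515)))
make_report("run1")
```
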
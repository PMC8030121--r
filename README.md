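# grsgdm

Weighted genetic scores for WHO 2013 gestational diabetes subgroups.

`grsgdm` implements, end to end, an analysis linking two weighted genetic
scores — one built from fasting-plasma-glucose (FPG) raising variants, one
from type 2 diabetes (T2D) risk variants — to the diagnostic subgroups of
gestational diabetes mellitus (GDM) defined by the WHO 2013 criteria. It
ships the two SNP weight panels as package data, performs genotype QC
(Hardy-Weinberg screening, call rates, duplicate concordance, effect-allele
alignment from VCF or dosage files), computes the scores, classifies
pregnancies from their oral glucose tolerance test (OGTT) triplets,
and runs the group comparisons and glucose-on-score regressions with
explicit Bonferroni accounting. A synthetic cohort generator with known
ground truth makes the whole pipeline runnable — and testable — without
access-controlled pregnancy cohort data.

## The score

For a panel of N SNPs with per-allele weights β and effect-allele dosages
a ∈ {0, 1, 2},

```
GS = N * Σ aᵢβᵢ / Σ βᵢ
```

so the score ranges over [0, 2N] and an individual heterozygous at every
SNP scores exactly N. Scores are computed only for individuals genotyped at
every panel SNP (strict complete-data rule). The shipped panels have
N = 15 (FPG, Σβ = 0.452 mmol/L per allele) and N = 38 (T2D,
Σβ = 4.321 log-odds per allele), obtained from 16 and 41 candidate SNPs by
the documented exclusions (Hardy-Weinberg failures and one variant whose
primary effect is on BMI).

A useful consequence of the rescaling: the population slope of fasting
glucose on the FPG score is Σβ/N ≈ 0.0301 mmol/L per score unit when each
allele contributes its panel weight — which is exactly how the synthetic
generator is built.

## Classification

Each OGTT triplet (fasting, 1-hour, 2-hour glucose, mmol/L) is assigned to
exactly one of six categories using the WHO 2013 thresholds (fasting ≥ 5.1,
1-hour ≥ 10.0, 2-hour ≥ 8.5, all inclusive): `control`, `fasting_only`,
`one_hour_only`, `two_hour_only`, `combined` (fasting plus either post-load
criterion), and `unclassified`. Controls must additionally sit below a
2-hour bound of 7.8 mmol/L by default (`control_2h_bound = 8.5` relaxes
this to the case threshold).

## Worked example

```r
library(grsgdm)

cohort <- simulate_cohort(sim_config(n_samples = 2628, seed = 42))
fit <- gdm_gs_fit(cohort$phenotypes, cohort$genotypes)
fit
#> Genetic-score analysis of WHO 2013 GDM diagnostic subgroups
#>   2628 pregnancies; control 2-hour bound 7.8 mmol/L
#>   subgroups: control=2315, fasting_only=84, one_hour_only=80,
#>              two_hour_only=28, combined=24, unclassified=97
#>   complete scores (both panels): 1759 of 2628
```

Per-subgroup FPG-score means with 95% confidence intervals
(`score_ci_table(fit)`, stars from the raw P of the t-test against
controls):

```
      category    n  mean    sd ci_low ci_high stars
       control 2027 15.50 2.847  15.38   15.63
  fasting_only   76 16.52 3.396  15.75   17.30    **
 one_hour_only   69 16.60 2.628  15.97   17.24    **
 two_hour_only   27 15.47 2.736  14.39   16.55
      combined   22 17.68 2.594  16.53   18.83   ***
```

The control-group mean and SD (15.50, 2.85) sit on the closed-form
Hardy-Weinberg values for the shipped panel
(`score_moments(gdm_panel("FPG"))` gives 15.56, 2.92). The key regression
coefficients, in mmol/L per score unit:

```r
round(coef(fit)[c("fasting.fpg_gs.unadjusted", "fasting.fpg_gs.adjusted")], 4)
#> fasting.fpg_gs.unadjusted   fasting.fpg_gs.adjusted
#>                    0.0305                    0.0227
```

The unadjusted slope recovers the construction target Σβ/N = 0.0301;
adjusting for the post-load measures attenuates it, as expected when the
score also loads (weakly) on the 1-hour and 2-hour values. The power of
detecting a predictor explaining 6% of variance at n = 2,628 and α = 0.002
is 1 to machine precision (`power_variance_explained(2628, 0.06, 0.002)`).

`summary(fit)` prints the full comparison and regression tables, and
`plot(fit)` draws the two-panel means-with-CIs figure.

For a file-driven run (or a fully reproducible simulated one) use the
pipeline, which writes self-describing text artifacts — HWE screen, score
and category tables, the regression grid, a per-subgroup summary, and a
run log with seed and config hash but no timestamps:

```r
run_pipeline(run_config(out_dir = "run1", seed = 515,
                        sim = sim_config(n_samples = 2628, seed = 515)))
make_report("run1")
```

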
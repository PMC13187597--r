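# topartr

Composite homologous recombination deficiency (HRD) scoring and
molecularly-guided-therapy analytics for cancer cohorts, built around the
analysis needs of biliary tract cancer (BTC) precision-oncology programs.

## Who this is for

Translational researchers and molecular tumor boards working with
multi-omic cohort data: per-sample somatic/germline variant tables,
allele-specific copy-number segments, 96-channel mutation catalogs,
fusion calls, and clinical outcomes on molecularly guided therapy. The
package turns those tables into the cohort-level quantities such programs
report — TMB, signature exposures, scar scores, the composite TOP-ART HRD
score, alteration co-occurrence statistics, and PFS-ratio benefit rates —
with every stage testable on a built-in synthetic cohort generator.

## The models at the core

**TOP-ART score.** Per sample,

    total = impairment + pattern
    impairment = germline points (core 2 / associated 1, cap 2)
               + bi-allelic somatic points (core 2 / associated 1, cap 2)
    pattern    = instability points (HRD-LOH >= 10: +1, LST >= 15: +1)
               + SBS3 point (qualifying exposure: +1)
    positive  <=>  total >= 3  AND  pattern >= 1

with HRD-LOH the count of >= 15 Mb non-whole-chromosome LOH regions and LST
the count of >= 10 Mb adjacent copy-state transitions after 3 Mb smoothing.

**Signature exposures.** For a catalog y and signature matrix S (96 x K),
exposures solve `min_{x >= 0} || y - S x ||`, with presence confidence from
a multinomial bootstrap (high confidence = 95% CI excluding zero).

**Co-occurrence.** For genes a, b the overlap null is Poisson-binomial with
`q_j = p_aj * p_bj`, where `p_gj = plogis(mu_g + lambda_j)` matches every
gene and sample marginal; `p_co = P(X >= obs)`, `p_ex = P(X <= obs)`,
BH-corrected per family.

**PFS ratio.** `r_i = PFS2_i / PFS1_i`; the benefit rate is the
kernel-smoothed Kaplan-Meier survival of the ratio evaluated at
delta = 1.3, with a percentile bootstrap CI over patients.

## Worked example

```r
library(topartr)

cohort <- generate_cohort(cohort_params(n_patients = 115, seed = 7))
report <- run_cohort_analysis(cohort, default_config())
report
#> <cohort_report>
#>   samples: 115; median TMB 1.632/Mb (0 high, 0.0%)
#>   signature 3: 33.9% present, 23.5% high-confidence
#>   TOP-ART positive: 50/115 (43.5%), median score 2
#>   co-occurrence pairs tested: 190
#>   PFS-ratio benefit rate at delta=1.30: 0.573

glance(report$pfs_ratio)[, c("n_used", "benefit_rate", "ci_lower",
                             "ci_upper", "median_ratio")]
#> # A tibble: 1 × 5
#>   n_used benefit_rate ci_lower ci_upper median_ratio
#>    <int>        <dbl>    <dbl>    <dbl>        <dbl>
#> 1     18        0.573    0.366    0.787         1.61
```

Reading: of 115 simulated patients, 43.5% are TOP-ART positive (score >= 3
with detected genomic patterns); 33.9% carry detectable SBS3 exposure, 23.5%
with bootstrap confidence. Among the 18 evaluable guided-therapy patients,
57% kept progression-free for at least 1.3x as long on the guided therapy
as on their prior line (95% CI 37-79%), with a median PFS ratio of 1.61.

Each stage is also available on its own and pipes naturally:

```r
cohort$segments |> scar_scores()
cohort$catalogs |> fit_exposures() |> detect_sig3(min_fraction = 0.1)
cohort$clinical |> pfs_ratio_analysis(delta = 1.3) |> autoplot()
```

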
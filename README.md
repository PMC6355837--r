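# methconcord

Cross-tissue DNA methylation concordance analysis: how faithfully do
peripheral tissues (blood, saliva, buccal) mirror brain DNA methylation
within individuals?

Brain tissue is essentially inaccessible in living cohorts, so epigenetic
studies of neuropsychiatric traits measure methylation in surrogate tissues.
Whether a surrogate is informative depends on *which question you ask*, and
this package keeps the two standard answers separate:

* **Across-subject concordance** — Pearson correlation, over CpG probes,
  between two tissues' subject-averaged beta profiles
  (`across_subject_correlation()`). High for almost any tissue pair, because
  all tissues share the same genome-wide methylation architecture.
* **Within-subject concordance** — for each CpG *j*, Spearman's rank
  correlation across subjects between paired measurements in two tissues
  (`within_subject_correlations()`), with exact permutation p-values when
  there are ≤ 7 complete pairs and a t approximation (df = n − 2) above
  that. This is the biomarker question, and typically only a minority of
  CpGs are concordant.

Around that core: probe QC (strict detection-p > 0.01 rule, an iterative
greedy-cut removal of unreliable probes/samples, SNP-proximity and
context-specific exclusion rules, SNP-probe sample-identity checks), the
interpercentile-range variable-CpG classifier (trim 10% per side, flag when
the remaining range is ≥ 0.05 beta), the Meng–Rosenthal–Rubin test for
comparing two overlapping dependent correlations

    Z = (z1 − z2) · sqrt( (n − 3) / (2 (1 − r_xy) h) ),

stratification by genic class / regulatory features / mQTL status / gene
sets plus a probe–gene–region query, classical (Torgerson) MDS with a
distance-versus-correlation regression, reference-based cell-composition
estimation (exact simplex-constrained least squares) and per-probe
residualization adjustment, and a deterministic synthetic multi-tissue
cohort generator whose latent cross-tissue correlation, cell mixtures and
QC failures are fully known — so every stage is verifiable without any
external data. See `vignettes/methconcord-methods.Rmd` for the models and
the design decisions.

## Worked example

```r
library(methconcord)

# synthetic 4-tissue cohort: 21 subjects, saliva ~70/30 leukocyte/epithelial,
# buccal ~20/80, blood ~pure leukocyte, brain neuron/glia
bundle <- generate_cohort(synth_config(n_probes = 5000, seed = 7))

cfg <- run_config(list(c("brain", "blood"), c("brain", "saliva")), seed = 7)
report <- run_pipeline(cfg, bundle = bundle)

report$correlation_matrix
#>   tissue_a tissue_b overall_r variable_r
#> 1    brain    blood     0.938      0.888
#> 2    brain   saliva     0.953      0.908
#> 3    brain   buccal     0.947      0.895
#> 4    blood   saliva     0.993      0.986
#> 5    blood   buccal     0.946      0.893
#> 6   saliva   buccal     0.977      0.953

report$concordance$brain_vs_saliva$summary_all
#> ConcordanceSummary [brain vs saliva]
#>   across-subject Pearson r : 0.953
#>   CpGs evaluated           : 4136 (+0 null)
#>   nominally correlated     : 58.6%
#>   moderately correlated    : 44.0%
#>   mean / median rho        : 0.455 / 0.473
#>   Bonferroni survivors     : 46 (p < 1.21e-05)
```

Reading it: the across-subject correlations are uniformly high and saliva is
the most brain-like peripheral tissue at the averaged-profile level (0.953) —
a consequence of its balanced cell mixture, not of shared brain signal —
while blood–saliva is the strongest peripheral pair (0.993). The
within-subject summary tells the complementary story: under the generator's
latent per-CpG correlation of 0.5, about 59% of CpGs reach nominal
significance at n = 21, and the "variable_r" column shows averaged-profile
correlations recomputed on just the variable CpGs, where they are
systematically lower. With a real cohort, replace the bundle with
`read_bundle()` on TSV beta matrices / sample sheet / annotation, or drive
everything from a YAML config via the `inst/exec/methconcord` script
(`simulate` and `run` subcommands).

The statistics used for headline claims are one-liners:

```r
bonferroni_threshold(0.05, 822996)
#> 6.075364e-08   # the genome-wide p < 6.1e-8 level for an EPIC-sized family

compare_dependent_correlations(0.90, 0.86, 0.97, 822996)
#> z = 322.8, p < 2.2e-308 (reported as a bound; underflow flagged)
```

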
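# metabomr

Metabolome-wide two-sample Mendelian randomization (MR) in R, tidyverse-style.

## The problem

Observational associations between circulating metabolites and downstream
traits — here motivated by reproductive-timing outcomes such as age at
menarche and age at natural menopause — are confounded and subject to reverse
causation. Two-sample MR sidesteps both by using genetic variants as
instruments: a SNP that robustly shifts a metabolite level is randomly
allocated at conception, so its association with the outcome, scaled by its
effect on the metabolite, estimates the causal effect of the metabolite.
Screening hundreds of metabolites this way requires a pipeline: instrument
selection and strength filtering, allele harmonization between the two GWAS,
robust estimation, pleiotropy and directionality diagnostics, colocalization
to separate shared causal variants from LD coincidence, enrichment of the
prioritized metabolites, and observational validation in a cohort.
`metabomr` implements that pipeline end to end over plain tibbles, plus
seeded generators that simulate GWAS summary statistics, LD panels and
cohort tables with known ground truth.

## The statistics at the core

For instrument `j` with exposure effect `β_xj` (SD of metabolite per allele)
and outcome effect `β_yj` (years per allele):

- **Wald ratio**: `θ̂_j = β_yj / β_xj`, `se = se_yj / |β_xj|`.
- **IVW**: weighted regression of `β_y` on `β_x` through the origin with
  weights `1/se_y²`; equivalently the inverse-variance-weighted mean of the
  Wald ratios. Default multiplicative random effects: the SE is inflated by
  `max(1, sqrt(Q/(k−1)))` with `Q` Cochran's heterogeneity statistic.
- **MR-Egger**: the same regression with a free intercept; a nonzero
  intercept indicates directional pleiotropy (InSIDE assumption).
- **Weighted median / weighted mode**: quantile- and mode-based estimators
  robust to invalid instruments.
- **Instrument strength**: per-SNP variance explained `r² = 2β²f(1−f)` and
  the global `F = (R²/k) / ((1−R²)/(n−k−1))`; metabolites with `F < 10` are
  excluded.
- **MR-PRESSO-style outlier test**: the observed leave-one-out weighted
  residual sum of squares is compared against a parametric simulation null;
  outliers are flagged at a Bonferroni-corrected rank p and removed.
- **Colocalization**: per-SNP Wakefield log approximate Bayes factors,
  `log ABF = ½(log(1−r) + r z²)` with `r = sd₀²/(sd₀²+se²)`, combined over
  the single-causal-variant configurations into posteriors for H0–H4 with
  priors `p1 = p2 = 1e-4`, `p12 = 1e-5`; a metabolite colocalizes when
  `PP(H4) > 0.8` in any instrument region.
- **Enrichment**: one-tailed hypergeometric over-representation with BH FDR.

## Worked example

```r
library(metabomr)

study <- simulate_study(n_metabolites = 10, n_causal = 2, theta = 0.2, seed = 42)
res <- run_pipeline(study, study_config(seed = 42))
res
#> <mr_study>
#>   tested: 10  prioritized: 2  colocalized: 2
#>   tables: instruments, mr, sensitivity, mvmr, coloc, coloc_verdict, ...

dplyr::select(tidy(res), exposure, n_snp, estimate, se, p, fdr_q)
#> # A tibble: 10 x 6
#>   exposure n_snp estimate     se        p    fdr_q
#> 1 met_001      3   0.229  0.0170 3.45e-41 3.45e-40
#> 2 met_002      3   0.192  0.0182 6.73e-26 3.36e-25
#> 3 met_003      3  -0.0445 0.0562 4.29e- 1 7.15e- 1
#> ...

res$coloc_verdict
#> # A tibble: 2 x 4
#>   metabolite n_regions max_pp_h4 colocalized
#> 1 met_001            3     1.000 TRUE
#> 2 met_002            3     1.000 TRUE
```

The two metabolites simulated with a true causal effect (`theta = 0.2` years
per SD) are recovered with estimates near 0.2, pass the FDR gate, and their
instrument regions colocalize with the outcome (`PP(H4) ≈ 1`); the eight
null metabolites are not prioritized. `autoplot(res)` draws the forest plot,
`plot_coloc(res$coloc)` the posterior decomposition, and
`write_results(res, "out/")` serializes every table as TSV with a run
manifest.

Real summary statistics enter through `read_summary_stats(path, dialect)`,
where the dialect (a named list or YAML file) maps the file's column names
onto `snp/chr/pos/ea/oa/eaf/beta/se/p/n`.

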
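---
title: "Methods: metabolome-wide two-sample MR with metabomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-wide two-sample MR with metabomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

## The causal model and its assumptions

`metabomr` analyzes the linear structural model behind two-sample Mendelian
randomization. A metabolite level $X$ (in SD units) is shifted by $k$ genetic
variants with per-allele effects $b_j$; an outcome $Y$ (in years, e.g. an age
at a reproductive event) depends on the metabolite through a causal effect
$\theta$ and possibly on variant $j$ directly through a pleiotropic effect
$\alpha_j$:

$$\beta_{yj} = \theta\, b_j + \alpha_j.$$

Valid instruments satisfy three assumptions: (1) *relevance* — the variant is
robustly associated with the metabolite; (2) *independence* — it is not
associated with confounders of the metabolite–outcome relation; and
(3) *exclusion restriction* — $\alpha_j = 0$. The package enforces relevance
directly (genome-wide significance, LD clumping, the $F$-statistic filter),
probes exclusion through the Egger intercept, the
residual-sum-of-squares outlier test and Cochran's $Q$, addresses
directionality with Steiger filtering and bidirectional MR, and addresses the
shared-variant question with approximate-Bayes-factor colocalization.
Independence cannot be tested from summary data; the multivariable model with
BMI as a second exposure probes the single most plausible violation in this
application domain.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `p_iv` | 5e-8 | instrument significance threshold (inclusive) |
| `clump_r2`, `window_kb` | 0.001, 500 | LD pruning: discard neighbours within ±500 kb at $r^2 \ge$ 0.001 |
| `proxy_r2` | 0.8 | minimum $r^2$ for an LD proxy of an outcome-missing SNP |
| `f_min` | 10 | weak-instrument cut on the global $F$; boundary kept, "below" excluded |
| `fdr` | 0.05 | BH q-value gate defining the prioritized set |
| `p1`, `p2`, `p12` | 1e-4, 1e-4, 1e-5 | colocalization priors per SNP |
| `coloc_half_width` | 5e5 bp | region half-width: the stated 1 Mb total span is read as ±500 kb around the instrument |
| `maf_min` | 0.01 | MAF floor inside colocalization regions |
| `h4` | 0.8 | colocalization verdict: strict `max PP(H4) > 0.8` over a metabolite's regions |
| `early_cutoff` | 45 years | early-menopause exclusion in validation models |
| `palindrome_maf_limit` | 0.42 | A/T and C/G SNPs are frequency-oriented only below this minor-allele frequency, else dropped |

The global $R^2$ entering $F$ is the *sum* of per-SNP $2\beta^2f(1-f)$
values, valid because clumped instruments are near-independent. The clumping
window is interpreted as ±`window_kb` around the index SNP; both the window
convention and the region half-width are configurable because the verbal
conventions in the field are ambiguous.

## Estimator conventions

IVW defaults to multiplicative random effects: the fixed-effect SE is scaled
by $\max(1, \sqrt{Q/(k-1)})$, never below the fixed-effect SE. MR-Egger uses
the same floor-at-1 residual scale, orients all exposure effects
non-negative (flipping pairs jointly), and refers both coefficients to the
two-sided normal distribution — the same reference as IVW; in null
simulations this combination is well calibrated, whereas the $t_{k-2}$
reference stacked on the variance floor is conservative. Weighted-median
interpolation follows the percentile rule on the standardized cumulative
weights ($S_j - w_j/2$, crossing 0.5); the weighted mode uses a Gaussian
kernel with the modified Silverman bandwidth
$0.9\,\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$, ignoring a zero component
(all-identical ratios return that ratio directly). Both report seeded
parametric-bootstrap SEs (defaults: 1000 draws standalone, 500 in the
pipeline). Estimators below their instrument minimum (2 for IVW as a
meta-analysis, 3 for Egger/median/mode, exposures+1 for multivariable MR, 4
for the outlier test) return explicit not-computable marker rows rather than
errors, so pipeline tables mirror the blanks of a supplementary table.

The outlier (MR-PRESSO-style) test simulates its null by redrawing both
effect vectors from their estimated sampling distributions under the
leave-one-out IVW fits and compares weighted residual sums of squares by
rank, with the $+1$ correction (minimum attainable p of $1/(n_{sim}+1)$).
Per-SNP outlier p-values are reported from the first round, but *flagging*
is iterative — remove the single most extreme sub-threshold SNP, refit,
repeat — because while a strong outlier remains in the set it contaminates
every leave-one-out slope and would implicate innocent instruments.

Steiger filtering compares $2\beta^2f(1-f)$ between the two studies per SNP
(both traits standardized; the $t^2/(t^2+n-2)$ fallback is used when the
frequency is missing), with a Fisher-z two-sample test; the aggregate
verdict is all-SNPs-pass, matching its use as a filter.

Colocalization is computed entirely in log space with log-sum-exp, because a
50-SNP region with $z = 8$ signals overflows the linear scale. H3 uses the
log-difference identity
$\sum_{i \ne j} = \sum_i \sum_j - \sum_{i=j}$; a single-SNP region therefore
has $PP(H_3) = 0$ exactly, and $p_{12} = 0$ gives $PP(H_4) = 0$ exactly.
The effect prior SD is 0.15 per trait (the quantitative-trait convention of
the field's standard implementation), via the beta/se route.

## What the generators emulate — and what they do not

`simulate_ld_panel()` produces block-diagonal AR(1) LD ($r = \rho^{|i-j|}$
within a block, 0 across blocks, blocks > 500 kb apart), which gives exact
closed-form $r^2$ for clumping and proxy tests. `simulate_gwas_pair()` draws
summary statistics directly on the effect scale: marginal means $Rb$ (so LD
neighbours of a causal SNP carry signal, exercising clumping), noise
correlated by $R$ with the standardized-trait SE $1/\sqrt{2f(1-f)n}$, which
reduces to independent $\hat\beta_j \sim N(b_j, se_j^2)$ draws for an LD-free
panel. A configurable fraction of outcome records is emitted with swapped
(0.1) or strand-flipped (0.05) allele labels, and panels can carry
palindromic allele pairs, to exercise harmonization deterministically under
the seed. `simulate_cohort()` generates event ages linear in the metabolite
and BMI with optional early-event contamination and missingness in the
childhood BMI z-score columns.

Not emulated: genotype-level sampling (no coalescent or forward simulation),
winner's-curse selection effects, sample overlap between the two GWAS,
heritability architecture beyond the explicit per-SNP effects, non-linear
exposure–outcome relations, and platform differences between metabolite
assays. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact of real
GWAS data.

True per-SNP effects in the calibration fixtures vary across instruments
(uniform on 0.05–0.25 SD/allele at $n_{exp} = 50{,}000$, giving global
$F > 30$): heterogeneous instrument strength is both realistic and required
— MR-Egger is unidentified when all true effects coincide (the
regression has no spread in $x$).

## Design choices on genuinely open points

- **FDR family**: q-values pool all metabolites tested against one outcome
  (configurable), rather than splitting by exposure-source GWAS.
- **Palindromic SNPs**: frequency-based orientation below a 0.42
  minor-allele-frequency limit, else dropped — the convention of the
  two-sample MR tooling ecosystem.
- **Imputation order**: missing age-8 BMI z-scores take the age-7 value
  first, age-9 second; the adjacent-age rule is stated unordered in the
  field, so the priority is fixed and documented here.
- **z-scoring** uses the sample SD ($n-1$).
- **Proxy orientation** uses the signed panel correlation; $r^2$ alone
  cannot orient alleles. Ties in $r^2$ break by base-pair distance, then id.
- **Colocalization regions**: one run per instrument SNP per metabolite, the
  verdict taking the maximum $PP(H_4)$ — the "at least one instrument
  region" reading.
- **Sensitivity/colocalization scope**: only FDR-prioritized metabolites by
  default (`sensitivity_all = TRUE` widens it), matching the study design
  the pipeline mirrors.
- **Instrument counts per metabolite** are a generator parameter
  (`blocks_per_metabolite`, default 3), not a fixed constant.

## Problem sizes and tolerances

The test suite and the acceptance script use desk-scale sizes chosen for
minutes-scale runtimes on a single CPU: 500 replicates in the suite (300 in
the faster acceptance script) for parameter recovery and null calibration
(IVW bias < 0.01, CI coverage in 0.92–0.97, rejection rates 0.05 ± 0.03),
1000 random instrument sets for the
estimator-oracle identity at $10^{-12}$, 1000 simulations per outlier test,
50-SNP regions for colocalization (posterior sums within $10^{-9}$), and
100 seeds × 50 metabolites (5 causal, $\theta = 0.2$) for the end-to-end
funnel with a ≥ 90% full-recovery requirement. Exact brute-force enumeration
backs the hypergeometric p-values for universes up to 15.

## Known limitations

Correlated instruments are not modelled in the IVW (clumping is assumed to
have removed LD); colocalization assumes a single causal variant per trait
per region; the outlier test's simulation null conditions on the estimated
leave-one-out slopes, so its p-values are approximate in small sets;
bootstrap SEs for median/mode estimators inherit Monte Carlo error of order
$1/\sqrt{n_{boot}}$; and the validation regressions are ordinary least
squares — no censoring model for women who have not yet reached the event.
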
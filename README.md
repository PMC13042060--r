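# strivar

Statistical toolkit for characterizing **inter-individual variation** in
multi-donor, multi-region single-nucleus RNA-seq studies of the human
striatum and cortex. It is written for analysts of village-design snRNA-seq
cohorts (tissue from ~20 donors pooled per experiment, nuclei reassigned to
donors via transcribed genetic variants) who want to ask: which cellular and
molecular features differ from person to person, how are they shaped by age,
sex, and common genetic variation, and how consistently do they reappear
across a donor's brain regions?

## What it computes

* **Cell-type abundance** — beta-binomial regression of per-sample counts
  `k` out of `N` with a logit link:
  `logit μ = b_region + β_age · (age − 60)/10 + β_sex`, overdispersion
  `ρ ∈ [0,1)` so `Var(k) = Nμ(1−μ){1+(N−1)ρ}`. Slopes read as log-odds per
  decade of age. Inference is cluster-robust on donor (donors are sampled in
  several regions), with BH correction over explicitly declared test
  families. Derived summaries: lifespan decline `1 − exp(β·span)`,
  cross-region Spearman correlation of abundance residuals, and a
  conservative median fold-difference between two random donors,
  `exp(0.9539·σ_shared)`, from the covariance of two regions' log fractions.
* **Differential expression by age and sex** — per-gene weighted linear
  models on log2 CPM pseudobulk (effects in log2 fold change per decade),
  cross-cell-type effect correlations, k-means clustering of gene age
  profiles, and a moment-based **transcriptome-wide impact** estimator,
  `mean(β̂² − SE²)`, that compares the magnitude of true age effects across
  cell types without power confounding.
* **Transcriptional aging clocks** — elastic-net age prediction per cell
  type with strictly out-of-sample (nested CV) predictions, a GAM bias
  curve that removes shrinkage toward the cohort mean, cross-cell-type
  correlation of corrected age residuals, and Jaccard overlap of clock
  gene sets.
* **cis-eQTL mapping** — inverse-normal-transformed expression regressed on
  dosage (±1 Mb, Bonferroni-then-BH eGene calls at FDR 0.01), a
  sign-oriented eQTL × cell-type effect matrix, K-means effect-pattern
  clustering (K = 13), pairwise sharing ρ², and a constraint-vs-effect-size
  test.
* **Village QC** — expected genotypic-doublet fraction `1 − Σp_i²`, total
  doublet rate inversion, doublet-enriched cluster flagging, and data-driven
  sample exclusion (low ascertainment + CLR/robust-z compositional
  outliers).
* **Synthetic cohort generator** — multi-region cohorts (counts, metadata,
  genotypes, pseudobulk expression) with donor-level propensities shared
  across regions, age/sex/eQTL effects, and a truth record, so every
  estimator above is validated by parameter recovery without any data
  download.

## Worked example

Simulate a cohort at the default study conditions (150 donors aged 27–90,
five brain regions, ~5,000 nuclei per sample, OPC abundance declining at
−0.096 log-odds per decade), then fit the abundance model:

```r
library(strivar)

cfg    <- cohort_config(seed = 42)
cohort <- generate_cohort(cfg)
counts <- generate_cell_counts(cohort$donors, cohort$truth, cfg)

obs <- abundance_observations(counts, cohort$donors, "OPC")
fit <- fit_beta_binomial(obs)
tidy(fit)
#> # A tibble: 7 × 9
#>   term      estimate std_error std_error_model statistic p_value p_lrt conf_low
#>   <chr>        <dbl>     <dbl>           <dbl>     <dbl>   <dbl> <dbl>    <dbl>
#> 1 regionCaH    -3.45    0.0305          0.0237     -113.       0    NA    -3.51
#> 2 regionDFC    -3.43    0.0316          0.0237     -109.       0    NA    -3.49
#> 3 regionic     -3.28    0.0310          0.0224     -106.       0    NA    -3.34
#> # … 4 more rows (remaining regions, age_decade, sexM)
glance(fit)
#> # A tibble: 1 × 6
#>   logLik     rho n_obs n_donors converged se_type
#> 1 -3801. 0.00184   750      150 TRUE      cluster
```

The fitted age slope (−0.102 log-odds per decade for this seed; generating
value −0.096, cluster-robust SE ≈ 0.008) converts to a lifespan decline:

```r
beta <- tidy(fit)$estimate[tidy(fit)$term == "age_decade"]
decline_over_span(beta, span_decades = 5)
#>   beta_age span_decades decline
#> 1   -0.102            5   0.399
```

i.e. roughly a 40% drop in OPC representation between ages 30 and 80. The
donor-level deviations from the age trend are correlated between every pair
of regions — a donor with more OPCs than expected for their age in one
region tends to have more everywhere:

```r
res <- age_residuals(obs, fit)
cross_region_correlation(
  dplyr::select(res, donor_id, region, value = residual),
  family_size = 498)
#> # A tibble: 10 × 6
#>    region_a region_b n_shared   rho  p_value  q_value
#>  1 CaH      Pu            150 0.597 6.95e-16 1.15e-13
#>  2 CaH      NAC           150 0.496 1.09e-10 5.42e- 9
#>  3 CaH      ic            150 0.600 4.70e-16 1.15e-13
#>  # … 7 more pairs, all positive, all q < 1e-8
```

The same pattern extends to expression: `generate_pseudobulk()` +
`fit_age_sex_de()` give per-decade log2FCs, `train_clock()` +
`fit_bias_curve()` give corrected age residuals, and `map_cis_eqtls()` +
`build_effect_matrix()` + `cluster_eqtls()` give cell-type-resolved genetic
effect patterns. See the methods vignette
(`vignettes/strivar-methods.Rmd`) for the models and design decisions.

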
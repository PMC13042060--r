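---
title: "Models and methods behind strivar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strivar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strivar analyzes inter-individual variation in multi-donor, multi-region
single-nucleus RNA-seq studies of the human striatum and cortex: how
cell-type abundances and gene expression differ from person to person, how
those differences are shaped by age, sex and common genetic variation, and
how much of a donor's deviation reappears across their brain regions. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where more than one defensible choice
existed. Every empirical statement here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The synthetic cohort generator

Real cohorts of this kind (hundreds of donors, millions of nuclei) cannot
ship with a package, so every analysis is validated against a generator
that reproduces the statistical structure the analyses assume, together
with a truth record sufficient to regenerate every observable from a seed.

**Demographics.** Ages are uniform on a configurable range (default 27-90
years) and capped at 90, reflecting the common brain-bank convention that
precise ages above 89 are withheld; sexes are Bernoulli draws; donors are
assigned to pooled "villages" of ~20.

**Abundance.** For donor $i$, region $r$, cell type $g$ the latent
fraction is
$$\mathrm{logit}\, p_{igr} = b_{gr} + \beta_g \frac{\text{age}_i - 60}{10}
  + u_{ig} + e_{igr}, \qquad
  u_{ig} \sim N(0, \tau_g^2),\; e_{igr} \sim N(0, \sigma_g^2),$$
where $u_{ig}$ is a donor-level propensity shared by all of that donor's
regions and $e_{igr}$ is sample noise. Counts are a single multinomial
draw over the named cell types plus an explicit remainder class. This
guarantees compositional closure (counts sum to the sample's nuclei) while
keeping each type's marginal logit exactly equal to its linear predictor;
a joint softmax would couple the marginals and break the exactness that
the noise-free checks rely on. Age is centered at 60 and scaled to decades
everywhere so slopes read as log-odds per decade.

The default panel (nine striatal/cortical cell types, OPC slope -0.096
per decade, ~5,000 nuclei per sample, 150 donors, 5 regions) constitutes
the study conditions under which all recovery tests run. Variances default
to $\tau^2 = 0.04$, $\sigma^2 = 0.02$ for OPCs and comparable values
elsewhere — enough donor-level spread that cross-region sharing is
detectable without swamping the age signal.

**Calibrating cross-region sharing.** The quantity reported for glial
abundances is the squared Pearson correlation ($r^2$) of a cell type's
observed *fractions* between two regions. Three separate layers separate
that observable from $\tau^2$: the correlation of latent logits is
$\tau^2/(\tau^2+\sigma^2)$ (not its square), the logit-to-fraction map is
nonlinear, and binomial sampling at ~5,000 nuclei adds noise. Setting
$\tau^2/(\tau^2+\sigma^2)$ equal to a target $r^2$ directly would produce
an observed $r^2$ near the target's *square* and make recovery impossible.
`calibrate_sharing()` therefore solves for $\tau^2$ (holding
$\tau^2+\sigma^2$ fixed, default 0.1) such that the TRUE squared Pearson
correlation of observed fractions equals the target, computing the
fraction-scale moments by two-dimensional Gauss-Hermite quadrature (40
nodes) with the binomial variance term included. The residual discrepancy
seen in recovery runs (~0.005-0.015) is the ordinary finite-sample bias of
a sample correlation at n = 114 donors, not a calibration error.

**Expression.** Pseudobulk counts are negative binomial (dispersion 0.2 by
default; 0 gives noise-free expectations) around
$\mu = L_i \cdot 2^{\ell_{ij}}/10^6$ with log-normal library sizes
($\log L \sim N(15, 0.3^2)$) and
$$\ell_{ij} = \text{base}_j + \gamma_{jc}\frac{\text{age}_i + b_i - 60}{10}
  + s_j\, \mathbb{1}[\text{male}] + \beta^{\text{eQTL}}_{jc} d_{i},$$
where $\gamma_{jc}$ is the per-decade log2 fold change in cell type $c$,
sex effects $s_j$ exist only on sex-chromosome genes (Y genes are silent
in XX donors; X-escape genes are elevated in XX donors), $d_i$ is the
dosage of the gene's cis SNP (Hardy-Weinberg draws, SNPs independent),
and $b_i$ is an optional donor-level "biological age" offset (default off;
switched on to probe whether clocks run fast or slow together). The
negative-binomial dispersion and library-size parameters are plausible
values for pseudobulk aggregates, not fitted claims.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: droplet-level artifacts (ambient RNA,
UMI saturation), linkage disequilibrium between SNPs, batch/village
technical effects on expression, non-uniform age distributions,
covariance between abundance and expression noise, and spatial structure.
The generator exposes a covariate hook but simulates none beyond age and
sex by default.

## Cell-type abundance: beta-binomial regression

Each cell type is modeled marginally: counts $k$ out of denominator $N$
follow a beta-binomial with logit-linked mean (region intercepts, age in
centered decades, sex) and overdispersion $\rho \in [0,1)$ parameterized
as shape parameters $a = \mu(1-\rho)/\rho$, $b = (1-\mu)(1-\rho)/\rho$, so
$\mathrm{Var}(k) = N\mu(1-\mu)\{1+(N-1)\rho\}$. Sampling variability in
nuclei counts is handled by the denominator itself. Optimization is BFGS
from a binomial-GLM warm start with $\rho$ on the logit scale, restarted
once from the first optimum; non-convergence is reported, never silent.
On small instances the optimum matches an independent iterative
grid-search MLE to $10^{-4}$ log-likelihood units, and estimates agree
with glmmTMB's independent beta-binomial implementation.

**Why cluster-robust inference is the default.** Donors are sampled in up
to five regions and carry a shared propensity $u_{ig}$, so a donor's
observations are positively correlated while the marginal model treats
them as independent. For a donor-level covariate such as age this makes
model-based Wald intervals severely anti-conservative (~70% coverage at
the default design, verified by simulation). When any donor contributes
more than one observation, the reported SEs, CIs and p-values therefore
use a sandwich estimator clustered on donor with a $G/(G-1)$ correction;
model-based Wald SEs and likelihood-ratio p-values are reported alongside.
With this choice, 95% CIs cover the generating slope in >=90% of 200
cohort replicates and null discovery rates are calibrated.

**Denominators.** The abundance of a type can be expressed relative to all
nuclei (glia), to all neurons (interneurons), or to an explicit set such
as MSNs (interneuron displays, MSN subtype ratios);
`abundance_observations()` builds the (k, N) pairs for any of the three.

**Derived summaries.** `decline_over_span()` converts a slope to a
fractional decline, $1-e^{\beta s}$, exact on the odds scale and a good
approximation of the fraction scale for rare types (the exact
fraction-scale decline is reported when a baseline is supplied).
`pairwise_fold_difference()` isolates the component of inter-individual
variation shared between two regions — the sample covariance of the two
regions' log fractions, clipped at zero — and reports the median
fold-difference between two random donors,
$\exp(0.9539\sqrt{\hat\sigma^2_{\text{shared}}})$ (the median of
$|X - Y|$ for independent normals), with a parametric bootstrap CI. A
negative covariance returns fold 1.0 with a warning flag rather than an
imaginary answer. BH correction always takes an explicit family size, so
fixed families (44 abundance tests, 498 cross-region correlations) can be
declared even when only partially materialized.

## Pseudobulk differential expression

Counts are aggregated per (donor, cell type, region), normalized to
$\log_2(\text{CPM}+1)$, and each gene is fit by a linear model on age
(decades), sex and declared covariates, weighted by the log cell count of
the donor (deeper profiles are less noisy). A Gaussian model on log2 CPM
was chosen over a count GLM because pseudobulk aggregation makes the
normal approximation serviceable and keeps every estimator checkable
against a closed-form least-squares oracle; a count-model option would be
an extension, not a correction. Genes expressed in fewer than 25% of
donors are skipped; BH runs within (cell type, region, test).

Effect profiles (genes x cell types of per-decade log2FCs) include genes
significant at q < 0.05 in at least one cell type — the inclusion rule is
a package decision, configurable, since only the resulting gene count is
conventionally reported. Cross-cell-type Spearman correlations are
computed on union-significant genes with an all-genes variant alongside.
Gene-profile k-means uses 50 restarts under a fixed seed; K defaults to 8
for gene profiles and 13 for eQTL patterns.

**Transcriptome-wide impact (TWI, simplified).** Because the number of
significant genes mostly measures statistical power, the package
summarizes how strongly age reshapes a cell type's transcriptome by a
method-of-moments deconvolution: each squared estimate overstates the
squared true effect by its squared standard error, so
$\widehat{\mathrm{TWI}} = \frac{1}{G}\sum_j (\hat\beta_j^2 - s_j^2)$
estimates the mean squared true effect unbiasedly, with a gene-level
bootstrap SE. This is deliberately only the first moment of the effect
distribution — a full distributional deconvolution is out of scope — and
pure-noise genes contribute zero in expectation, which the tests verify.

## Transcriptional aging clocks

Per cell type, donor age is regressed on the standardized log2 CPM of that
cell type's age-associated genes by elastic net (mixing $\alpha = 0.5$;
$\lambda$ from an inner 5-fold CV). Predictions are strictly out of
sample: an outer 10-fold CV yields one held-out prediction per donor, with
standardization and penalty selection confined to each training fold
(glmnet standardizes internally on the training data). Repeating the
outer CV over 20 fold assignments gives a per-donor prediction SD.
Out-of-sample prediction was chosen over in-sample fitting as the
defensible default wherever the convention is unstated; the CV scheme is
recorded in the model object.

Clock predictions shrink toward the cohort mean, so raw residuals are
age-correlated. A penalized cubic-spline Gaussian additive model
(mgcv, smoothness by GCV) of predicted on chronological age defines the
expected prediction at each age; corrected residuals are deviations from
this curve and have exactly zero Pearson correlation with the fitted
relationship by construction (the rank correlation retains ordinary
$1/\sqrt{n}$ sampling noise). Cross-cell-type correlations of corrected
residuals — the "clocks run fast or slow together" signal — use Spearman
by default with Pearson alongside; gene-set overlap between models is the
Jaccard index of nonzero-coefficient sets.

## Cell-type-resolved cis-eQTL mapping

Expression is inverse-normal transformed (Blom offset
$(r - 3/8)/(n + 1/4)$, average ranks for ties) and regressed on SNP dosage
with age and sex as nuisance covariates (expression-PC correction is
deliberately not default). Within +/-1 Mb of the TSS (configurable), the
lead SNP is the minimum-p SNP; the gene-level p is Bonferroni (min p times
the number of cis SNPs, capped at 1), and BH across genes within each cell
type calls eGenes at FDR 0.01. Bonferroni-then-BH was chosen over
permutation gene-level p-values for speed and conservatism; genes with no
cis SNP are reported as NA rows, never dropped.

For the effect matrix, each eGene's lead SNP is taken from the cell type
with the smallest gene-level p and its standardized per-allele effect
recomputed in every cell type — reconciling per-cell-type discovery with
one row per eQTL. Rows are sign-oriented so the most common effect
direction is positive; only entries of at least 25% of the row's maximum
|effect| vote, because a single strong negative effect must not be
outvoted by noise-level signs in unaffected cell types (ties fall back to
the sign of the row sum; orienting twice changes nothing). Effects are
kept both on the standardized scale (clustering) and as fold-change
magnitudes (the constraint analysis, which reports a Spearman correlation
of |effect| with the constraint score plus a two-group Wilcoxon).
Discovered cell-type specificity is a lower bound on true specificity:
specific effects have fewer chances to reach significance, so the shared
fraction is biased upward.

## Village QC and doublet accounting

In a pooled village with donor proportions $p_i$, a random doublet is
detectable from mixed genotypes with probability $1 - \sum_i p_i^2$
(maximized at equal pooling: 0.95 for 20 donors), so the total doublet
rate is the observed genotypic-doublet rate divided by that factor.
Cluster-level flagging tests each cluster's genotypic-doublet count
against the dataset-wide rate (one-sided binomial, BH across clusters) and
additionally requires at least 2x enrichment, so that very large clusters
with trivial excess are not flagged. Expression-based classification of
same-donor doublets is out of scope; cluster-level flagging is the
implemented use of genotypic doublets.

Sample exclusion mirrors data-driven (not metadata-driven) curation: low
ascertainment (< 500 nuclei by default) and compositional outliers — CLR
transform with pseudocount 0.5 on zero counts (zeros occur for sparse
interneurons), per-region robust z (median/MAD), excluded when
max |z| > 4. The thresholds are exposed because only the resulting
exclusion fractions, not the rule, are conventionally reported; every
exclusion carries a machine-readable reason.

## Numerical choices and degenerate inputs

* Beta-binomial: $\rho$ optimized as $\mathrm{logit}(\rho)$, started at
  0.02; `fix_rho` near 0 reproduces binomial logistic regression exactly
  (used by the limit tests). Mean clamped to $[10^{-12}, 1-10^{-12}]$.
* Per-observation scores for the sandwich use central differences with
  step $10^{-6}(|\theta|+10^{-3})$; a singular information matrix falls
  back to a pseudoinverse with a warning.
* k-means: 50 restarts, `iter.max = 100`, seed-scoped RNG (the caller's
  RNG state is restored); the Lloyd objective is verified non-increasing.
* Ridge/elastic-net oracle checks account for glmnet's internal scaling of
  the Gaussian response by its population SD.
* Constant clock features are dropped with a warning; fewer than 4
  distinct ages, all-identical INT inputs, empty Jaccard unions,
  single-donor villages, and all-samples-excluded QC are errors, not
  silent results.

## Problem sizes

The test suite validates estimator equivalences on small instances
(8-12 observations for grid-search oracles) and runs parameter-recovery
batteries at the full study conditions: 200 cohort replicates of 150
donors x 5 regions for abundance-slope recovery and coverage, 200
replicates for each null-calibration battery (abundance, DE, eGenes), 200
replicates of 114 paired donors for cross-region sharing, and 20
replicates for clock residual behavior. `scripts/acceptance.R` re-runs the
recovery quantities at the same sizes (about 3 minutes on one CPU). These
sizes are the package's validation conventions; all are arguments, not
constants.

## Known limitations

The abundance model is marginal per cell type, so it does not enforce
joint compositional constraints during inference (the generator does, via
closure). The TWI estimator reports one moment of the effect-size
distribution and can go slightly negative under the null. Clock models are
dataset-internal: coefficients are not transferable across datasets.
eQTL mapping tests single-SNP dosage only — no haplotypes, trans effects,
conditional signals or colocalization. The fold-difference summary assumes
approximately log-normal shared variation. And all validation is against
the generator's assumptions; features absent from the generator (see
above) are untested by construction.
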
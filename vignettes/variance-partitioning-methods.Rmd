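---
title: "Methods: partitioning feed-efficiency variance between host genetics and the gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning feed-efficiency variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were
genuinely open. Everything quantitative asserted here is computed by the
test suite or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## 1. Residual feed intake

`compute_rfi()` defines RFI as the ordinary-least-squares residual of
average daily feed intake on average daily gain and metabolic mid-weight,

$$\mathrm{ADFI} = \beta_0 + \beta_1\,\mathrm{ADG} + \beta_2\,\mathrm{MMW} + \mathrm{RFI},$$

with MMW the mid-test average body weight raised to 0.75, the standard
metabolic exponent relating body mass to maintenance energy. ADG enters
linearly; no quadratic or test-period terms are used. By the normal
equations RFI has exactly zero mean and zero correlation with both
regressors, which the tests verify to 1e-8. The fit refuses collinear
designs (condition number of the cross-product above 1e12) and fewer
than 4 records.

## 2. Relationship matrices

**Genomic (GRM).** VanRaden method 1 on minor-allele counts:
$G = ZZ^\top / (2\sum_j p_j(1-p_j))$ with $Z = X - 2p$. All genotypes
are recoded to minor-allele counts per SNP on input, so allele
frequencies and effect signs are reproducible regardless of the
reference orientation of the source file. Missing genotypes are
mean-imputed per SNP before matrix algebra (`impute_genotypes()`); LD
`ld_r2()` instead uses pairwise-complete observations, since imputation
would bias the genotype correlation toward zero.

**Microbial (MRM).** Per-taxon $\log_{10}(\text{abundance} +
\text{pseudocount})$, columns standardized to zero mean and unit sample
variance, then $M = SS^\top/q$. Taxa with zero variance on the log
scale are dropped. The pseudocount is half the smallest nonzero relative
abundance in the table — scale-adaptive, so the MRM is invariant to a
global rescaling of the raw counts followed by renormalization; a fixed
1e-6 would not be.

**Bray-Curtis.** $\mathrm{BC}(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i +
y_i)$, computed via `vegan::vegdist`, reported as similarity
$1-\mathrm{BC}$ for the resampling stage.

**Kinship strata.** Pairs with GRM entry ≤ 0.05 are "distant", ≥ 0.10
"close", the rest intermediate and excluded. Kinship is the GRM entry
directly, with no /2 conversion — the thresholds are defined on the
same scale on which they are applied, so they remain interpretable. The
boundary values are included in their strata (≤ and ≥, not < and >); the
difference is measure-zero but fixing it makes the classification
deterministic.

## 3. REML variance components

`reml_fit()` fits $y = Q\alpha + u + e$, $u \sim N(0, K\sigma^2_u)$,
$e \sim N(0, I\sigma^2_e)$ for a single relationship matrix $K$ (GRM for
heritability, a site's MRM for microbiability). $K$ is eigendecomposed
once; in the rotated coordinates the covariance is diagonal in the
variance ratio $h = \sigma^2_u/(\sigma^2_u+\sigma^2_e)$, and the
restricted log-likelihood — profiled over $\alpha$ and the total
variance — is maximized over $h \in [0,1]$ by bounded one-dimensional
optimization at tolerance 1e-8, with the endpoints checked explicitly
because the optimizer never evaluates them. This is exact for one
component and has no convergence tuning, unlike AI-REML. The tests
confirm the returned optimum dominates a 1,001-point likelihood grid and
agrees with the grid argmax within 0.002.

$\sigma^2_p$ is defined as $\sigma^2_u + \sigma^2_e$ after covariate
projection; covariate-explained variance is not counted in the
denominator. The ratio's standard error comes from finite-difference
curvature of the profile likelihood at the optimum (step 1e-4) and is
`NA` at a boundary, where the quadratic approximation fails; boundary
fits are flagged instead. A $K$ proportional to the identity makes the
components unidentifiable (the likelihood is flat in $h$) and triggers a
warning.

`variance_explained()` assembles the covariates: an intercept plus the
top 5 genomic principal components always; for microbiability
additionally the first 3 principal components of trait-associated SNPs
when supplied, so the microbial estimate is conditioned on the host
genetic signal. PCA scores come from the GRM eigendecomposition; because
the GRM is built from column-centered genotypes, non-null scores have
exactly zero mean, and the sign convention (largest-magnitude score
positive) makes them deterministic.

## 4. Mixed-model association scan

`lmm_gwas()` tests each SNP in $y = Q\alpha + x\beta + u + e$. The
variance ratio is estimated once under the null and reused for every
marker — the score-style approximation that makes genome-wide scans
practical; re-optimizing per SNP changes third-decimal p-values at
100–1,000× the cost. With weights fixed, each SNP reduces to generalized
least squares in the rotated coordinates, and the likelihood-ratio
statistic is $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ against
$\chi^2_1$. When $G = I$ the procedure collapses to OLS plus an LR
test; the tests verify this equivalence to 1e-6, and the acceptance
suite verifies null calibration (fraction of p < 0.05 within
0.05 ± 0.01 on 10,000 null SNPs over a polygenic background).

One caveat the tests made explicit: with only a few hundred markers, a
tested SNP's own effect is partly absorbed by the GRM ("proximal
contamination"), costing real power; the power test therefore builds the
GRM leaving the tested SNP out. At genome scale (millions of markers)
the contamination is negligible.

**Thresholds.** `bonferroni_threshold(alpha, n)` is plain
$\alpha/n$. The suggestive threshold divides by the simpleM effective
test count instead: per non-overlapping block of SNPs (default 1,000,
which bounds the eigendecomposition cost), the smallest number of
leading eigenvalues of the genotype correlation matrix whose sum reaches
99.5% of the total, summed over blocks. Duplicated SNPs halve the
count; orthogonal SNPs leave it untouched.

## 5. Two-part taxon association and group screens

Taxa detected in more than 30% of samples are tested in two parts:
presence/absence (0/1 regressor; its slope equals the present-vs-absent
mean difference in the trait) and log10 relative abundance among present
samples only. Both parts include an intercept and a residual error
term; the model description we implement labels $e$ ambiguously, and a
regression with an intercept but no error term is not estimable, so
both are present. BH adjustment is applied separately within each part
across taxa — the two parts answer different questions (does carrying
the taxon matter vs does its level matter) and are reported separately,
so pooling them into one family would mix the two discovery lists. A
taxon present in every sample has a constant binary regressor; that part
is flagged `NA` and the quantitative part still runs.

`extreme_group_screen()` adds two non-parametric confirmations per
taxon: ANOVA on the trait between the top-k and bottom-k abundance
samples, and a Wilcoxon rank-sum on abundance between the top-k and
bottom-k trait samples (k = 40 by default, matching the design scale
the screen is meant for; callers with smaller cohorts lower k). Ranks
are tie-broken by sample order so the grouping is deterministic. A
taxon is called overall significant only when the two-part model and
both screens pass at BH-adjusted p < 0.05.

## 6. Kinship-vs-similarity resampling

Each replicate draws, without replacement, 500 pairs from the distant
stratum and 500 from the close stratum (pairs, not individuals — two
sampled pairs may share an individual, as nothing in the procedure
requires exclusivity), pools them, and computes the Pearson correlation
between pair kinship and pair Bray-Curtis similarity; single-stratum
modes are also available. The 95% interval discards the lowest and
highest 2.5% of replicate values and takes the extremes of the
remainder — an empirical trim, not a normal approximation, because the
replicate distribution is the object of interest. Determinism under a
fixed seed and monotonicity of the mean replicate correlation in a
planted kinship-similarity signal are tested properties.

## 7. Co-occurrence networks

Taxa present in at least 95% of samples are log10-transformed (shared
pseudocount rule) and all pairwise Pearson and Spearman correlations
computed, with t-approximation p-values (for Spearman this is the
standard large-sample approximation on the rank correlation) BH-adjusted
within each method. An edge requires |r| > 0.3 and adjusted p < 0.05
for **both** methods by default: demanding agreement between a linear
and a rank-based measure suppresses edges driven by single outliers. The
disjunctive reading (either method suffices) is exposed as
`require_both_methods = FALSE` for sensitivity analysis.
`aggregate_correlation()` correlates per-sample summed abundances of two
taxon groups, e.g. order-level aggregates.

## 8. The synthetic-data generator

`simulate_bundle()` emulates the statistical structure the analyses
assume, not the biology that produces it:

- **Genotypes** — founders from per-SNP Hardy-Weinberg with allele
  frequencies uniform on [0.05, 0.5]; two-generation full-sib families
  by Mendelian transmission. This design is the simplest that yields
  both kinship strata the resampling needs (founder pairs near 0,
  full-sib and parent-offspring pairs near 0.5). Monomorphic SNPs are
  resampled; everything is recoded to minor-allele counts.
- **Microbiota** — per taxon, abundance = Bernoulli(presence) ×
  exp(Normal(μ + genotype·shift, σ)), rows closed to proportions. The
  Bernoulli-hurdle × log-normal form matches the structure the two-part
  model assumes; the log-normal shape itself is an assumption of this
  package, documented here, not an inference from data. SNP-linked
  taxa shift their natural-log abundance by the minor-allele count times
  a configured effect. Site profiles draw presence probabilities from a
  Beta(4, 1.2) (mostly common taxa, a tail of rare ones) and per-taxon
  log-scale locations and spreads at random.
- **Phenotype** — genetic value = Σ standardized causal genotypes ×
  effects; microbial value = Σ standardized log10 abundances of causal
  taxa × effects; both rescaled so the realized variance fractions equal
  the configured h² and m² exactly (standardizing before applying
  effects makes the variance bookkeeping exact rather than
  in-expectation). Growth records (ADG, body weights, ADFI) are emitted
  so that `compute_rfi()` on them returns the simulated trait.

What the generator does **not** emulate: taxon-taxon ecological
interactions (taxa are independent given genotype, so co-occurrence
networks on generated data are correctly empty — the network tests build
correlated communities explicitly), sequencing-depth or compositional
bias, phylogenetic correlation among taxa, site-to-site correlation
within a bird, and linkage disequilibrium beyond what family structure
induces. Passing tests therefore demonstrate correctness of the
estimators under the assumed generating process, not robustness to
real-data violations of it.

## 9. Problem sizes, fixtures and operating points

The test and acceptance problem sizes are chosen so the full suite runs
in well under a minute of recovery simulations per property while still
pinning each estimator's behavior: REML recovery uses 30 replicates of
n = 400 (100 founders + 60 families × 5 sibs) at M = 2,000 with true
ratio 0.40; microbiability ranking uses 20 bundles of n = 150 with
m² = 0.30 at one site and 0 at another; GWAS calibration uses 10,000
null SNPs at n = 300; resampling coverage uses 100 cohorts at 500
replicates each. The analysis drivers run a single 205-bird cohort —
the target design's size — and their console narratives state explicitly
which findings are expected sampling noise at that scale.

The two-part power check runs at a 5%-variance effect, n = 300, with a
20-taxon genus-scale panel (the size of a genus table after the 30%
prevalence filter) and the causal taxon fully prevalent so the effect
spans all samples. Power at this operating point is genuinely marginal:
Monte Carlo at 150 replicates gives ~0.81 true power at q = 20,
declining to ~0.74 at q = 50 purely through the BH multiplicity
penalty. The compact panel is the regime in which a ≥ 80% detection
rate is attainable at all; with wider panels the same effect size is
simply below the corrected detection limit.

## 10. Known limitations

- Single-random-component REML only; joint G + M models and bivariate
  traits are out of scope (the analyses fit genetics and microbiota
  separately).
- The GWAS reuses the null variance ratio per SNP; for very large
  per-SNP effects the LRT is slightly conservative relative to full
  re-optimization.
- Wilcoxon p-values with ties always use the normal approximation with
  tie and continuity corrections; exact enumeration is restricted to
  small untied samples (default combined n ≤ 20, the cost/accuracy
  crossover).
- The empirical trimmed CI of the resampling stage is a descriptive
  summary of replicate spread, not a frequentist interval for a
  population parameter; its coverage property is verified only under
  the independence null.
- Compositional closure induces weak negative correlation among taxa;
  none of the correlation-based stages correct for compositionality
  (SparCC-style estimators are deliberately out of scope).
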
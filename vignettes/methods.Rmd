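---
title: "Methods: two-cohort GWAS of myocardial infarction, SNP-set enrichment, and genotype risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort GWAS of myocardial infarction, SNP-set enrichment, and genotype risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardiogwas implements the analysis pipeline of a two-cohort, sex-stratified
nested case-control study of incident myocardial infarction (MI) and blood
biomarkers (LDL, HDL, apoB, triglycerides, adiponectin, CRP, total
cholesterol): genotype and sample quality control, per-SNP association
scans, two-cohort meta-analysis, SNP-set enrichment analysis (SSEA) of
eSNP sets, a four-model gene-by-environment interaction screen, and an
unweighted allele-count genotype risk score. Because the underlying cohort
data are restricted, the package ships a synthetic study generator with the
same statistical structure; everything downstream is tested against it.

## The statistical models

**Association.** Disease association uses unconditional logistic regression
of case status on allele dosage (0/1/2 copies of the counted allele) under
the additive genetic model, adjusted for covariates (age, smoking,
principal components); biomarker association uses OLS on the same dosage
coding. Each SNP is fit on its complete cases; separation or
non-convergence yields a flagged null row rather than an exception. The
per-SNP summary is the Wald `z = effect / se` and its two-sided normal
p-value — the bookkeeping the meta-analysis consumes.

**Genomic control.** The inflation factor is
`lambda = median(z^2) / 0.4549364` (the chi-square(1) median); statistics
are divided by `sqrt(lambda)` floored at 1, so deflation is never applied.

**Meta-analysis.** Two combination rules are implemented. The fixed-effects
inverse-variance rule combines per-allele effects,
`effect = sum(b_i / se_i^2) / sum(1 / se_i^2)`. The sample-size-weighted
signed-z rule combines the signed z-scores with weights
`w_i = sqrt(n_i / (n_1 + n_2))`, so the squared weights sum to one and the
combined `Z = w_1 z_1 + w_2 z_2` is standard normal under the null. When
`se` is proportional to `1/sqrt(n)` the two rules coincide exactly, which
the tests assert to 1e-6. "Effective number of individuals" defaults to the
total analyzed count per cohort; the balanced-design alternative
`4 / (1/n_cases + 1/n_controls)` is available (`effective_n`). Both
conventions reproduce the published combined z-scores at one decimal for a
1:2 case:control design. Allele harmonization handles ref/alt swaps by
negating effects; strand flips are not attempted because the synthetic data
are strand-consistent.

**SSEA.** A gene set becomes a SNP set through the gene-to-eSNP map (union
over genes, no double counting, optional distance thinning that keeps the
smallest-p SNP per window). The set's association p-values are compared
with a background by a one-sided Kolmogorov–Smirnov test oriented toward
stochastically smaller p-values — the QQ-plot framing of enrichment. Two
design choices were genuinely open and are both implemented, with the
default chosen for bias control:

* *Background*: all mapped eSNPs outside the set (default), which controls
  for eSNP-ascertainment bias; a one-sample Uniform(0,1) reference is the
  alternative mode.
* *P-value source*: the asymptotic one-sided two-sample p-value for sets of
  30+ SNPs; below that, a seeded permutation p (equal-size draws from the
  pooled universe, 10,000 by default). The permutation statistic is
  computed from ranks in the sorted universe, so the draw loop is
  vectorizable and exact ties are handled conservatively.

Benjamini–Hochberg q-values are reported alongside raw p-values across
sets.

**Gene-by-environment screen.** For each SNP, four nested logistic model
pairs are fit, crossing the environment coding — linear, or a natural cubic
spline with three degrees of freedom (interior knots at the tertiles,
boundary knots at the extremes, centered columns) — with the hypothesis:
*interaction-only* (product terms added to main effects; 1 or 3 df) or
*joint* (SNP main effect plus product terms versus covariates and
environment only; 2 or 4 df, the Kraft-style screen). The likelihood-ratio
statistic `2 * (l_full - l_null)` is floored at zero and referred to the
chi-square with the parameter-count difference. With spline coding the
interaction is dosage times each basis column — the only construction
consistent with the stated degrees of freedom. Which printed model id
corresponds to which cell of the cross is not recoverable from the source
material, so the mapping is a configurable argument
(`gxe_model_specs(order = ...)`) with a documented default. The screen
reports the four p-values side by side with the marginal main-effect p, and
flags SNPs passing a conservative Bonferroni threshold of 1e-9.

**Risk score.** Score alleles are chosen per trait by ascending association
p with a greedy distance rule: a candidate is kept only if it lies at least
100 kb (inclusive) from every *kept* SNP on the same chromosome — the
natural reading of a pairwise-separation constraint on the selected set,
and the tests verify the pairwise invariant exhaustively. Scoring is
+1/0/−1 per entry: +1 when homozygous for the trait-raising allele, −1 when
homozygous for the other allele, 0 when heterozygous — and 0 when missing,
a choice that keeps scores integer and bounded. Signs are reversed for the
protective biomarkers HDL and adiponectin; CRP and total cholesterol keep
the risk-increasing convention. Merged-trait scores deduplicate SNPs
(keeping the smaller source p) and re-apply the distance rule across the
merged list. The score is evaluated by logistic regression of MI on the
integer score. The default N grid `{10, 50, 100, 500, 1000}` is a choice —
no grid is fixed by the source — and is exposed as an argument.

## The synthetic study generator

The generator inverts the analysis models, so parameter recovery is
testable:

* **Genotypes.** One MAF per LD block, drawn from `maf_range` (default
  0.05–0.5). Within a block, each of the two allele copies is a thresholded
  equicorrelated Gaussian; the latent correlation is calibrated by numeric
  tetrachoric inversion so the *realized genotype* correlation matches
  `ld_r`, not the latent one (a naive copula at `ld_r = 0.8` yields
  genotype correlations near 0.65). Hardy–Weinberg holds per SNP because
  the two copies are independent. Positions run at a fixed 25 kb spacing,
  ~250 SNPs per chromosome, so a 10-SNP block spans >100 kb and the
  distance-based pruning rule is non-trivial. Missingness is injected
  completely at random.
* **Disease.** `logit P(case) = intercept + sum(log(OR) * dosage) + ...`,
  with the intercept tuned by bisection so the pool case fraction matches
  the design ratio (1:2); the exact configured counts are then sampled from
  an oversampled pool (factor 1.5), mirroring nested case-control
  sampling. Only the case:control ratio matters downstream; risk-set
  matching is not emulated and the analysis is unconditional.
* **Biomarkers.** Seven traits, each `sum(beta * dosage) + N(0,1)`,
  standardized to mean 0 / SD 1; causal sets and signed effects are drawn
  once per *study* and shared by both cohorts, because a two-cohort
  biomarker meta-analysis presumes shared genetics. Signs are recorded so
  the HDL/adiponectin sign reversal in the risk score is testable.
* **Interaction SNPs** carry `gxe_beta * dosage * E` (E ~ N(0,1),
  alcohol-like) with zero marginal SNP effect, reproducing the pattern of
  interaction hits with null main effects. Interaction SNPs are drawn from
  common variants (MAF ≥ 0.2): a per-genotype interaction is only
  identifiable with enough minor-allele carriers, and the recovery
  properties the tests assert presuppose identifiability.
* **Gene sets.** Synthetic genes map to `esnps_per_gene` SNPs. Enriched
  sets draw half their eSNPs from the causal SNPs; null sets draw from SNPs
  outside causal LD blocks, without replacement across sets when capacity
  allows, so null sets are disjoint and their enrichment p-values
  independent — the condition under which across-set uniformity is a
  meaningful property.
* **Covariates.** Age and smoking carry the mild case-control imbalance
  typical of published baseline tables; they are generated for adjustment,
  not used for matching.

Defaults mirror the emulated study: cohorts of 464+945 and 425+878
subjects, 2,000 SNPs, 20 disease-causal SNPs at OR 1.4, biomarker effects
of 0.25 SD/allele, 100 gene sets of which 3 are enriched, two interaction
SNPs at `gxe_beta = 0.5`.

What the generator does *not* emulate: realistic human LD maps, imputation
dosages, X-chromosome inheritance, self-reported ancestry strata, or
risk-set matching. Tests passing on this generator therefore demonstrate
the correctness and calibration of the *analysis*, not robustness to every
feature of real array data.

## Numerical and testing choices

* Logistic fits go through `stats::glm.fit` with Wald covariance from the
  final weighted QR; flags replace estimates when a fit fails to converge,
  hits a boundary, or shows separation-scale estimates (|effect| > 15 or
  se > 100).
* HWE uses the 1-df chi-square without continuity correction — the
  conventional array-QC default, checkable by hand; monomorphic SNPs get
  p = 1 and are excluded by their own filter.
* Duplicate samples are detected by pairwise genotype concordance over the
  non-missing overlap (> 0.95 flags the lower-call-rate member), a proxy
  for identity-by-descent that is exact on synthetic data.
* PCA ancestry screening mean-imputes missing calls, standardizes by
  `sqrt(2p(1-p))`, and flags samples beyond 3 SD on component 1 or 2.
* The null-calibration test suite runs a zero-effect study of 2 cohorts ×
  1,350 subjects × 2,000 *independent* SNPs: KS uniformity across SNPs has
  its nominal reference only under independence, and marginal-test
  calibration, not LD, is the property under test. The genomic-control
  lambda is averaged over 5 replicate studies because the median-based
  estimator has sd ≈ 0.05 at 2,000 SNPs — a single draw cannot certify a
  ±0.05 calibration band. Interaction-model type-I error is measured over
  6,000 independent replicates (fresh phenotype, environment and genotype
  each time): with a single shared phenotype draw, the empirical rate
  across SNPs fluctuates around a draw-dependent conditional size and is
  uninformative about the unconditional 5% level.
* The risk-score behavior suite uses a strongly polygenic pleiotropic
  architecture (600 of 2,000 SNPs with ±0.1 SD/allele lipid effects and
  aligned MI log-odds at 0.55× the lipid effect): the qualitative claim
  that significance grows with the number of scored SNPs presupposes that
  marginal SNPs keep adding signal, which fails when a few strong loci
  dominate. Cross-cohort evaluation under disjoint architectures is the
  non-replication control.
* Problem sizes throughout the test suite (single-CPU): scans of 2,000
  SNPs at n ≈ 1,350–2,700, 50 enrichment replicates, 100 recovery
  replicates, 6,000 interaction null replicates, 12+3 risk-score
  replicates.

## Known limitations

* The spline-basis construction fixes knots on the full environment vector
  before per-SNP complete-case subsetting; with the default 0.5% missing
  rate the difference to per-SNP knot recomputation is negligible and
  keeps the basis comparable across SNPs.
* The 3-df spline interaction LRT is mildly anti-conservative at n = 2,700
  (unconditional size ≈ 0.053–0.054 at the 5% level, measured over 12,000
  null replicates) — a known property of product-term LRTs with moderate
  df, not specific to this implementation (verified against `glm`/`anova`).
* Permutation p-values resample SNP labels, not subjects, and therefore
  assume exchangeability of p-values across the eSNP universe; distance
  thinning is provided to damp the LD dependence this ignores.
* The VCF reader handles GT-only biallelic records (the pipeline's own
  interchange format); it is not a general-purpose VCF parser.
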
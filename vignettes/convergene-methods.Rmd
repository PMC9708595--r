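---
title: "Methods: convergent common- and rare-variant gene-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent common- and rare-variant gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(convergene)
```

## The scientific question

Common variants (minor allele frequency above ~1%) and ultra-rare variants
(alleles seen once across a cohort plus its reference panels) are usually
studied by different designs — GWAS summary statistics on one side, exome
sequencing case-control burden tests on the other. For strongly selected
polygenic disorders such as schizophrenia, a natural question is whether
the two ends of the allele-frequency spectrum implicate the *same*
biology. `convergene` operationalises that question as a parallel gene-set
enrichment analysis: the same named gene-sets are tested for common-variant
enrichment (an LD-aware competitive regression on GWAS summary statistics)
and for rare-variant enrichment (a covariate-adjusted logistic burden
regression in an exome cohort), and the per-set enrichment betas from the
two arms are then correlated.

Four gene-set families are built:

1. **PI genes** — protein-truncating-variant-intolerant genes, defined by a
   constraint score `pLI > 0.9` (strict inequality; the boundary is
   excluded). These proxy strong negative selection.
2. **Brain cell-type sets** — for each of 14 human and 24 mouse brain cell
   types, the top 1600 genes by expression specificity in that type.
   Mouse sets are translated to human gene ids through a homology map.
3. **Synaptic sets** — ontology-derived sets of synaptic location and
   function, retained when they hold 50 or more genes (inclusive).
4. **Intersection sets** — each cell-type set intersected with the PI set
   (`<cell>_x_PI`): genes both brain-relevant and under strong selection.

Under the default configuration this yields 1 + 14 + 24 + 35 + 38 = 112
analysed sets, plus brain-expressed background sets (all brain-expressed
genes and their top 50%/20%/10% by mean expression) used only as
conditioning covariates.

## The common-variant arm

**Gene statistic.** After summary-statistic QC (all copies of duplicated
SNP ids removed; records with INFO < 0.8 removed; both thresholds strict in
the stated direction), SNPs are assigned to genes by closed-interval
position with no flanking window. Each SNP p-value is inverted to a
1-df chi-square, `q_j = [Phi^{-1}(p_j / 2)]^2`, and the gene statistic is
the sum `T = sum_j q_j`. Under the null, with `R` the SNP correlation
(LD) matrix of the gene, `T` is distributed as a weighted sum of
independent 1-df chi-squares with weights the eigenvalues of `R`. The tail
probability is computed by Imhof-type numerical integration of the
characteristic-function inversion; when the integration fails, or lands in
the deep tail (below 1e-8) where an oscillatory integral carries absolute
rather than relative accuracy, a Pearson three-moment chi-square match is
used and recorded per gene in the `method` column. When all eigenvalues
coincide (notably `R = I`) the tail is the exact `pchisq` value. The gene
z-score is the upper-tail probit of the gene p-value.

**Competitive regression.** Gene z-scores are regressed on set membership,
an intercept, and gene-level covariates (gene length, SNP count, and their
logs). The membership coefficient is the enrichment beta; the p-value is
one-sided for beta > 0 (two-sided available by flag). Conditional analyses
add further membership indicators: every brain and intersection set is
conditioned on each brain-expressed background set, and intersection sets
additionally on their parent cell-type set, on PI, and on both —
localising whether an intersection signal is just brain expression, just
constraint, or their combination.

**Inference model.** Ordinary least squares is valid here because the
synthetic design gives every gene its own independent LD block, so gene
statistics are independent. For real data, where neighbouring genes share
LD, `competitive_test(gene_corr = ...)` accepts a gene-gene correlation
matrix and fits the same regression by generalized least squares
(Cholesky whitening).

## The rare-variant arm

**Variant classes.** The total allele count of a variant pools the
in-cohort count with a reference-panel count; the allele frequency
denominator is `2 * panel_total_n` chromosomes (cohort + panel, 188,023
individuals by default). Classes: *ultra-rare* (singletons; total AC
exactly 1), *rare* (AF < 0.1%, singletons included) and *rare excluding
singletons* (AF < 0.1% and AC >= 2). Classes are crossed with consequence:
protein-truncating variants carry the hypothesis; synonymous variants are
the negative control.

**Sample QC.** Within each frequency class, individuals are excluded when
their synonymous qualifying count deviates from the cohort median by more
than 4 unscaled median absolute deviations ("more than" strict; no 1.4826
consistency factor). With MAD = 0 any positive deviation excludes — a
documented sharp edge of the unscaled filter.

**Burden regression.** Per individual, the burden score is the count of
qualifying alleles of the class in the set's genes (alleles, not a carrier
indicator; homozygotes count twice). Case status is regressed on the
burden with sex, ten genetic PCs and (by default) the individual's
exome-wide count of the same class, by maximum-likelihood logistic
regression with Wald two-sided p-values. Separation triggers a
Firth-penalized refit, flagged `firth` in the `status` column. Conditional
forms add other sets' burden scores as covariates; because intersection and
PI burdens share variants, the fit reports a variance-inflation diagnostic
(`vif`) alongside the focal estimate.

## Multiple testing and convergence

Benjamini–Hochberg FDR at 5% is applied separately within each
variant-class family (common, `urv_ptv`, `rare_excl_ptv`, ...), across all
analysed sets including the synaptic family; background sets are never part
of a family. Convergence between arms is summarised by correlating per-set
betas: a plain estimate (both Pearson and Spearman are reported, since a
rank and a product-moment correlation answer subtly different questions and
output metadata records both) and a weighted Pearson estimate with weights
`1 / (se_a * se_b)`. The weighted estimator is invariant to rescaling all
weights, so normalised and raw inverse-SE-product weights give identical
results. Sets FDR-significant in both arms form the overlap report.

## What the synthetic generator emulates

The pipeline's inputs are restricted-access in real life, so the package
ships a fully seeded generator whose defaults define the study conditions:

| Quantity | Default | Why |
|---|---|---|
| GWAS sample size `N` | 105,318 | scale of a large schizophrenia GWAS |
| human / mouse cell types | 14 / 24 | the cell-type panels the sets mirror |
| genes | 12,000 | makes the top-1600 selection ~15% of the ~10,800 qualifying brain-expressed genes, the stated proportion of the source selection |
| SNPs per gene / AR(1) rho | 10 / 0.6 | desk-scale LD blocks with realistic local correlation |
| `tau2_null` / `tau2_enriched` | 1e-6 / 5e-6 | per-SNP effect variances giving mild genome-wide inflation and clear set-level enrichment at this `N` |
| cohort | 4625 cases / 5966 controls | the ultra-rare analysis sample size |
| `mu_ptv` / `mu_syn` per gene | 7.5e-5 / 4e-4 | ~0.9 rare PTVs and ~5 synonymous alleles per exome, the order seen in exome burden studies |
| planted burden log-OR | 0.3 | a per-allele effect recoverable within 2 SE at this cohort size |
| panel for singleton calling | 188,023 | cohort + reference-panel denominator |

Mechanics worth knowing when interpreting tests:

* **GWAS z-scores** follow `z ~ MVN(R b sqrt(N), R)` per gene block with
  `b_j ~ N(0, tau2)`, `tau2` elevated in enriched sets. One block per gene,
  blocks independent — this is what makes OLS inference exact in the
  competitive test and gives clean null calibration.
* **pLI** is a two-component Beta mixture (`Beta(0.5, 8)` and
  `Beta(8, 0.5)`, 15% weight on the constrained component), mimicking the
  bimodality of real constraint scores. The implied `P(pLI > 0.9)` is the
  mixture tail (~0.12), which calibration tests target exactly.
* **Exome alleles** arrive as Poisson events on the individuals-by-genes
  grid; within a gene an allele either founds a new variant site or recurs
  at the most recent site, so in-sample allele counts above 1 occur. A
  configurable fraction of variants has its reference-panel count forced to
  zero so true singletons exist. Case status is *prospective* logistic with
  the planted per-allele log-odds on causal-set PTV counts — making the
  planted log-OR the exact estimand of the burden regression, which is what
  permits parameter-recovery tests rather than loose directional checks.
  Synonymous alleles never enter the linear predictor.

What the generator does **not** emulate: realistic allele-frequency spectra
or site-frequency correlations, real LD maps, population substructure,
genotyping/imputation artefacts beyond simple INFO and duplicate-record
injection, and the upstream variant-annotation pipeline (consequence labels
are taken as given). Passing tests therefore demonstrate the *statistical
machinery* — calibration, recovery, conditioning behaviour, determinism —
not robustness to those real-data complications.

## Numerical choices and edge cases

* p-values clamped to `[1e-300, 1 - 1e-16]`; gene z clamped to |z| <= 37
  (the double-precision probit limit).
* Imhof integration walks a tolerance ladder (1e-6, 1e-4, default) before
  falling back to the three-moment match; the chosen method is recorded
  per gene.
* Expression-specificity ranking divides a gene's expression in the focal
  type by its mean over all types plus a pseudocount of 0.01; ties break
  lexicographically by gene id, so set construction is deterministic.
* Duplicate-SNP QC removes **all** copies of a duplicated id (the
  conservative reading); real-data users who want keep-first should
  deduplicate upstream.
* Mouse genes mapping to more than one human gene are dropped entirely;
  many-to-one mappings collapse after translation. Counts are logged on the
  result's `homology_log` attribute.
* Empty intersections cannot be represented as rows of the long gene-set
  tibble; they are preserved on an `empty_sets` attribute with a warning,
  and any set with fewer than `min_set_size` (default 10) scored genes is
  reported with status `skipped_small` rather than silently dropped.
* The allele-frequency denominator is the combined cohort + panel; this is
  configurable because real pipelines differ in whether the denominator
  includes the cohort.
* The exome-wide mutation-count covariate is class-matched (the focal
  frequency class and consequence), configurable, since pooling classes is
  an equally defensible reading.

## Problem sizes used by the shipped checks

The test suite exercises the full 112-set construction at the default
12,000-gene universe; statistical calibration checks run at reduced but
adequately powered sizes chosen once (5,000-gene null GWAS for uniformity;
1,000 null replicates of 1,000 genes for competitive type-I error; a
4,000/4,000 cohort for log-OR recovery; 500 small cohorts for synonymous
type-I error; a 500-gene end-to-end run, twice, for bit-identical
reproducibility). `scripts/acceptance.R` re-runs the full default
configuration end to end and reports the quantities it computes.

## Known limitations

* The competitive test implements the sum-of-chi-squares ("mean") gene
  model only; top-SNP and multi-model variants are out of scope.
* OLS inference assumes independent gene statistics; for real data supply
  `gene_corr` (GLS) or expect mild miscalibration near long-range LD.
* The Firth fallback reports Wald intervals; profile-likelihood intervals
  are not implemented.
* The MAD filter with MAD = 0 is aggressive by construction; inspect the
  synonymous count distribution before relying on it for small cohorts.
* Weighted Spearman has no canonical definition and is deliberately not
  reported; the weighted estimate is always weighted Pearson.
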
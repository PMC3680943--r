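# vasculotype

Analysis toolkit for expression profiles of microdissected tumor
vasculature. Breast-tumor microvasculature is molecularly heterogeneous:
beyond differing from normal vasculature, tumor vessels fall into
expression-defined subtypes (a pericyte-poor, actively remodeling type and a
pericyte-rich, more mature type). Those inter-subtype differences are large
enough to *mask* the much smaller expression differences associated with
disease recurrence — so an outcome predictor only works after the subtype
signal is removed. This package implements that full analysis as a tested,
reusable pipeline for anyone working with vascular (or other
compartment-resolved) expression cohorts:

- **Data handling** — tab-delimited log2 expression matrices, sample
  annotation tables, probe→gene collapsing by maximal interquartile range
  (IQR), strict IQR variable-gene filtering, row Z-scoring.
- **Class discovery** — Ward minimum-variance clustering on the correlation
  distance d(i,j) = 1 − cor(xᵢ, xⱼ), tree cutting, bootstrap clade support
  (proportion of gene-resampled trees containing each clade), and PCA.
- **Differential expression** — empirical-Bayes moderated t-statistics. Per
  gene, the pooled two-group variance s²_g (d degrees of freedom) is shrunk
  toward a prior (d₀, s₀²) estimated from all genes by method-of-moments on
  log s²_g: the posterior variance is s̃² = (d₀s₀² + d s²)/(d₀ + d), and
  t̃ = β̂ / √(s̃² v) has d₀ + d degrees of freedom. FDR control by
  Benjamini–Hochberg.
- **Subtype characterization** — pericyte-marker scores (mean row Z-score of
  ACTA2, PDGFRB, RGS5, LAMB1), Spearman/Welch/Fisher tests, gene-signature
  overlap (hypergeometric), and signature-induced segregation scored by
  adjusted Rand index.
- **Recurrence prediction** — the subtype-adjusted predictor: per gene,
  Δ_g = mean(B) − mean(A) is estimated on training samples and subtracted
  from subtype-B profiles; the k most recurrence-associated genes are chosen
  by Wilcoxon rank-sum; a linear discriminant classifier is trained; all of
  it nested inside leave-one-out cross-validation (LOOCV), plus a gene-set
  size scan.
- **Synthetic cohorts** — a generator that plants the whole statistical
  structure (15 normal + 9/8 tumor subtype samples, 5/12 recurrence split,
  gene-specific variances from a scaled inverse-χ² prior, subtype-masked
  recurrence effects, MVD classes correlated with subtype) with full ground
  truth, so every stage is testable without any external data.

## Worked example

```r
library(vasculotype)

cohort <- generate_cohort(synth_config(seed = 1))
ann <- cohort$samples
tumor <- ann$tissue == "tumor_vasculature"

# class discovery on the tumor samples
tree <- ward_linkage(correlation_distance(cohort$matrix[, tumor]))
clusters <- cut_k(tree, 2)
adjusted_rand_index(clusters, ann$subtype[tumor])
#> [1] 1

# moderated differential expression between subtypes
de <- moderated_de(cohort$matrix[, tumor], ann$subtype[tumor])
sum(de$q <= 0.05)
#> [1] 701

# subtype-adjusted nested LOOCV recurrence predictor
cv <- loocv_run(cohort$matrix[, tumor], ann$subtype[tumor], ann$recurrence[tumor], k = 6)
cv
#> Nested LOOCV recurrence predictor (k = 6, subtype-adjusted, selection nested)
#>   accuracy: 15/17 = 88.2%   Fisher exact p = 0.01471
#>      
#>       no yes
#>   no  12   2
#>   yes  0   3

loocv_run(cohort$matrix[, tumor], ann$subtype[tumor], ann$recurrence[tumor],
          k = 6, adjust = FALSE)$accuracy
#> [1] 0.4705882
```

The clustering recovers the two planted vascular subtypes exactly (ARI = 1);
the subtype contrast yields hundreds of moderated-t discoveries; and the
recurrence predictor reaches 15/17 under honest nested cross-validation
*only* when the inter-subtype mean differences are removed first — without
the adjustment the same pipeline drops to chance-level accuracy (0.47).
That adjusted-vs-unadjusted contrast is the package's central reproduced
phenomenon.

## Command line

A thin CLI wraps the same functions (see `inst/exec/vasculotype`):

```sh
vasculotype simulate --out cohort/ --seed 1
vasculotype cluster  --matrix cohort/expression.tsv --iqr-threshold 2 --boot 10000 --seed 1 --k 2 --out out/
vasculotype de       --matrix cohort/expression.tsv --annot cohort/samples.csv --contrast B_vs_A --out de.tsv
vasculotype predict  --matrix cohort/expression.tsv --annot cohort/samples.csv --out pred/ --k 6
vasculotype run      --matrix cohort/expression.tsv --annot cohort/samples.csv --out report/
```

## Documentation

The methods vignette (`vignettes/vasculotype-methods.Rmd`) describes the
statistical model, the synthetic-cohort design and its limits, numerical
conventions (quantile type, tie-breaks, ridge regularization), and known
limitations.
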
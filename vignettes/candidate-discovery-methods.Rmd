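---
title: "Methods: cross-species discovery of pain candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species discovery of pain candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

painmodnet implements a multi-evidence strategy for nominating candidate
genes for pain response and regulation. The idea is that a gene worth
following up should leave a footprint in several independent data types at
once: it should sit in a transcriptional module enriched for known pain
genes, occupy a well-connected position in the protein-interaction
neighborhood of those genes, respond transcriptionally in a pain model, and
covary with pain-related phenotypes across genetically diverse strains and
brain regions. Each stage is implemented from first principles in this
package, and every stage is validated against planted ground truth from the
package's own synthetic-data generators.

This vignette describes the statistical model behind each stage, the
default settings and why they were chosen, and what the synthetic study
does and does not capture.

## 1. Coexpression modules

The module-detection core follows the weighted-coexpression-network
tradition. From a gene-by-sample expression matrix (optionally trimmed of
outlying samples by average-linkage clustering of sample profiles, and
restricted to the highest-mean genes):

1. **Adjacency.** The unsigned adjacency between genes $i$ and $j$ is
   $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$. The soft-threshold power
   $\beta$ is chosen by `pick_soft_threshold()`: for each candidate power,
   connectivities $k_i = \sum_{j \ne i} a_{ij}$ are binned into 10
   equal-width bins and $\log_{10}$ frequency is regressed on $\log_{10}$
   mean connectivity; the fit index is $R^2$ signed by the negated slope
   sign, so a straight *descending* degree distribution (the scale-free
   signature) scores positively. The chosen power is the smallest one
   reaching the target index (default 0.8), falling back to the argmax.
   Scans with fewer than three non-empty bins, which occur when
   connectivity is nearly constant, are flagged invalid and excluded.

2. **Topological overlap.** The adjacency is converted to the topological
   overlap matrix
   $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
   with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$, which rewards pairs
   that share neighbors rather than merely correlating with each other.
   `tom_from_adjacency()` is tested against a literal triple-loop oracle to
   1e-12.

3. **Modules.** Genes are clustered by average linkage on
   $1 - \mathrm{TOM}$ and the tree is cut at a fixed quantile (default
   0.4) of the merge heights. Because TOM dissimilarities saturate close to
   1 for unrelated genes, the informative merges — genes joining their
   module — happen in the *low* tail of the height distribution, so a
   below-median quantile separates modules without a per-dataset tuning
   step. Clusters below `min_module_size` (default 50) become "gray"
   (label 0, unassigned); surviving modules are relabeled by decreasing
   size.

4. **Eigengenes and merging.** Each module's eigengene is the first right
   singular vector of the row-standardized member submatrix (the sample
   space first principal component), sign-aligned with the mean member
   profile and scaled to unit norm. Modules whose eigengenes are closer
   than `cut_height` (default 0.25 in correlation dissimilarity) are merged
   iteratively until all retained eigengene dissimilarities exceed the
   threshold.

## 2. Reference-set enrichment

`hypergeom_module_enrichment()` scores each module against a curated
reference gene set with the hypergeometric distribution over the analyzed
gene universe, reporting the enrichment ratio
(observed / expected overlap), one-sided tail probabilities and
Benjamini–Hochberg FDR across modules. The most significantly
over-represented module is carried forward as the "pain module".
Over-representation of the module's members in pathway and
transcription-factor-target collections uses the same machinery
(`ora()`), with redundant significant terms grouped into clusters by
Cohen's kappa similarity of their gene memberships
(`kappa_term_network()`), each cluster reported through its
lowest-p representative.

## 3. Protein-interaction subnetwork

Interaction edge lists (for example a STRING export) are loaded with a
combined-score threshold (default 0.7, the conventional high-confidence
cutoff; integer 0–1000 scores are auto-scaled). Within the pain module,
`extract_reference_subnetwork()` keeps the reference genes and their first
neighbors with all edges among them. Hubs are ranked two ways: by degree
and by maximum neighborhood component (MNC), the size of the largest
connected component of the subgraph induced by a node's neighbors. Dense
ranks are used so ties share a rank; `mnc()` is validated against a
brute-force component search on random small graphs.

## 4. Differential expression

Counts from a two-group design are analyzed with a self-contained
TMM + negative-binomial exact-test implementation:

- **Normalization.** `tmm_factors()` computes trimmed-mean-of-M-values
  factors (30% M-trim, 5% A-trim, precision-weighted). The precision
  weights are delta-method Poisson variances computed on the
  counts-per-million scale, which makes the factors exactly invariant to
  pure sequencing-depth changes: a resequenced library with the same
  composition receives the same factor.
- **Dispersion.** `estimate_dispersion()` scales counts to a common
  effective library size and pools a method-of-moments dispersion
  $(\hat v - \hat\mu)/\hat\mu^2$ across groups per gene. The common value
  is a lightly trimmed mean (5% per tail) of the per-gene estimates: the
  per-gene distribution is strongly right-skewed, and heavier trimming
  behaves like a median and systematically understates the common
  dispersion, which in turn inflates the null rejection rate. Per-gene
  values are shrunk toward the common value with weight 0.7 — at these
  group sizes the per-gene moment estimates are noisy, so heavy shrinkage
  toward the pooled value stabilizes them.
- **Test.** `nb_exact_test()` conditions on the rounded per-gene total of
  the normalized counts and models the two group sums as negative binomial
  with group-size-proportional means under the null; the two-sided p-value
  sums the probabilities of all splits no more probable than the observed
  one. Supplying a fixed `target_size` makes p-values exactly invariant to
  depth-only changes; with the data-driven default (mean effective library
  size) they are approximately so. Fold changes are log2 ratios of
  normalized group means with a 0.5 pseudo-count.
- **Calibration.** On null simulations at the generative dispersion, the
  rejection rate at $p < 0.05$ sits within three binomial standard errors
  of 0.05; with estimated dispersions it stays within [0.03, 0.07].
  Sensitivity for planted four-fold changes at moderate baseline
  expression exceeds 0.8 at FDR < 0.05.

DE calls (default fold change ≥ 1.5, FDR < 0.05 strict) are overlaid on
the subnetwork as up/down/ns/untested node flags.

## 5. Phenotype correlation screen

`correlate_panel()` screens each gene's expression across recombinant
inbred strains against each phenotype with pairwise-complete Pearson
correlation and a two-sided t-distribution p-value; tests with fewer than
four complete pairs or zero variance are reported untestable. The screen
deliberately flags raw $p < 0.05$ without multiple-testing correction —
it mirrors the reference-population browsing workflow it models, where
per-correlation significance is reported as-is; a BH mode is available.
Per-gene evidence is summarized as the number of brain regions with at
least one significant phenotype correlation (`count_significant()`,
`pan_region_genes()`) and as the sign balance of significant correlations
(`sign_balance()`), used later for direction-consistency checks.

## 6. Candidate shortlist

`shortlist_candidates()` intersects four criteria over the subnetwork's
genes: degree ≥ 4, |log2FC| ≥ 1 with FDR < 0.05, at least one
significantly associated trait in a gene–trait association table
(`filter_gwas()` counts distinct traits at $p < 0.05$ and at a stricter
$10^{-3}$), and significant correlation in ≥ 4 regions. The degree and
region minima of 4 reflect the minima such multi-evidence shortlists
retain in practice and are configurable; the shortlist fold-change bar
(2-fold) is deliberately stricter than the DE stage's own 1.5. Shortlisted
genes are checked for direction consistency (up-regulated genes should
carry predominantly positive phenotype correlations, down-regulated
negative; equal counts are flagged as ties) and annotated for
reference-set membership, separating "known" from "novel" candidates.

## 7. The synthetic study

All validation runs on data from the package's own generators
(`simulate_study()`, `write_synthetic_fixture()`), whose default preset
(`synth_preset()`) plants:

- 2000 genes × 60 samples with four latent-factor modules of sizes
  300/200/150/100, factor loading 0.8, noise sd 0.6 — a within-module
  correlation near 0.64, comfortably above background but far from
  degenerate;
- a reference set of 100 genes, 40 inside module 1;
- an interaction graph over module-1 genes (mean degree 4) whose planted
  candidates and some reference genes are degree-boosted;
- negative-binomial counts (3 vs 3, dispersion 0.1) with strong planted
  fold changes on six candidate genes and graded 2/4/16-fold tiers on
  background genes;
- eight brain-region strain panels (27–69 strains, 31 phenotypes, 10%
  missing phenotype values) with candidates correlated at $|\rho| = 0.7$
  in four phenotypes per region, signs matching their fold-change
  direction;
- a sparse gene–trait table with candidate associations planted below
  $10^{-4}$.

The problem sizes are the package's own choices, scaled so a full
end-to-end run takes seconds while every stage still has real work to do
(TMM faces log-normal library-size variation; the correlation screen faces
missing data; module detection faces a 37% background). Generators take
explicit integer seeds, never touch the global random state, and the
pipeline is fully deterministic: identical inputs and configuration yield
byte-identical output tables.

What the simulation does *not* capture: microarray probe-level artifacts,
batch effects, correlated phenotypes within a panel, linkage between
strains, overdispersion heterogeneity beyond the planted constant, or any
cross-species identifier mapping — inputs are assumed to share one gene
namespace. Conclusions about real datasets therefore still require the
usual dataset-specific diagnostics (sample clustering, scale-free fit,
dispersion plots), which the package exposes but does not automate away.

## Running the pipeline

```{r}
library(painmodnet)

dir <- tempfile("study-")
cfg <- write_synthetic_fixture(dir, seed = 1)
validate_inputs(cfg)
res <- run_pipeline(cfg)

res$pain_module
res$candidates[res$candidates$shortlist, ]
```

The numbered scripts under `analysis/` run the same stages one at a time,
writing each stage's tables under `results/`.
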
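---
title: "Methods: statistics and simulation design in degnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and simulation design in degnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

degnet implements the classic case–control blood-transcriptome analysis
chain: variance filtering and unsupervised signature discovery, per-probe
differential testing with probe-to-gene collapsing, gene-set
over-representation, interactome over-connectivity against a curated
background network, and a chromosomal hot-spot scan. This vignette states
the statistical model of each stage, the numerical conventions, and the
design of the synthetic-data generator used to validate the chain.

## Data model

Expression values are log2 intensities in a probes × samples matrix
(`expr_matrix`), each sample labelled `case` or `control`. Probes map
many-to-one onto gene symbols through an annotation table that also
carries genomic coordinates and a pseudogene flag. A curated interaction
network is a directed, signed edge list over *network objects* (proteins
or complexes); genes map many-to-one onto objects, so paralogs that the
curation does not separate (e.g. two interferon-induced GTPase genes
mapping to one object) collapse to a single node.

## Signature stage

* **CV filter.** The coefficient of variation is computed on the linear
  (anti-logged) scale, `sd(2^x)/mean(2^x)`, because intensity-scale
  dispersion is what array-era variance filters measured; probes are
  retained when CV is strictly greater than the threshold (default 0.12,
  so a threshold of 0 retains everything).
* **Clustering.** Dissimilarity is `1 − r` (Pearson). Samples use
  centroid linkage: `hclust` requires squared Euclidean-like input for
  centroid, so the dissimilarities are squared going in and merge heights
  square-rooted coming out. Probes use average linkage. Items are sorted
  lexicographically before clustering so the dendrogram is invariant to
  input order, and probes are standardized (per-probe z-scores) before
  sample clustering by default so high-intensity probes do not dominate.
* **PCA.** `prcomp` on samples; explained-variance fractions are reported
  over all components. Separation of the case/control labels is
  quantified by the adjusted Rand index of a two-group cut of the sample
  dendrogram against the true labels.

## Differential expression

Per probe, Welch's unequal-variance two-sample *t* on the log2 values
(vectorized over rows; cross-checked against `stats::t.test` in the test
suite). The signed fold change is the ratio of the anti-logged group
means — a ratio of geometric means — reported as a negative reciprocal
when below 1, so `−1.57` means 1.57-fold lower in cases. Probes qualify
as differential at `p < 0.05` (strict) **and** `|FC| ≥ 1.4` (inclusive);
these marginal thresholds deliberately reproduce the conventional
workflow and are not multiplicity-corrected (BH q-values are reported
alongside for reference). Unannotated and pseudogene probes are dropped,
then probes collapse to one record per gene: maximum `|FC|` wins, ties
broken by smaller p, then lexicographic probe id.

## Gene-set over-representation

For a query of *n* genes in a universe of *G*, a term with *K* members in
the universe and *k* in the query is scored by the hypergeometric upper
tail `P(X ≥ k)`; BH adjustment is applied across the collection. Query
genes outside the universe are dropped with a warning.

## Interactome over-connectivity

This is the chain's core statistic. Map the recovered genes onto network
objects, giving a dataset of *n* of the *N* background objects. For each
candidate object with *R* distinct neighbors (undirected projection,
self excluded), let *A* be its neighbors inside the dataset. Then

* expectation `E = nR/N`,
* `sd = sqrt(n (R/N) (1 − R/N) (N − n)/(N − 1))` (hypergeometric),
* z-score `(A − E)/sd` and connectivity ratio `A/E`,
* exact tail p: upper (`P(X ≥ A)`) when `z ≥ 0`, lower when `z < 0`.

Objects with `R = 0` are flagged `isolated` rather than scored. The test
is discrete and therefore conservative at nominal alpha for small *R*;
the test suite calibrates the empirical rejection rate under a null
against the analytically expected rate `mean(P(p_i < alpha))` rather
than against alpha itself. `connectivity_from_counts()` exposes the bare
computation for validating published tables that print `(A, n, R, N)`.
Companion analyses: `overconnected_pairs()` enumerates direct
interactions within the over-connected set, `regulator_enrichment()`
scores regulator target sets against the DEG list with the same
hypergeometric machinery, and `topology_summary()` reports degree splits
and mean local clustering coefficients.

## Chromosomal hot spots

Genes are ordered along the genome (first probe per gene defines the
locus). Every candidate stretch of consecutive genes that is delimited
by DEGs at both ends and contains at least `min_k` DEGs (default 3)
among its *m* genes is scored by the genome-wide hypergeometric tail
`P(X ≥ k)` with *D* DEGs among *G* ordered genes. Windows at `p ≤ 0.05`
are retained and overlapping or adjacent windows merge, the merged
window keeping the *minimum* member p-value (its span statistic is
recomputed but the minimum is what survived selection). A permutation
null (`hotspot_permutation_p`) re-places the *D* DEG labels uniformly
and reports `(1 + hits)/(B + 1)`; for a single unmerged window it
estimates exactly the analytic span statistic, which the test suite
verifies at B = 100,000.

## Synthetic-data generator

`simulate_study()` plants known structure so every stage can be scored
against truth:

* **Genome**: `n_genes` genes in contiguous chromosome blocks, 1–3
  probes per gene (probabilities 0.7/0.2/0.1), a fraction unannotated or
  pseudogene-flagged among non-DEG genes.
* **Expression**: per-probe baselines plus Gaussian log2 noise
  (`noise_sd`, default 0.5 — a free choice representing moderate
  array-scale variability, not an estimate from any dataset). Planted
  DEGs shift cases by `sign · log2(FC)` with FC uniform in `fc_range`
  (default 1.5–4) and 95% of plants down-regulated, matching a
  suppressed-signature regime.
* **Hot spots**: intervals of `hotspot_span_genes` placed round-robin
  across chromosomes, each seeded with `max(3, round(0.3 · span))`
  planted DEGs.
* **Network**: preferential attachment (`igraph::sample_pa`) over
  `network_nodes` objects with random edge directions and signs. Hubs
  are planted by rewiring moderate-degree nodes (degree window 8–30) so
  that half their neighborhood is DEG-mapped; the global top-degree
  nodes are unusable as planted hubs because their required DEG
  neighborhoods would exceed the DEG budget.
* **Gene sets**: random terms, with the first `n_enriched_terms` drawing
  70% of their members from planted DEGs.

Seeding: each stage derives its own seed (`seed`, `seed + 1`,
`seed + 2` for expression, network, gene sets), so every `simulate_*`
function is deterministic standalone and `simulate_study` is
byte-reproducible. All seeds are plain integers below 2^31.

The packaged validation regime is a desk-scale version of a full study:
1200 genes with 99 planted DEGs, 8 cases vs 6 controls, a 3000-node
network with 16 planted hubs, 6 hot spots, and 5 enriched terms among
100. These sizes are the package's own choice, small enough to run in a
test suite while keeping every stage's signal-to-noise regime realistic;
the generator defaults (9000 genes, 26,494-node network) correspond to
full scale.

## Known limitations

* Marginal DEG thresholds (`p < 0.05`, `|FC| ≥ 1.4`) carry a sizeable
  false-discovery proportion at small DEG fractions (expected ~0.3 at
  the validation regime); the BH q-value column is provided for stricter
  use.
* The generator's noise is homoscedastic Gaussian on the log2 scale; no
  probe-level variance heterogeneity, batch structure, or
  intensity-dependent variance is modelled.
* The hot-spot scan tests each window against genome-wide totals without
  correcting for the number of candidate windows scanned (the optional
  BH adjustment addresses retained windows only).
* Network curation effects (study bias toward well-known proteins) are
  not modelled; preferential attachment reproduces the degree
  distribution only.
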
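---
title: "polyprof: methods for isoform-level polysome-profile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyprof: methods for isoform-level polysome-profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprof)
```

## Overview

Polysome profiling with RNA sequencing of individual gradient fractions
(TrIP-seq-style experiments) measures, for every transcript isoform, how
its molecules distribute across ribosome-load classes: a cytoplasmic
input, the 80S monosome, discrete polysome peaks carrying two to seven
ribosomes, and an unresolved "eight-plus" fraction. `polyprof`
implements the downstream analysis of such data at isoform resolution:

1. **quantify** — TPM/RPKM normalization, a variance-stabilizing
   transformation (VST), ribosome-weighted polysome counts, ribosome
   density, and abundance filters;
2. **clusterize** — hierarchical clustering of isoform fraction
   profiles and of samples, cluster meta-profiles, and Jaccard
   resampling stability;
3. **features** — decomposition of transcripts into 5′ leader, CDS, and
   3′ UTR, and tabulation of a 24-feature registry per isoform;
4. **linkedcompare** — gene-linked isoform pairs between high- and
   low-polysome clusters, compared feature-by-feature with Cliff's
   delta, bootstrap confidence intervals, and Mann–Whitney U tests;
5. **project** — projection of an external (e.g. staged single-cell)
   expression matrix onto the reference clusters and detection of
   translationally consequential isoform switches;
6. **synthdata** — a fully seeded synthetic-data generator with planted
   ground truth, so that every stage above is testable by recovery
   without any external download.

The package is driven either programmatically or through a pipeline
(`run_pipeline()`, `cli_main()`) configured by a single YAML file.

The nine fraction types are named `cyto`, `mono`, `p2` … `p7`,
`p8plus`; sample columns follow the `<fraction>_<replicate>`
convention:

```{r}
fraction_types()
```

## Weighted polysome counts

Fraction-level read counts are converted into an estimate of
ribosome-bound reads by the weighted sum

$$\mathrm{count} = \sum_i w_i \, n_i,$$

where $n_i$ is the read count in the fraction carrying $i$ ribosomes
and $w_i = i$ for the resolved fractions (monosome = 1, two to seven
ribosomes = 2…7). The terminal fraction pools everything with eight or
more ribosomes; its weight is the midpoint between its nominal load (8)
and an assumed ceiling of about 40 ribosomes per transcript:

$$w_{8+} = \frac{40 + 8}{2} = 24.$$

```{r}
weight_scheme()$weights
```

`weight_scheme(include_monosome = FALSE)` restricts the sum to
fractions with two or more ribosomes; `ribosome_density()` divides the
weighted count by the cytoplasmic count, and `translation_efficiency()`
is the analogous ratio for arbitrary signals.

## Normalization

TPM follows the standard definition
$\mathrm{TPM}_i = \mathrm{RPKM}_i \cdot 10^6 / \sum_g \mathrm{RPKM}_g$
(`rpkm_to_tpm()`, `counts_to_rpkm()`), so each sample sums to one
million.

For clustering, counts are variance-stabilized with the analytic map
for negative-binomial counts with variance $\mu + \alpha\mu^2$:

$$\mathrm{vst}(x) = \frac{2\,\mathrm{asinh}\sqrt{\alpha x}}{\ln 2},$$

which is finite at zero, strictly increasing, and asymptotically
$\log_2 x + \mathrm{const}$ for large counts. The dispersion $\alpha$
is estimated by method of moments across replicate columns (median of
$(\mathrm{var}-\mathrm{mean})/\mathrm{mean}^2$ over rows).
`filter_and_center()` then averages replicates within fraction types,
removes isoforms whose nine-fraction mean VST value is not greater than
one, and subtracts each surviving row's mean, giving *relative
expression* profiles.

## Clustering and stability

Isoform profiles are compared by Spearman rank correlation distance
$d = 1 - \rho_s$ (`spearman_distance_matrix()`) and clustered with
Ward's method (`hcluster(..., "ward.D2")`). Trees can be cut at a fixed
$k$, at a height, or by *refinement*: increase $k$ until two cluster
meta-profiles become indistinguishable (pairwise Spearman
$\rho \ge 0.95$ of the mean profiles) and keep the deepest
distinguishable cut. Samples are clustered with Euclidean distance and
complete linkage on the VST matrix (`cluster_samples()`); on the
default synthetic data the four-group cut separates
{cytoplasmic}, {monosome}, {p2–p4}, and {p5–p8plus}, recapitulating the
physical structure of the gradient.

Cluster stability (`jaccard_stability()`) perturbs the data `n = 100`
times per scheme, re-clusters, and records for each reference cluster
the best Jaccard coefficient $|A \cap B| / |A \cup B|$ against the new
clustering:

* **bootstrap** — points resampled with replacement (coefficients
  computed over the unique sampled points);
* **jitter** — Gaussian noise, 0.1 × each column's standard deviation;
* **noise** — a random ~5% of points replaced by uniform draws within
  each column's observed range (replaced points excluded from the
  comparison).

A cluster with mean coefficient ≥ 0.75 is conventionally called stable.

## Feature registry

`decompose()` splits each transcript into 5′ leader, CDS, and 3′ UTR
from its GTF exon/CDS structure and genomic sequence, strand-aware.
`tabulate_features()` assembles 24 features per isoform: region lengths
and GC content, exon count, leader structure scores (cap and minimum
75-nt window; the default folding proxy is base-pair maximization with
Watson–Crick + GU pairing and a minimum hairpin loop of 3 nt, negated
so lower = more structured — a thermodynamic backend can be plugged
in), codon-usage statistics (mean, minimum five-codon window, rare-codon
stretches), the fraction of the 3′ UTR inside A/U-only runs longer than
5 nt, cognate (ATG) and non-cognate (near-cognate start) uORF counts by
leader scanning or from a supplied table, miRNA site counts and summed
context scores (all and expressed-filtered), half-life lookup,
cytoplasmic expression, and the median expression from the 80S through
the eight-plus fraction. Isoforms missing from an auxiliary table get
`NA`, never 0.

## Gene-linked comparisons

To compare well- and poorly-translated isoforms *of the same genes*,
clusters are ranked by the weighted ribosome load of their
meta-profiles (`rank_clusters_by_polysome()`), the top and bottom
clusters form the high/low sets, and `build_linked_sets()` emits all
cross pairs of isoforms within each gene that spans the partition. Each
member's features join its side's pooled distribution. For every
feature, `compare_features()` reports Cliff's delta

$$d = \frac{\#(x_i > y_j) - \#(x_i < y_j)}{mn} = \frac{2U}{mn} - 1,$$

computed via midranks (ties contribute zero), a percentile bootstrap
95% confidence interval, and a two-tailed Mann–Whitney U test (exact
null distribution for small tie-free sets, tie-corrected normal
approximation with continuity correction otherwise), flagged at the
α = 0.001 convention.

## Projection and isoform switches

`cluster_external()` clusters stage-averaged external profiles (log2,
row-centered) with the same Spearman/Ward machinery.
`map_to_reference()` assigns each cell's expressed transcripts
(TPM > 1) to their reference cluster and averages per-cluster
percentages within stages, reporting the standard deviation across
cells. `find_switches()` reports same-gene isoform pairs in different
external clusters whose reference clusters fall on opposite sides of
the high/low partition, oriented in time by the external cluster peak
stages (`low_to_high` / `high_to_low`).

## The synthetic-data generator

All inputs can be simulated with planted ground truth:

```{r}
arch <- make_archetypes(8)
sim <- simulate_counts(arch, n_genes = 50, seed = 1)
sim
```

**Archetypes.** `make_archetypes(k)` draws from a fixed library of up
to 12 fraction-distribution shapes organized around the three
ribosome-load regimes of a sucrose gradient — monosome-bound, light
polysomes (2–4), heavy polysomes (5–8+). Each shape has a core block in
one or more regimes with a distinctive within-block tilt; tails decay
geometrically with distance in a *warped* gradient coordinate in which
the mono|p2 and p4|p5 transitions are wider than steps within a regime
(a transcript bound by one ribosome differs qualitatively from one
bound by several, while neighboring heavy fractions overlap
physically), plus a small uniform baseline. This construction makes
every pair of archetypes differ in fraction *rank order* (all pairwise
Spearman correlations < 0.95, required for the rank-based clustering to
tell them apart) while keeping the four sample groups crisply
separated.

**Counts.** Expected counts are `depth × abundance × weight`; the
cytoplasmic expectation mixes the ribosome-fraction expectations with a
free cytoplasmic term (larger for poorly translated archetypes), so
ribosome density is a planted parameter. Counts are negative binomial
(size = `dispersion`); replicates share expectations; everything is
seeded.

**Annotation.** `simulate_annotation()` realizes planted feature
differences: isoforms of low-polysome archetypes receive longer 3′ UTRs
(means 1551 vs 982 nt; within each gene the long-class UTRs are
guaranteed longer than the short-class ones), more A/U runs, and
cognate uORF cassettes at an elevated rate, embedded in mutually
consistent GTF + genome FASTA + transcript sequences with introns and
both strands, plus auxiliary tables (codon usage, miRNA sites,
half-lives, uORFs).

**External matrix.** `simulate_external()` plants isoform switches: for
a configurable fraction of genes with a high/low archetype pair, the
dominant isoform changes linearly between the first and last stage.

## Pipeline

```{r, eval = FALSE}
cfg <- default_config()
cfg$outdir <- tempfile("polyprof_run_")
res <- run_pipeline(cfg)
```

writes `counts.tsv`, `annotation.gtf`, `genome.fa`, `vst.tsv`,
`relative_expression.tsv`, `isoform_clusters.tsv`, `meta_profiles.tsv`,
`sample_dendrogram.nwk`, `stability.json`, `features.tsv`,
`linked_pairs.tsv`, `effect_sizes.tsv`, `stage_map.tsv`,
`switches.tsv`, and a provenance manifest. The same stages are exposed
as CLI subcommands via `cli_main()` (script in `inst/cli/polyprof.R`).
Identical configurations give byte-identical outputs.

## Limitations

* The folding proxy maximizes base pairs; it is not a thermodynamic
  energy model (plug in an external backend for that).
* RPKM uses annotated transcript length with no fragment-length
  correction; cross-library normalization beyond library size is out of
  scope.
* The generator plants qualitative structure for testability; its
  depth/dispersion defaults are chosen for fast, stable recovery, not
  fitted to any particular experiment.
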
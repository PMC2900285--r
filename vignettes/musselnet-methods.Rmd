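---
title: "Tissue co-expression networks from two-channel arrays: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue co-expression networks from two-channel arrays: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselnet)
```

## The analysis in one paragraph

`musselnet` reconstructs the classic tissue-atlas co-expression analysis for
two-channel cDNA microarrays, as applied to the *Mytilus galloprovincialis*
MyArray 1.0 atlas (GEO accession GSE2176): 3840 spotted cDNA sequences
profiled in four tissues (gills, gonads, foot, digestive gland) with two
biological replicates each.  Per-spot test/reference intensity ratios are
log2-transformed; per-gene one-way ANOVA across tissues flags differential
expression at raw p < 0.05; the Pearson correlation of every gene pair's
log2 profile across the eight arrays defines a co-expression graph with an
edge wherever PCC > 0.90; Markov Clustering (MCL, inflation 3.0) of that
graph identifies modules, of which only those with more than 10 genes are
kept; and the 1-hop neighborhood of a set of seed clones — the heat shock
protein (Hsp) clones, in the original use — is extracted as a dedicated
subnetwork.  Network rows are summarized by node count, edge count and
average connectivity (the mean degree, 2E/N).

## Model and assumptions, stage by stage

**Normalization.**  The analysis scale is `log2(test/reference)`.  The
package deliberately applies *only* the binary logarithm: deposited
two-channel series typically store already-normalized intensity ratios, and
no within-array loess or print-tip correction is attempted.  Missing spots
propagate as `NA` — never as silent zeros, which would fabricate strong
negative log-ratios.

**Differential expression.**  One-way fixed-effects ANOVA per gene, with
replicates treated as independent observations: with four tissues and two
replicates, 3 between and 4 within degrees of freedom.  The error model is
Gaussian on the log2 scale.  Two conventions matter at the boundaries: a
gene with zero within-tissue variance but real between-tissue differences
receives F = Inf and p = 0 (exact separation); a completely flat gene has
no defined F and can never be called DE.  No multiple-testing correction is
applied by default — the filter is the historical raw p < 0.05 — but
`filter_de(..., adjust = "BH")` provides Benjamini–Hochberg for modern use.
With eight samples the raw filter's false-positive yield is substantial
(about 5% of null genes, which the acceptance checks verify directly), and
that is part of what the published 547-gene DE set means.

**Correlation network.**  Pearson correlation across all eight arrays (not
the four tissue means: the replicate axis carries real information, and
collapsing it would leave 4 points per gene).  Pairs are computed over
pairwise-complete samples with a minimum overlap of 3; zero-variance genes
are excluded with a message.  The edge rule is strict — PCC > 0.90, ties at
exactly 0.90 excluded — and nodes are only those genes incident to at least
one edge, which is why a network can cover fewer genes than the array
(the published inferred network covers 96% of clones).  With only eight
samples the null distribution of the PCC is wide (the two-sided p-value of
r = 0.9 at n = 8 is about 0.002), so even pure noise contributes edges;
this is a property of the design, not of the implementation, and it is why
the published network is so dense.

**Markov Clustering.**  MCL is implemented from scratch on sparse matrices:
the weighted adjacency matrix gets per-node self-loops equal to the maximum
incident edge weight (standard MCL practice; self-loops damp oscillation),
is column-normalized to a stochastic flow matrix, and is then iterated
through expansion (matrix squaring) and inflation (elementwise power 3.0
followed by column renormalization), pruning entries below 1e-5 and
stopping when the largest entrywise change drops below 1e-6 or at 100
iterations (non-convergence returns the current state with a warning).
Clusters are attractor systems of the limit matrix: nodes with positive
diagonal mass are attractors, attractors connected through the limit
matrix's nonzero structure form one system, and every other node joins the
system receiving the largest share of its flow, with ties broken towards
the system containing the lexicographically smallest gene id so that the
partition is deterministic and equivariant under node relabeling.  Edge
weights (PCC values) are used as flows by default; `use_weights = FALSE`
gives the binary-adjacency variant.  The published analysis does not state
its pruning or weighting choices, so exact reproduction of its 1719-node
clustered network may depend on settings the defaults can only approximate.

**Clustered network.**  The "clustered" network is the induced subgraph on
the union of retained clusters (strictly more than 10 genes): every
original edge between two retained nodes is kept, including edges running
between clusters.  The alternative — keeping only within-cluster edges —
is inconsistent with the published figures of 47% node retention alongside
75% edge retention, which only an induced subgraph reproduces.

**Seed subnetwork.**  "Nearest neighbors" of the seed clones are read as
1-hop neighbors in the network the seeds were identified in (the clustered
network, in the original analysis), and the subnetwork is again an induced
subgraph, so neighbor–neighbor edges appear.  Absent seeds are reported,
never dropped silently.  Which clone ids constitute the seed set is an
input (`read_seed_table()`): clone-level annotations live outside the
expression data.

**Connectivity table.**  For an undirected graph the package reports mean
degree 2E/N and maximum degree.  Published tables of this kind sometimes
carry "out-degree" and "in-degree" columns that no undirected formula
reproduces; `network_stats(..., directed_convention = TRUE)` reports the
lexicographic ordered-pair reading, clearly labelled, and no agreement
with any particular published directed column is forced.

## Promoter sequence operations

The promoter side of the original study needed two primitives, both
provided here in reusable form.

**PWM scanning.**  A JASPAR-style count matrix (e.g. the p53 binding-site
matrix) becomes per-position log2-odds scores with a pseudocount of 0.8
spread by the background (uniform by default); every window of motif width
is scored on both strands, and windows at or above the cutoff are reported
at plus-strand, 0-based, half-open coordinates.  Windows containing
ambiguous bases are skipped.  Historical tools report cutoffs on their own
scales (e.g. a "cut-off score 2" whose units are tool-specific), so the
cutoff here is a plain log2-odds value supplied by the user and
score-scale equivalence with any external tool is not guaranteed.  The
matrix itself is always an input, never bundled: which matrix version a
study used is part of its provenance.

**Local alignment.**  `local_align()` is Smith–Waterman with affine gaps
(a gap of length L costs `gap_open + L * gap_extend`), delegated to
`Biostrings::pairwiseAlignment()` and reported with percent identity over
alignment columns — the statistic behind element-similarity calls such as
a LINE-like repeat "69% identical over 181 nt".  Aligning against a
reverse complement is an explicit flag.  All-mismatch inputs return the
empty alignment with score 0.

## The synthetic atlas generator

Because the deposited atlas cannot be redistributed, `generate_dataset()`
builds an expression matrix of the same shape with known ground truth.
Its defaults *are* the study conditions: 3840 genes, four tissues, two
replicates, log2 scale.  Three gene classes are planted:

* **DE genes** (`n_de_genes = 400`, `de_effect = 2` log2 units): Gaussian
  noise plus a mean shift in one round-robin-assigned tissue.  A two-fold
  shift per tissue is a moderate, realistic effect for tissue-specific
  transcripts; 400 genes (~10%) leaves the raw-p filter's output in the
  hundreds, as in the published 547.
* **Module genes** (`n_modules = 8` of `module_size = 15`,
  `module_corr = 0.95`): each module shares a latent per-tissue profile
  plus independent gene noise.  The gene-noise variance is calibrated
  against the *realized* sample variance of the drawn profile,
  `sigma^2 = v_P (1 - r) / r`, so that the expected within-module sample
  PCC tracks `module_corr`; calibrating against the population profile
  variance instead biases the realized correlation noticeably downwards
  (to ~0.81 at a 0.90 target) because a four-tissue profile's sample
  variance is itself highly variable.  Module profiles are
  rejection-sampled to pairwise |PCC| <= 0.85 so distinct planted modules
  remain separable at the 0.90 edge threshold — with only four tissues,
  two unconstrained random profiles collide above 0.90 with appreciable
  probability.
* **Background genes**: i.i.d. Gaussian noise, `noise_sd = 0.5` log2
  units, a typical residual spread for spotted two-channel arrays.

The generator is bit-reproducible from its seed.  What it does *not*
emulate: dye bias, spatial artifacts, intensity-dependent variance,
correlated measurement error, or the heavy annotation redundancy of a
clone-based platform (several clones per gene).  Consequently, passing the
planted-recovery tests shows the pipeline's operations are correct and
well-calibrated under the design's sample sizes — it does not show that
any particular biological network is right, and the synthetic atlas's
*edge counts* in particular are much lower than the published ones, whose
noise is not i.i.d.  Pipeline runs therefore always report stage-wise
count diffs against reference counts rather than asserting agreement.

## Numerical and degenerate-input choices

* ANOVA is computed by vectorized group sums of squares; tiny negative
  sums from floating-point cancellation are clamped to zero.
* Correlation thresholding is strict; `NA` correlations (insufficient
  overlap, zero variance) never become edges.
* MCL columns re-normalize after pruning, so the working matrix stays
  stochastic to within the convergence tolerance at every step; an
  all-zero column (possible after aggressive pruning) is reset to a
  diagonal unit so the matrix stays stochastic.
* Hierarchical clustering uses Euclidean distance; the linkage is
  `average` by default and configurable (the original description names
  the distance but not the linkage).  Genes with missing values are
  dropped from clustering and PCA, with a message.
* PCA is computed on gene-centered, unscaled data via the singular value
  decomposition (`prcomp`); explained variance fractions sum to 1 over
  the full rank.
* All tabular outputs are written sorted, so identical runs are
  byte-identical.

## Problem sizes used in the checks

The package's own test suite exercises the full pipeline at the atlas's
native size (3840 x 8) once, and otherwise works at 100–300 genes, 20–30
network nodes for the MCL cross-checks, 200 null replicates for the
type-I-error calibration, and 40-mers for the alignment oracles — sizes at
which every independent oracle (brute-force correlation, dense MCL,
exhaustive window scoring, Gotoh DP) runs in seconds while still giving
the comparisons statistical teeth.

## Known limitations

* The published clustered-network and seed-network counts depend on
  normalization details, MCL pruning behaviour and seed clone identities
  that the original description leaves open; real-data runs should expect
  stage-wise diffs and should inspect them (`reference_counts` in
  `pipeline_config()`), not assume equality.
* With two replicates per tissue the ANOVA is underpowered and the PCC
  null is wide; both are faithfully reproduced properties of the design,
  not removable by implementation choices.
* The GEO reader handles the series-matrix table block (ratio or log2
  values, declared by the caller) and two-channel division via
  `ratio_from_channels()`; it does not download from GEO or parse full
  SOFT family files.
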
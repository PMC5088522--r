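---
title: "Gene age hallmarks and coexpression structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene age hallmarks and coexpression structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomark)
```

phylomark combines two views of a multi-tissue transcriptome: an
*evolutionary* view, in which every protein-coding gene is dated by the
lowest common ancestor (LCA) of its ortholog group on a time-calibrated
taxonomy lineage, and a *relational* view, in which genes are linked by
robust coexpression across tissues. This vignette explains the models and
procedures, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## Gene dating by ortholog-group LCA

A taxonomy is a single-rooted parent-pointer tree whose leaves are species.
The focal lineage is the ordered chain of clades from the root-most ancestor
(index 1) to the focal species (index $n$); for human it has 31 consecutive
levels, from *cellular organisms* to *Homo sapiens*, each calibrated with a
divergence age in million years ago (Mya). Ages decrease strictly along the
lineage and reach 0 at the focal species. The bundled calibration
(`human_lineage()`) uses TimeTree-style point estimates and is deliberately
user-editable (`read_lineage_yaml()`): the analysis depends on the *order*
of clades far more than on the exact ages, which only position points on the
time axis.

An ortholog group is the set of species in which orthologs of a focal gene
are found, the focal species included. The gene's age is the lineage level
of the group's LCA: because the focal species is a member, the LCA always
lies on the root-to-focal path. `lca()` implements the generic tree
operation; `assign_gene_ages()` exploits the lineage structure — the LCA's
lineage level is the shallowest attachment level among the members — which
is algebraically equivalent and is cross-checked against the generic
operation (and against a brute-force root-path-intersection oracle) in the
test suite. Groups lacking the focal species cannot be dated and are
skipped with a warning and a reported count.

### Hallmark stages and emergence profiles

Gene counts per lineage clade are coarse-grained into eight contiguous
"hallmark" stages. The default human scheme (`human_stage_scheme()`)
anchors stage boundaries at named clades: st1 cellular organisms; st2 up to
Eukaryota; st3 up to Metazoa; st4 up to Vertebrata; st5 up to Euteleostomi;
st6 up to Mammalia; st7 up to Primates; st8 through Homo sapiens.
`stage_profile()` reports per-stage counts, percentages of the total and
cumulative percentages in lineage order (always ending at 100%);
`time_axis()` places the cumulative curve on the Mya axis, and
`collapse_to_common_strata()` supports comparisons between assignments made
on different but nested stratifications. Counts are conserved at every
level of coarse-graining, and merging adjacent clades never changes the
cumulative value at surviving boundaries — both are tested properties.

## House-keeping and tissue-enriched genes

Expression is taken as an FPKM matrix over samples grouped into tissues
with 2–5 biological replicates. The working scale for value comparisons is
$\log_2(\mathrm{FPKM}+1)$; expression *calls* are made on the FPKM scale. A
gene is called expressed in a tissue if at least one replicate reaches
FPKM ≥ 1 (the threshold is inclusive and configurable). From the calls:

* **HK (house-keeping)** genes are expressed in *every sample* of every
  tissue and are additionally present in a curated reference list — the
  intersection guards against calling a gene HK on expression breadth
  alone.
* **TE (tissue-enriched)** genes are expressed in at most three tissues.
  Three (not one) tolerates physiologically coupled tissues that share
  expression programs, such as colon/rectum or duodenum/small intestine.

The strength of the HK-versus-reference overlap is summarised by the odds
ratio of the 2×2 table over the expressed-gene universe. Two estimators are
exposed: the conditional maximum-likelihood estimator under the noncentral
hypergeometric model, with its exact confidence interval (the
`fisher.test` estimator; the default, because its asymmetric exact bounds
are the natural companion of a Fisher test), and the cross-product ratio
$ad/bc$ with a Woolf log-normal interval and Haldane 0.5 correction for
empty cells. Reference genes outside the universe are dropped before
tabulation. The HK/TE expression contrast pools all gene-by-sample log2
values per class and reports the mean difference with two-sided Welch
t-test and Wilcoxon rank-sum p-values.

### The ambiguous mean-FPKM filter

Genes enter the analysis when their per-tissue replicate-mean FPKM reaches
1 — but "in all the selected tissues" versus "in at least one tissue" are
both defensible readings of such a filter. The literal all-tissues reading
would make every retained gene ubiquitous and leave nothing
tissue-restricted to classify, contradicting the existence of TE genes, so
`filter_expressed_genes()` defaults to the any-tissue reading and exposes
the literal one behind `rule = "all_tissues"`.

## Sample relatedness

Sample-to-sample distances are $1 - \rho$, with $\rho$ the Spearman
correlation of the genome-wide expression vectors (average ranks for ties —
standard Spearman; tie handling is not otherwise constrained). Because the
statistic is rank-based, FPKM and log2 inputs give identical distances, a
tested invariant. A zero-variance sample has undefined correlation; rather
than abort a whole clustering for one degenerate column, it is reported
with a warning and placed at the maximum distance (2). Agglomerative
clustering uses `hclust`, complete linkage by default with average linkage
available.

## The validated coexpression network

Candidate edges are all unordered gene pairs with full-sample Spearman
$r \ge 0.85$ (one-sided: strong anti-correlation is not coexpression;
zero-variance genes are excluded and counted). Candidates are then
*resampling-validated*: in each of 100 iterations, two replicates per
tissue are drawn at random (tissues with exactly two contribute both,
deterministically), correlations are recomputed on the subsample, and each
pair records whether it stayed at or above threshold. Only pairs validated
in **all** iterations enter the network. This de-weights correlations
driven by single outlier samples or by replicate structure. Candidate
pre-filtering before validation keeps the cost at
$O(|\mathrm{candidates}| \cdot n_\mathrm{iter})$ rather than all pairs per
iteration. One seeded generator draws all tissues of iteration $i$ before
$i+1$, making runs reproducible and invariant to gene and edge order.

Modules are found with the MCODE procedure: each vertex is weighted by the
core number $k$ of the highest $k$-core of its closed neighborhood times
that core's density; modules grow from the highest-weight unassigned seed,
admitting neighbors whose weight is at least $(1 - 0.2)$ of the seed
weight; post-processing removes singly connected members ("haircut") and
discards modules without a 2-core; each vertex belongs to at most one
module. Parameters default to the algorithm's published defaults (degree
cutoff 2, node score cutoff 0.2, 2-core, haircut on, fluff off). Note that
weight-guided growth targets dense regions but does not maximise density
per se: a module can cross a "bridge" between two equally heavy cliques,
because bridge endpoints inside a clique weigh as much as the clique's
interior. The test suite pins this behaviour explicitly rather than
pretending the algorithm separates everything a density intuition would.

Module ages: `module_age_composition()` reports per-stage member
proportions (members without an age assignment are counted separately),
and `age_homogeneity_test()` asks whether a module's dominant-stage
proportion exceeds what random age labels would give, by permuting stage
labels across the network's assigned nodes. The dominant-stage proportion
is discrete, so the default add-one p-value is valid but conservative; a
`tie_break = "randomized"` option implements the classical randomized
p-value for discrete statistics, which is exactly uniform under the null
and is the right choice for calibration checks. P-values are BH-adjusted
across modules.

## Term enrichment

Over-representation uses the hypergeometric upper tail including the
observed count, $p = P[X \ge k]$ with
$X \sim \mathrm{Hypergeom}(N, K, n)$ — the standard convention when the
tail side is not otherwise specified — with Benjamini–Hochberg adjustment
across terms. The universe is the analysed gene set (expressed genes, and
for stage tests the aged genes), configurable. Annotations are plain
two-column tables; no annotation snapshot ships with the package, and no
web enrichment service is called.

## The synthetic-data generator

The generator exists so that every downstream stage has planted ground
truth. It emulates a down-scaled multi-tissue FPKM study; the default
design is 10 tissues × 3 replicates and 2000 genes (a full 32-tissue, 2–5
replicate design is supported), with 20% HK genes, 15% TE genes, five
coexpression modules of 20 genes, and per-sample log2 noise of SD 0.25.
The original study analyses real data and prescribes no generative model,
so all distributional choices here are explicit stand-ins, chosen once to
be realistic and kept configurable:

* **HK genes**: gene-level baseline $\mathcal{N}(5, 1)$ in log2 units,
  clamped so every sample stays at or above FPKM 1 (the defining
  property).
* **TE genes**: expressed in 1–3 random tissues at level
  $3 + \mathcal{N}(0,1)$ log2 (lower and more variable than HK, as
  observed in real tissue atlases), uniform $[0, 0.5)$ FPKM elsewhere —
  off-tissues can never cross the threshold.
* **Module genes**: a per-tissue latent profile
  $\max(\mathcal{N}(5, 2), 0)$ broadcast to replicates, plus a nonnegative
  gene-level offset and per-sample noise. Replicates therefore correlate
  like biological replicates, and with zero noise all module genes share
  one rank pattern exactly (pairwise Spearman $r = 1$), which anchors the
  noise-free tests.
* **Background genes**: independent noise around a gene baseline
  $\mathcal{N}(3, 1)$ — no tissue structure, so background pairs reach
  $r \ge 0.85$ essentially never.
* **Gene ages**: HK genes draw stages with ancient-skewed weights, TE
  genes with recent-skewed weights, background genes follow a genome-wide
  hallmark profile; module genes take their module's planted stage.
  Ortholog groups are built by inverting the dating procedure — the focal
  species plus members attached at (and optionally below) the planted
  clade — so dating must recover the plant exactly, for 100% of genes.

What the generator does **not** emulate: read-level sequencing noise and
FPKM estimation, gene length and GC effects, correlated background
structure (batch effects, cell-type composition), partially overlapping
modules, and dating error from incomplete ortholog detection. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
calibrated on its own assumptions, not that real-data results would be
free of those confounders.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own testing budget: 2000-gene default simulations, 10,000
genes for age-recovery checks, 100 random trees × 100 taxon sets for LCA
oracle equivalence, 100 resampling iterations, and 500–1000 permutations
for homogeneity tests. Numerical details worth knowing:

* Thresholds (`FPKM >= 1`, `r >= 0.85`, mean-FPKM filter) are inclusive.
* Spearman ties use average ranks throughout.
* The stage-profile cumulative always ends at exactly 100% by
  construction.
* `overlap_stats_from_counts()` applies the Haldane correction only for
  the sample estimator; the conditional-MLE path handles zero cells
  natively.
* All generators and resampling loops consume a single integer seed;
  identical seeds give byte-identical outputs (a tested property).

## Known limitations

Real-data magnitudes from the study this package's design follows —
18,545 expressed genes, the 8,961/7,668/2,459 class counts, a
2,298-node/20,005-edge validated network, and the 1.61 log2 HK–TE mean
difference — require the full 116-sample tissue atlas and a
contemporaneous ortholog-database release. They are documented
**non-targets** here: the package reproduces the *arithmetic* on published
summary tables exactly, and validates the *methods* on planted synthetic
truth, but does not re-derive those dataset-scale numbers. Dating accuracy
on real data is bounded by ortholog-group quality, which the package takes
as input rather than inferring from sequences.
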
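# phylomark

**Gene age hallmarks and coexpression structure of tissue transcriptomes.**

phylomark is an R package for asking *how old are the genes a genome
expresses, and do coexpressed genes share an age?* It is aimed at
computational biologists working with multi-tissue RNA-Seq (FPKM) profiles
and ortholog-group resources, and it covers the whole analysis path:

1. **Phylostratigraphic gene dating.** Each protein-coding gene is dated by
   the lowest common ancestor (LCA) of its ortholog group on the focal
   species' taxonomy lineage — for human, the 31 consecutive NCBI clades
   from *cellular organisms* to *Homo sapiens* — calibrated in million
   years ago (Mya). Per-clade counts are coarse-grained into eight
   evolutionary **hallmark stages** (st1 Prokaryota … st8 Primates → *Homo
   sapiens*) and summarised as cumulative emergence curves on the time
   axis.
2. **House-keeping vs tissue-enriched classification.** From expression
   calls at FPKM ≥ 1, HK genes are expressed in every sample of every
   tissue *and* present in a curated reference list (overlap strength
   summarised by a conditional-MLE odds ratio with exact CI); TE genes are
   expressed in at most three tissues.
3. **A resampling-validated coexpression network.** Gene pairs with
   full-sample Spearman r ≥ 0.85 are kept only if they stay above threshold
   in 100/100 random two-replicates-per-tissue subsamples; dense modules
   are extracted with the MCODE algorithm and profiled by member age, with
   a permutation test for age homogeneity.
4. **Hypergeometric term enrichment** (upper tail, BH-adjusted) for stage
   sets and modules.
5. **A synthetic-data generator** that plants ground truth (gene classes,
   gene ages via invertible ortholog groups, coexpressed modules), so every
   stage of the pipeline is testable offline.

All user-facing functions are tibble-first and pipe-friendly; results come
with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Stage-profile arithmetic on a published-style per-stage count table:

```r
library(phylomark)

stage_profile(c(1178, 2178, 1395, 2333, 5070, 1953, 2821, 509))
#> Stage profile (all): 17437 genes over 8 stages
#> # A tibble: 8 × 5
#>   stage stage_label     n pct_of_total cumulative_pct
#>   <int> <chr>       <dbl>        <dbl>          <dbl>
#> 1     1 st1          1178         6.76           6.76
#> 2     2 st2          2178        12.5           19.2
#> 3     3 st3          1395         8.00          27.2
#> 4     4 st4          2333        13.4           40.6
#> 5     5 st5          5070        29.1           69.7
#> 6     6 st6          1953        11.2           80.9
#> 7     7 st7          2821        16.2           97.1
#> 8     8 st8           509         2.92         100
```

6.76% of genes date to the prokaryotic stage; the largest single step is
st5 (Vertebrata → Euteleostomi, 29.1%), and the cumulative curve reaches
97.1% by the end of st7 — new-gene emergence has essentially saturated
before the primate-specific stage.

Overlap between an expressed-in-all-samples set (7,668 genes) and a
3,804-gene reference HK list, 3,524 shared, in an 18,545-gene universe:

```r
overlap_stats_from_counts(3524, 7668 - 3524, 3804 - 3524, 18545 - 7668 - 280)
#> Overlap odds ratio (cmle): OR = 32.19 [28.36, 36.72], p = 0
#> 2x2 table (a,b,c,d): 3524, 4144, 280, 10597; overlap = 92.6%
```

An odds ratio of ~32 means reference HK genes are vastly over-represented
among genes expressed in every sample — breadth of expression and curated
house-keeping status agree strongly.

End to end on a simulated study (2000 genes, 10 tissues × 3 replicates,
five planted 20-gene modules):

```r
run <- run_pipeline(list(seed = 1))
run
#> phylomark pipeline run
#>   expressed genes: 1989 (in all samples: 1615; ubiquitous: 1671)
#>   HK: 400, TE: 300 (overlap OR = Inf)
#>   dated genes: 2000; validated edges: 878; network: 100 nodes / 878 edges; modules: 5
```

All 400 planted HK and 300 planted TE genes are recovered (the infinite OR
is expected here: the planted reference is by construction a subset of the
expressed-in-all set). The validated network contains exactly the planted
module genes, and the five MCODE modules are age-pure — each one's
dominant stage is its module's planted stage:

```r
asn <- assign_gene_ages(run$data$groups, run$data$taxonomy,
                        run$data$lineage, scheme = run$data$scheme)
comp <- module_age_composition(run$modules, asn)
comp[comp$dominant, ]
#> # A tibble: 5 × 6
#>   module_id stage     n proportion n_unassigned dominant
#>   <chr>     <int> <int>      <dbl>        <int> <lgl>
#> 1 module_01     2    20          1            0 TRUE
#> 2 module_02     5    20          1            0 TRUE
#> 3 module_03     7    20          1            0 TRUE
#> 4 module_04     8    20          1            0 TRUE
#> 5 module_05     1    15          1            0 TRUE
```

See `vignette("phylomark-methods")` for the models, parameter rationale
and known limitations. Real-dataset magnitudes from the tissue-atlas
literature (e.g. an 18,545-gene expressed universe or a 2,298-node
validated network) require the corresponding full datasets and are
explicitly out of scope here.

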
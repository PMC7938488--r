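# iepbcc

Bipartite clustering analysis of interacting enhancer–promoter pairs (IEPs).

## The problem

Enhancers regulate distal genes through physical chromatin contacts, and a
central question in regulatory genomics is how enhancers *share* their
target genes: does each enhancer pick its targets independently, or do
groups of enhancers act together on a common gene set? `iepbcc` answers
this from experimentally supported interaction data. It builds IEP sets
from chromatin-interaction evidence (Hi-C loop lists, sparse normalized
contact matrices at a read-count cutoff, or generic two-anchor link tables
from ChIA-PET / promoter-capture Hi-C / SPRITE), applies cell-specific
activity filters, and measures target sharing with the **bipartite
clustering coefficient (BCC)**.

Every IEP set is a bipartite graph with enhancers on one side and target
genes on the other. For two same-side nodes *u*, *v* with neighbor sets
*n(u)*, *n(v)*:

    BCC(u, v) = |n(u) ∩ n(v)| / |n(u) ∪ n(v)|

and the per-node coefficient averages this over the set *n(n(u))* of nodes
sharing at least one neighbor with *u*:

    BCC(u) = Σ_{v ∈ n(n(u)), v ≠ u} BCC(u, v) / (|n(n(u))| − 1)

A BCC near 1 means that two enhancers sharing one target tend to share
*all* their targets — i.e. enhancers form clusters that synchronously
contact a common gene set. The package tests this against
degree-preserving random IEPs with an upper-tail binomial test, groups
enhancers into clusters as maximal cliques of the shared-target graph
(Bron–Kerbosch), classifies each cluster's genes into fully and partially
shared targets, and characterizes clusters by member distances and
consecutiveness, super-enhancer overlap, TAD containment, and cross-sample
sharing. A synthetic-data generator with planted enhancer-cluster/gene-set
bicliques and tunable edge noise makes the whole pipeline testable without
any external downloads.

Intended users: computational biologists analyzing enhancer–promoter
interaction catalogs who want a reproducible, tested implementation of the
BCC statistic and its companion cluster analyses.

## Worked example

Generate a miniature chromosome with 10 planted enhancer clusters and 5%
spurious-contact noise, then run the core analyses:

```r
library(iepbcc)

truth <- generate_synthetic(synthetic_config(n_clusters = 10,
                                             noise_add_rate = 0.05,
                                             seed = 42))
graph <- bipartite_graph(truth$noisy_ieps)
average_bcc(graph, "enhancer", "all")
#> BCC summary (enhancer side, restrict = all)
#>   mean BCC over 37 eligible node(s): 0.8784
#>   % nodes with multiple partners and BCC > 0: 75.68
#>   % of those with BCC >= 0.90: 71.43

clusters <- find_enhancer_clusters(truth$noisy_ieps, truth$enhancers)
clusters
#> 11 enhancer cluster(s); sizes: 2 5 4 3 5 3 3 3 4 4

null_pool <- unlist(lapply(1:5, function(s)
  bcc_pool(bipartite_graph(randomize_ieps(truth$noisy_ieps, truth$enhancers,
           truth$promoters, side = "enhancer", seed = s)), "enhancer")))
compare_to_null(bcc_pool(graph, "enhancer"), null_pool)
#> binomial test: 20 of 28 observed nodes with BCC > 0.90 (null frequency 0.0000)
#>   p-value = 0

tad_containment(clusters, truth$tads, truth$enhancers)$average
#> [1] 100
```

Reading: despite the injected noise the mean enhancer BCC stays high
(0.88), most multi-target enhancers keep BCC ≥ 0.9, and no node in the
five degree-preserving random replicates exceeds 0.9, so the binomial
upper tail underflows to 0 — target sharing at this level does not arise
by chance. The 11 recovered cliques are the 10 planted clusters plus one
noise-induced split, and every cluster sits inside a single TAD by
construction.

For real data, `run_pipeline()` drives the same stages from a config list
pointing at enhancer BEDs, a GENCODE-style GTF, interaction files in any
of the three dialects, and optional H3K27ac/expression activity evidence,
super-enhancer and TAD annotations; it writes per-stage TSV/JSON artifacts
and a manifest.

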
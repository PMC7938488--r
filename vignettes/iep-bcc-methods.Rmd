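---
title: "Methods: bipartite clustering of enhancer-promoter interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite clustering of enhancer-promoter interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iepbcc)
```

## The model

An IEP set — a collection of interacting enhancer-promoter pairs from one
sample — is treated as a bipartite graph: enhancers on one side, target
genes on the other, an edge per pair with physical contact evidence. The
statistic of interest is the bipartite clustering coefficient. For two
same-side nodes $u$, $v$ with neighbor sets $n(u)$, $n(v)$,

$$BCC(u,v) = \frac{|n(u) \cap n(v)|}{|n(u) \cup n(v)|},$$

the Jaccard similarity of their partner sets, and per node

$$BCC(u) = \frac{\sum_{v \in n(n(u)),\, v \neq u} BCC(u,v)}{|n(n(u))| - 1},$$

where $n(n(u))$ is the set of same-side nodes sharing at least one
partner with $u$. Averaging $BCC(u)$ over eligible nodes summarizes how
strongly enhancers (or genes) share partners: a value near 1 means two
enhancers sharing one target tend to share all their targets, the
signature of enhancer clusters acting on a common gene set.

Two reading conventions in the per-node formula deserve care, and both
are fixed here by the worked three-enhancer example (`e1`-{p1,p2,p3},
`e2`-{p1,p2}, `e3`-{p1}, whose per-node values are 1/2, 7/12 and 5/12 and
whose average is exactly 0.5):

* $u \in n(n(u))$ whenever $\deg(u) \ge 1$, so the denominator
  $|n(n(u))| - 1$ counts the *other* sharing nodes (the worked example
  needs denominator 2 for all three enhancers);
* a node sharing no partner with any other node has an *undefined* BCC
  (`NA`), not 0, and is excluded from averages. Scoring such nodes 0
  would deflate the mean with nodes that carry no information about
  sharing.

`average_bcc()` reports the mean either over all defined nodes
(`restrict = "all"`) or only over nodes with $\ge 2$ partners
(`restrict = "multiple"`); single-partner nodes can only contribute BCC
values through other nodes' neighborhoods, so the "multiple" view
isolates the nodes whose own sharing behavior is measurable. Two headline
percentages accompany the mean: the share of side-nodes with multiple
partners and BCC > 0, and the share of those at or above 0.9. The
summary tables use an inclusive $\ge 0.9$; the significance test uses a
strict $> 0.9$. Both conventions appear in practice and the package
follows each location's usage rather than silently unifying them — the
difference only matters for nodes at exactly 0.9, which arise from small
rational neighbor-set ratios and are rare on real data.

## Building IEP sets

**Coordinates.** Every interval is 0-based half-open (BED convention);
the GTF reader converts its 1-based inclusive coordinates on input, with
TSS = start − 1 on `+` genes and end − 1 on `-` genes. "Overlap" always
means at least one shared base under half-open arithmetic — the weakest
consistent reading, applied uniformly to activity filters and anchor
overlaps. Chromosome names are normalized to one prefix style because
loop lists and gene annotations disagree about `chr`.

**Promoters.** One promoter per annotated gene: the window from 1000 bp
upstream to 100 bp downstream of the TSS, oriented by strand. The window
includes the TSS base itself (1101 bp total); upstream/downstream phrasing
does not determine inclusivity, so the symmetric, testable convention was
adopted. Windows are clipped at position 0.

**Activity.** Enhancers are kept when they overlap H3K27ac peaks (or,
for samples without H3K27ac data, the interaction anchors themselves);
promoters when their gene reaches 0.30 RPKM, applied inclusively, with
genes absent from the expression table treated as unexpressed. `none`
evidence passes everything through — the rule for segmentation-derived
enhancers that are already cell-specific and for samples without RNA-seq.

**Interaction dialects.** Three readers feed one pair representation:
loop lists (two ~5-kb anchors, no quantitative support — stored as `NA`,
never 0, so cutoff filters cannot be wrongly triggered), sparse 5-kb
contact matrices with optional normalization vectors (raw counts divided
by the product of the two bins' factors, entries with NaN factors
dropped, symmetric duplicates collapsed to the upper triangle keeping the
maximum), and schema-mapped link tables. IEPs are formed across anchors
only: an enhancer on one anchor pairs with every promoter on the other
anchor, in both orientations, and a single wide feature overlapping both
anchors never creates self-evidence. Duplicate pairs found under several
records keep the maximum support, not the sum, because records at
adjacent bins are not independent. In cutoff mode a pair qualifies when
some bin pair reaches the cutoff (inclusive "at least"); only existence
matters, so the output is monotone non-increasing in the cutoff.

**Distance filter.** IEPs whose enhancer-to-promoter-window gap is below
2.5 kb are removed. The gap is measured between closest interval ends (0
when overlapping) rather than between midpoints: it is the conservative
choice, removing the most ambiguous near pairs where a 5-kb anchor can
cover both features at once.

## Significance against degree-preserving nulls

Random IEP sets preserve one side's degrees exactly: each enhancer is
re-paired with partners drawn uniformly without replacement from the
same-chromosome promoter universe (dually for promoters). The universe
defaults to all active same-chromosome partners, not only those appearing
in IEPs — the weaker null; intra-chromosomality is forced by the IEP
invariant. Candidates violating the 2.5-kb rule are excluded before
sampling (equivalent to redrawing invalid picks, since sampling without
replacement is uniform over valid subsets), because the observed IEPs
were so filtered and an unfiltered null would differ trivially. Five
replicates with consecutive seeds are the default, pooled into one null
sample; pooling (rather than averaging per-replicate frequencies) matches
how the observed side is pooled and keeps the frequency estimate stable
when single replicates have few multi-partner nodes.

The test statistic is the count $k$ of observed multi-partner nodes with
BCC > 0.9 among $n$, against the null frequency $p$ of the pooled
replicates, with the upper-tail binomial p-value

$$p\text{-value} = 1 - \sum_{i=0}^{k-1} \binom{n}{i} p^i (1-p)^{n-i}.$$

The sum is evaluated as the complementary upper tail in log space
(log-sum-exp over `lchoose` terms): the literal alternating-style
summation loses all precision for $n$ in the thousands, while the
log-space tail is accurate to ~12 significant digits against a
cumulative-distribution oracle and cleanly underflows to 0 — reported as
0, matching how vanishing p-values are conventionally stated — when the
observed count is unreachable under the null. Degenerate inputs are
pinned: $k = 0$ gives 1 (empty sum), $p = 0$ gives 0 for $k \ge 1$, and
an empty null pool sets $p = 0$.

Rank comparisons (within-cluster distances or sequence similarities vs
random pairs) use the standard two-sided Mann-Whitney test with normal
approximation and tie correction.

## Enhancer clusters

The shared-target graph joins enhancers with at least one common target;
clusters are its maximal cliques with at least two members, enumerated by
Bron-Kerbosch (cliques may share enhancers; output order is made
deterministic by sorting member ids). Each cluster's target genes split
into *fully shared* (adjacent to every member) and *partially shared*
(adjacent to a proper non-empty subset); the two sets partition the
target union, and partial targets vanish exactly when the cluster's
enhancers have identical neighbor sets.

Cluster geometry statistics measure gaps between coordinate-adjacent
members (end-to-start, 0 when overlapping; midpoint distance would
penalize long enhancers). "Consecutive" is not self-defining, so one
rule is isolated behind a single helper: an adjacent member pair is
consecutive when no other active enhancer lies strictly within the gap
between the two intervals, and a member counts as consecutive when at
least one flanking pair is. Both per-member and per-pair percentages are
reported, since either accounting is defensible. The same construction
applies to target genes over the active-gene universe. Histogram bin
edges default to {0, 5k, 10k, 20k, 50k, 100k, 500k, 1M, 2M, ∞} bp,
reflecting that cluster members can sit up to two megabases apart.

Cross-sample sharing is directional (clusters of sample A found in B)
and defaults to exact member-coordinate-set equality — the strictest
reading of "the same cluster". A reciprocal span-overlap rule
(default 50%) is available for comparing samples whose enhancer
coordinates are segmentation-derived and therefore jittered.

Sequence identity between cluster members is percent identity of a
global Needleman-Wunsch alignment (matches / alignment columns, terminal
gaps included). Scores default to +1/−1 with a per-base gap penalty of
−2 and are config-exposed, since percent identity is only meaningful
relative to a stated scoring scheme.

**Super-enhancers and TADs.** A cluster overlaps a super-enhancer when
its *span* (first member start to last member end) shares ≥ 1 bp — the
span, not individual members, because the question is whether the
genomic region containing the cluster is the super-enhancer. Both
directional percentages are reported, plus span-within-SE fractions. TAD
containment chooses, per cluster, the single TAD fully containing the
most members (ties to the leftmost TAD); members straddling a boundary
are not contained. Inter-TAD gaps can optionally be treated as implicit
domains (off by default).

## The synthetic generator

`generate_synthetic()` emulates exactly the structure the analysis is
designed to detect: a linear chromosome with non-overlapping features
laid out left to right; `n_clusters` planted bicliques of 2-5 enhancers
(200-1000 bp) by 1-4 genes; intra-cluster gaps log-uniform on 1-20 kb
with a 5% tail out to 2 Mb, echoing that most cluster members sit within
10 kb while a minority are much farther; gene TSSs strand-alternating to
exercise both promoter-window orientations; singleton enhancers with no
planted interactions; and one TAD per cluster covering all its features
(`cover_clusters`) or random TADs. Every planted enhancer-promoter
window gap is at least 2.5 kb, so the distance filter is vacuous on
clean data and recovery can be asserted exactly.

Noise has two dials: `noise_drop_rate` deletes planted edges
(false negatives); `noise_add_rate` adds spurious edges (false
positives), by default only within TADs — contact false positives are
distance-bounded in practice, and the within-TAD candidates are the
singleton-enhancer x cluster-gene pairs — with a genome-wide mode under
`tad_policy = "random"` for worst-case tests. At zero noise the data sit
in the idealized regime: mean BCC 1 on both sides, recovered cliques
identical to planted clusters, no partially shared targets.

`emit_fixture()` writes the dataset in the external dialects (BED, a
minimal GENCODE-style GTF, the IEP TSV, a link table with 1-kb anchors
centered on enhancer midpoints and TSSs, TAD and super-enhancer BEDs,
truth JSON); re-reading the link table through the overlap and distance
stages reproduces the noisy IEP list exactly, which pins the whole I/O
and construction path end to end.

What the generator does **not** emulate: raw contact-count distributions
and their distance decay, inter-chromosomal noise, overlapping or nested
enhancers, transcript-level promoter multiplicity, segmentation jitter
between samples, and biased (non-uniform) false-positive placement.
Passing tests therefore certify the algorithmic pipeline — construction,
statistics, clustering, annotation — on data with known truth, not the
biological completeness of any particular upstream catalog.

## Problem sizes and numerical conventions

The test suite checks formulas against independent oracles: brute-force
per-node BCC on 200 random bipartite graphs of up to 8+8 nodes (tolerance
1e-12), exhaustive subset enumeration of maximal cliques on 50 random
graphs of up to 14 vertices, and the binomial tail against the
cumulative-distribution function on a grid up to $n = 200$ (12
significant digits). Planted-structure recovery uses the default 30
clusters; noise monotonicity averages 20 seeds per noise level
{0, 0.02, 0.05, 0.1}; null separation uses 30 clusters of 3 enhancers by
3 genes with five pooled replicates. These sizes keep the full suite
under a minute while leaving each property's failure modes visible —
larger runs change nothing structurally, as every statistic is exact
given the graph.

Other numerical choices: exact rational results (toy example) are
asserted to 1e-12; sampling uses R's default RNG under `withr`-scoped
seeds so library state never leaks; all randomized APIs take explicit
seeds and reruns are byte-identical; ties in TAD selection go to the
leftmost domain; empty inputs return typed empty results rather than
errors wherever the empty case is meaningful (empty BED, header-only
loop list, empty cluster list), and error otherwise (empty observed BCC
pool, empty alignment input).

## Limitations

* The analysis consumes called interactions; it does not call loops from
  raw contact data, and a cutoff on normalized counts inherits whatever
  normalization the input used.
* One promoter per gene. Alternative TSSs of the same gene are collapsed,
  which undercounts promoter-side multiplicity for genes with widely
  separated TSSs.
* The null preserves one side's degrees only; a both-sides-preserving
  edge-swap null is deliberately out of scope because the reference
  procedure randomizes one side.
* Cross-sample cluster identity by exact coordinates is strict; for
  segmentation-derived enhancers the span-overlap rule should be used,
  and its 50% threshold is a convention, not an inference.
* Functional enrichment of target genes is not implemented (external
  web-tool territory).
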
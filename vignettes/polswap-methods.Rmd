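---
title: "Detecting DNA polymerase swapping in phage genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA polymerase swapping in phage genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polswap)
```

## The problem

Tailed bacteriophages (*Caudoviricetes*) replicate with a DNA polymerase
(DNAP) from one of three families -- PolA, PolB or PolC -- that are so
distantly related as to be effectively unrelated at the sequence level.
Occasionally a phage lineage replaces its DNAP gene "in situ" with one from a
different family, or with a highly divergent group of the same family, while
the surrounding gene order is preserved. Such swaps are detectable as
DNAP-family heterogeneity inside groups of otherwise closely related genomes.

polswap implements the comparative-genomic machinery for finding these
events: a whole-proteome genome distance, a genome tree, fixed-depth clades,
DNAP family classification, and parsimony counting of replacements -- plus a
genome simulator that plants swaps with known ground truth, so every stage
can be validated without downloading genome collections.

## The genome distance

Genomes are compared through their ORF complements. For each genome, all ORFs
of at least 75 nt (stop codon included) are extracted from all six reading
frames: within each stop-to-stop segment of a frame the longest ORF -- first
start codon (ATG/GTG/TTG) through the stop -- is kept, and ORFs in different
frames may overlap. Translation uses the bacterial code (table 11) with the
initiator rendered M. A trailing ORF that reaches the sequence end without a
stop is kept, since phage genome records are often permuted mid-gene.

For a genome pair (A, B), reciprocal best hits (RBH) are computed between the
two ORF complements by Smith-Waterman local alignment under BLOSUM62 with
affine gaps (open 11, extend 1). A hit qualifies if it covers at least 50% of
the query protein and its e-value is at most 1e-3; e-values use fixed
Karlin-Altschul constants (lambda = 0.267, K = 0.041) with the partner
proteome as the search space. These are threshold devices, not calibrated
significance estimates. The distance is

D(A,B) = 1 - (C(A,B) + C(B,A)) / (L(A) + L(B)),

where C(A,B) is the length of genome A covered by ORFs that have an RBH in
genome B (interval union, so overlapping ORFs count once) and L are the
genome lengths. D is symmetric and lies in [0, 1]. The self-distance is fixed
at 0: under the formula it would equal the intergenic fraction, which would
distort tree building. Note that even nearly identical genomes have
D roughly equal to their non-ORF fraction as the lower end of the
between-genome scale.

Two search heuristics keep the all-vs-all step tractable without changing
which qualifying hits are reported: protein pairs sharing no exact 4-mer are
skipped (word seeding, as in heuristic search tools; this can in principle
miss marginal hits between highly diverged proteins, the same trade-off the
heuristic searches used in large-scale practice make), and a score-only
dynamic-programming pass prunes pairs that cannot reach the qualifying raw
score before the full traceback alignment is run (this second pass is exact).
`align_pair()` and DNAP classification always use the full alignment.

## Genome tree and ultrametrization

The tree is built from the distance matrix by neighbor joining (negative
branch estimates clamped to zero) and midpoint-rooted. Neighbor joining was
chosen over balanced-minimum-evolution search because it is deterministic,
dependency-free, and exact on additive matrices; the subsequent
ultrametrization absorbs most branch-length differences between the two
methods. Midpoint rooting is used because it is deterministic and
parameter-free.

Ultrametrization iterates from the leaves toward the root. At an internal
node with child subtrees of stem-inclusive heights H_1..H_k, the balanced
height is H_0 = mean(H_i), and all edges of subtree i including its stem are
scaled by q_i = H_0 / H_i. Including the stem in both the height and the
scaling is forced by the requirement that the subtrees actually reach height
H_0 at the node. Two conventions generalize the binary description: at
multifurcations H_0 is the arithmetic mean over all children, and a
zero-height child (H_i = 0) gets its stem set to H_0 directly, the limit of
the scaling rule. The result has exactly equal leaf depths, the topology is
unchanged, and the operation is idempotent.

For the worked example `((a:1,b:3):2,c:10)`: the inner node balances a and b
to height 2; at the root H_1 = 2 + 2 = 4 and H_2 = 10 give H_0 = 7, so the
(a,b) side is scaled by 7/4 and c by 7/10, and every leaf ends at depth 7.

## Clades, classification, and swap detection

The ultrametric tree is cut at depth 0.15 (about a third of the typical tree
depth, roughly a genus-level grouping): the clades are the maximal subtrees
of height at most 0.15, which partition the leaves. Downstream analysis
focuses on clades with more than one genome.

Each ORF is classified by its best local-alignment hit against a labeled
reference set of PolA/PolB/PolC proteins, at e-value at most 1e-4 against the
whole reference set. This single-pass best-hit search replaces the iterative
profile-based search a large-scale survey would use; at simulated scale the
reference-to-target divergence is controlled, so profile sensitivity is
unnecessary. Called proteins of the same family are then subgrouped by
single-linkage clustering at 0.5 global identity (matches / alignment
columns), labeled A1, A2, ... by decreasing cluster size.

Two types of DNAP heterogeneity are flagged per clade: type i, two or more
families among genomes carrying exactly one DNAP each (the swap signature);
type ii, a single genome carrying DNAPs of two or more families. Type-i
clades are grown into swap clades by merging with sister subtrees as long as
the sister contains at least one DNAP-encoding genome (the most conservative
reading of sister grouping; nested candidates are deduplicated to maximal
subtrees).

Swap events are counted by exact unit-cost small parsimony on the genome
tree: the minimum number of edges on which the leaf state changes, over all
ancestral labelings. Genomes without a DNAP are wildcards (absence is not
evidence of a transition); genomes with several DNAPs carry their family set.
The count is computed twice: on family states (inter-family swaps) and on
family+subgroup states (total swaps including intra-family replacements);
the refined count is never smaller. The Fitch set-merging procedure equals
this minimum on binary trees, but the common sequential-merge generalization
to multifurcations can undercount (four children with states A, A, B, B yield
one union event but two changes), so the implementation uses the unit-cost
Sankoff recursion, which is exact on any rooted tree; tests verify it against
exhaustive enumeration of ancestral labelings, including multifurcations and
wildcards.

## The simulator

`simulate_dataset()` generates datasets that exercise every assumption above:

* **Phylogeny**: Yule (pure-birth) topology, rescaled to a chosen ultrametric
  height (default 0.35 expected substitutions per site).
* **Genomes**: 20 protein-coding genes of 300 nt (ATG start, stop-free frame,
  terminal TAA) separated by 60 nt spacers -- a miniature of real phage
  genomes, whose gene-dense organization the distance formula relies on;
  32 genomes by default.
* **Evolution**: Jukes-Cantor substitutions per branch, with substitutions
  that would create an internal stop or destroy the start codon redrawn among
  permitted bases. This keeps ORFs intact (so the ORF caller's assumptions
  hold) with minimal machinery, at the cost of a slight downward bias in
  coding-site divergence relative to the nominal rate.
* **Rate variation**: lognormal per-gene rate multipliers (sd 0.7 on the log
  scale). This matters: the RBH distance reacts to divergence through ORFs
  dropping below the coverage/e-value thresholds, so with a single global
  rate all genes would cross the detection threshold together and distances
  would saturate abruptly. Rate variation makes RBH loss, and hence D, grow
  gradually -- the property the real data have because real genes evolve at
  very different rates.
* **DNAPs**: one designated slot (the middle gene) carrying a family exemplar;
  families are independent random genes (expected identity ~5%, far below
  any threshold, mirroring the effectively unrelated real families);
  within-family subgroups are variants at ~40% identity -- unambiguous family
  members that stay below the 0.5 subgroup-clustering threshold even after
  further drift along the tree (variants near 60% would single-linkage-merge
  with the parent subgroup and planted intra-family swaps would be
  undetectable by construction). The DNAP slot evolves at a reduced rate
  (multiplier 0.3), reflecting the strong conservation of polymerases.
  An optional second slot exercises type-ii heterogeneity.
* **Swaps**: each planted event replaces the DNAP gene at the top of a chosen
  branch with a donor family/subgroup exemplar, which then evolves down the
  subtree -- flanking genes untouched, the "in situ" property.
  `choose_swap_branches()` picks terminal branches whose nearest relative is
  close (so the swapped genome shares a shallow clade with an unswapped one)
  and that are mutually distant (so events are independent on the tree).

Everything is deterministic given the config seed.

What the simulator does *not* emulate: recombination, gene gain/loss beyond
the DNAP slot, rearrangement/permutation, codon-usage bias, and the sheer
scale and heterogeneity of public genome collections. Passing tests therefore
demonstrate that the machinery is correct and recovers planted truth under
controlled conditions, not that the thresholds are optimal for survey-scale
data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_orf_len` | 75 nt | minimum ORF length, stop codon included |
| RBH e-value | 1e-3 | qualifying-hit ceiling for the distance step |
| `min_cover` | 0.5 | minimum query coverage for a qualifying hit |
| classification e-value | 1e-4 | DNAP family call threshold |
| `clade_depth` | 0.15 | height of the fixed-depth clades |
| `subgroup_identity` | 0.5 | single-linkage threshold for within-family subgroups |

The 75 nt, 50%, 1e-4, 0.15 and 0.5 values are the analysis's canonical
settings; the RBH e-value ceiling, the substitution matrix and the
Karlin-Altschul constants are conventions chosen here (a permissive ceiling
mimics default search behavior; e-values act only as thresholds).

## Numerical choices and degenerate inputs

* Best hits are tie-broken deterministically: bit score, then alignment
  length, then lexicographically smaller subject id. All stages are
  deterministic given inputs and config.
* ORF length includes the stop codon and the 75 nt minimum applies to that
  length; one ORF per stop-segment per frame (nested shorter ORFs are not
  emitted); genomes are treated as linear; codons containing N never match a
  start or stop and translate to X.
* Ultrametricity checks use a relative leaf-depth spread of 1e-9; zero-height
  subtrees are aligned by setting their stem to the balanced height.
* Empty proteomes yield an empty RBH set with a warning, not an error;
  coverage of an empty set is 0 and the pair's distance is 1.
* `count_swaps_fitch()` returns 0 when at most one state is observed; a tip
  absent from the state map is an error (a tip *known* to lack a DNAP must be
  passed explicitly as `NA`).

## Problem sizes used in validation

The bundled validation runs at desk scale, chosen to finish quickly while
leaving the statistics meaningful: 20 simulated datasets of 32 genomes x 20
genes with 3 planted inter-family swaps each for end-to-end recovery; 200
random sequences/trees/replicates for the oracle-equivalence and property
checks; 100 random additive matrices for tree exactness. Survey-scale
headline numbers (tens of thousands of genomes) depend on a specific public
genome snapshot and a profile-search toolchain and are out of scope here.

## Known limitations

* Single-pass best-hit classification is less sensitive than iterative
  profile search; on real survey data it would miss the most divergent DNAPs
  (the package accepts extra labeled reference families, e.g. for divergent
  PolA-like groups, but builds no profiles).
* Parsimony on the genome tree counts a lower bound on swap events; manual
  reconciliation of genome and DNAP trees can resolve reticulate histories
  that parsimony undercounts.
* The sister-grouping rule is one defensible reading of a one-sentence
  procedure; alternatives (e.g. requiring heterogeneous sisters) would give
  smaller swap clades.
* Neighbor joining is exact only on additive matrices; RBH coverage distances
  are not additive, so deep topology should be read with the usual caution.

## A minimal run

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(n_leaves = 16, seed = 1), n_swaps = 2)
res <- analyze_genomes(ds$genomes, ds$refdb, truth = ds$truth)
glance(res$report)           # summary counts and tree-wide swap minima
res$report$swap_clades       # per-swap-clade membership and counts
autoplot(res$dist)           # distance heatmap
autoplot(res$report)         # DNAP families per clade
```
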
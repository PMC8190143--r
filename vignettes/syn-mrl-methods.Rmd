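---
title: "Microsynteny network phylogenomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsynteny network phylogenomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmrl)
```

## The problem

Most phylogenomic pipelines infer species trees from sequence alignments.
`synmrl` instead uses the *arrangement* of genes along chromosomes:
conserved local gene order (microsynteny) decays through genome
rearrangement, polyploidy and fractionation, and the pattern of which
genomes still share a syntenic context is itself a phylogenetic character.
This is attractive exactly where alignment-based inference is contentious
(deep radiations with extensive gene-tree conflict, lineages with dynamic
genome structure) because the characters are whole-genome structural
features rather than per-gene substitution histories.

The pipeline has four stages:

1. **Synteny block detection.** From per-genome gene positions and an
   all-vs-all homology search, pairwise collinear blocks are detected for
   every genome pair (including self-comparisons, which recover
   within-genome duplicated blocks).
2. **Network construction and clustering.** Anchor pairs from all blocks
   form one undirected, unweighted *synteny network*; its clusters
   (connected components by default) group genes sharing a syntenic
   context.
3. **Matrix representation.** Each cluster's *phylogenomic profile* (the
   number of member genes per species) is binarised to presence/absence;
   profiles over all clusters form a species-by-cluster binary matrix.
4. **Maximum-likelihood tree inference.** The binary matrix is analysed
   under a two-state Markov model with free state frequencies and
   FreeRate rate heterogeneity; supports come from nonparametric
   bootstrap; topologies are compared by Robinson-Foulds (RF) distance.

A stochastic simulator of gene-family syntenic-network evolution generates
data with the statistical structure the method assumes, and is used for
all validation experiments.

## Collinear block detection

Blocks are chains of anchor pairs. All positional logic uses 0-based gene
*ranks* along each chromosome (input base-pair starts are used for sorting
only, so 0/1-based input conventions are irrelevant; ties at equal start
break lexicographically by gene id for determinism). Three parameters
govern detection, with defaults matching the widely used "b5s5m25"
setting for plant genomes:

* `b_top` (default 5) — top homologous pairs retained per query, ranked by
  e-value, then bitscore, then subject id;
* `a_min` ("s", default 5) — minimum anchors per block;
* `g_max` ("m", default 25) — maximum intervening genes between
  consecutive anchors. We bound the gap *independently on each genome*
  ("max gene gaps" is read per genome, not as a sum); this is the stricter
  of the two readings and is flagged for sensitivity analysis via the
  exposed parameter.

Before chaining, tandem arrays are collapsed: hits sharing one endpoint
whose other endpoints form a transitively chained array (consecutive
members within `tandem_gap = 5` ranks) reduce to the single hit with the
smallest e-value (ties: larger bitscore, then smaller gene id). This
prevents local duplicate stacks from inflating chains.

Chaining itself is an exact dynamic program per chromosome pair and
orientation: the maximum-cardinality chain with strictly increasing query
ranks, strictly monotone subject ranks and both gaps within `g_max` is
extracted; its hits are removed, and extraction repeats best-first until
no chain reaches `a_min`. Chain score is the anchor count — no e-value
weighting — since the anchor count is what the `a_min` threshold is
defined on. Ties prefer forward orientation, then the chain with the
smallest starting ranks, making output deterministic. Anchor pairs are
canonicalised before chaining, so reciprocal comparisons (A vs B and
B vs A) yield identical networks; identical-gene self pairs are excluded.

## Network, clusters and profiles

The network is simple, undirected and unweighted; nodes exist only
through blocks, so every node has degree at least one. Default clustering
is connected components, which is exactly the definition used by the
simulation methodology. Map-equation community detection (for
empirical-scale networks) is supported by ingesting its output via
`cluster_network(method = "external")`; re-implementing it is out of
scope, and clusters smaller than two genes are dropped in either mode.
Summary statistics (node/edge counts, mean local clustering coefficient
with degree-<2 nodes contributing zero, syntenic percentages per genome
pair, per-species node fractions) reproduce the metrics used to profile
empirical networks.

Profiles are species-by-cluster gene counts; binarisation thresholds at
presence. Species ending up with all-zero rows are kept and flagged — in
practice they indicate genomes whose annotation quality deserves scrutiny.

Two derived encodings are provided:

* **CSSC selection** screens for Conserved Single-copy Synteny Clusters
  usable as sequence markers: median copy number below 2, presence in at
  least 90% of genomes, and at least 50% presence within every named
  taxonomic group. The median is computed over *all* species (zeros
  included); computing it only over species where the cluster is present
  would be the laxer reading of an ambiguous rule, and the all-species
  version is both stricter and deterministic.
* **MRL split encoding** turns a set of input trees into a supertree
  matrix: every internal bipartition with support of at least 85 becomes
  one binary column per tree (no deduplication across trees, as in
  standard supertree matrices). Taxa on the side away from the reference
  taxon (the lexicographically smallest leaf) are coded 1. Because all
  input trees must share the full leaf set, no missing-data symbol is
  needed. Under the symmetric binary model the 0/1 polarity is
  likelihood-invariant, which the test suite asserts.

Clade-specific signals are queried with explicit presence fractions
(`clade_signal_clusters`), and profile families can be explored with a
Ward dendrogram over Jaccard distances between profile columns
(`profile_dendrogram`). We deliberately expose the rule-based query with
explicit thresholds rather than hard-coding any particular dendrogram
cut, since such cuts are analysis decisions, not package invariants.

## The binary Mk model

Characters are modelled as a reversible two-state Markov process with
stationary frequencies $\pi_0, \pi_1$ (estimated by maximum likelihood,
the "+FO" component) and a FreeRate mixture of $k$ categories with rates
$r_j$ and weights $w_j$ constrained by $\sum_j w_j = 1$ and
$\sum_j w_j r_j = 1$. Transition probabilities are

$$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)\, e^{-\beta r t}, \qquad
\beta = \frac{1}{2\pi_0\pi_1},$$

so one unit of branch length is one expected change per character at
relative rate 1. Log-likelihoods use Felsenstein pruning over compressed
site patterns (for $n$ species there are at most $2^n$ patterns, so even
matrices with $10^5$ columns compress drastically) with per-site
rescaling against underflow; the pruning core is implemented in C++.

Choices worth stating explicitly:

* **No ascertainment-bias correction by default.** Constant (all-present)
  columns are genuine observations of conserved clusters and are retained;
  they influence branch lengths only. A flag
  (`condition_on_variable = TRUE`) enables conditioning on variability for
  sensitivity analyses.
* **FreeRate default is `k = 1`** for the desk-scale experiments (the
  homogeneous model), with `k` freely configurable; the FreeRate fit
  embeds the homogeneous optimum as a floor, so increasing `k` can never
  decrease the fitted likelihood.
* **Branch lengths are bounded to $[10^{-8}, 10]$** and optimization stops
  at log-likelihood gains below $10^{-6}$: saturated binary characters
  otherwise push lengths to infinity. Because the per-branch likelihood
  profile can be bimodal on noisy binary data (an interior optimum
  competing with a saturated one), each 1-D optimization first brackets
  the best region on a fixed log-spaced grid, then refines by golden
  section.

## Tree search, supports and distances

Inference starts from neighbor joining on corrected mismatch distances
$d = -\tfrac12 \ln(1 - 2\hat p)$ (the two-state analogue of the
Jukes-Cantor correction; saturated pairs are capped), then hill-climbs
with nearest-neighbor interchanges. Candidate moves are screened by
re-optimizing only the exchanged internal edge and then evaluated in
decreasing order of promise with full branch-length optimization; a move
is accepted only if it improves the log-likelihood by more than the
tolerance, so the search terminates at an NNI-local optimum and is fully
deterministic. On quartets and 5-taxon problems the search provably
attains the exhaustive optimum in the test suite.

Supports are standard nonparametric bootstrap percentages (columns
resampled with replacement, full search rerun per replicate). The
ultrafast bootstrap and SH-aLRT approximations of large-scale ML programs
are intentionally not reproduced; plain bootstrap values on identical
matrices will differ numerically from such approximations.

`rf_distance` is the size of the symmetric difference of nontrivial
bipartition sets, cross-checked in the tests against an independent
implementation.

## The simulator

Each gene family evolves along a rooted, dated species tree (branch
lengths in units of 100 My) as a linear birth-death process with
rearrangement, embedded in the branches and simulated exactly with a
Gillespie algorithm, branches processed in preorder:

* **Rates** $\lambda$ (duplication), $\mu$ (loss), $\nu$ (rearrangement),
  per gene per 100 My. The validated default is a single turnover rate
  $\lambda = \mu = 0.38$ (a magnitude estimated from monocot gene-content
  data) and $\nu = 0.38$.
* **Duplication** adds a gene copying each syntenic edge of its parent
  independently with probability $p_d$; no parent-copy edge is created.
  **Loss** removes the gene and its edges. **Rearrangement** deletes each
  incident edge independently with probability $p_r$. By default $p_d$
  and $p_r$ are redrawn once per simulation replicate from Beta($b$, $b$)
  with $b \sim$ Beta(2, 2) — a hyperprior spanning conservative to
  disruptive regimes.
* **Speciation** copies every extant gene into both daughter branches;
  all existing edges (within the branch and to other lineages) are
  inherited by both copies, and one new cross edge joins the two copies
  of the *same* parent gene. We read "genes sharing a common ancestor in
  the parent branch" as exactly these same-gene copy pairs; linking
  copies of *different* (merely syntenically linked) parent genes would
  be a broader reading, and the narrow one suffices to produce conserved
  multi-species clusters.
* **Root prior.** The gene count at the root is Geometric on
  $\{1, 2, \dots\}$ with parameter $p$ (default 0.66, mean $1/p$):
  a family must exist to be observed. Root paralogs start with no edges
  among them — no ancestor exists to license an edge — with a complete
  graph available behind the `root_complete` flag for comparison.

Clusters of a finished family are connected components over the extant
leaf genes, discarding singletons (a gene without syntenic partners is
invisible to block detection). A dataset concatenates the clusters of
`n_families` independent families; extinct families contribute nothing
but still count toward `n_families`. With $\lambda = \mu$ the per-leaf
gene count is a martingale with mean $1/p$ — note this holds per lineage,
not for the summed leaf total, since counts double at speciations — and
this, the pure-birth mean $e^{\lambda t}$, and byte-level determinism
under a fixed seed are asserted in the acceptance suite.

### What the simulator does and does not emulate

It generates presence/absence matrices whose columns arise from gene
birth, death, edge erosion and cluster fragmentation on a tree — the
structure the method assumes. It does *not* emulate: genome-scale
rearrangement maps (families are independent; real rearrangements hit
many neighboring families at once), map-equation clustering (components
only), tandem-array structure, annotation error, or assembly artifacts.
Passing the recovery experiments therefore shows correctness and
statistical behaviour of the method under its own model, not performance
on real genomes.

## Design of the recovery experiments

The validation experiments infer trees from simulated matrices and
measure RF distance to the truth. Problem sizes were fixed once: an
8-taxon study tree with 50 replicate seeds at 200 vs 2000 families for
the size trend, plus a paired run at $\lambda = \mu = 1.5$ for the
rate-stress trend; the test suite uses `k = 1` inference, which is
sufficient for topology at these scales.

The 8-taxon study tree (`example_species_tree(8)`) is a balanced, evenly
sampled clade: crown age 1.0 (100 My), internal branches 0.15-0.25,
terminals 0.2-0.25. This design was chosen deliberately. Pilot designs
with sparse deep sampling — e.g. an isolated two-taxon outgroup whose
terminals exceed 80-100 My — are *not* recoverable at this turnover rate
regardless of the number of families: the presence/absence characters
saturate along long unbroken branches, and the misplaced attachment is
a genuine likelihood optimum, not a search failure. With denser taxon
sampling the same depth is unproblematic (the 15-taxon tree of
`example_species_tree(15)`, with a 130-My crown, is recovered exactly
with 1000 families). This mirrors practice: the approach is applied
either to densely sampled deep clades or to family-level data sets, and
taxon sampling that breaks up long branches matters, as it does for any
likelihood method prone to long-branch effects. We record this as a known
limitation of small-taxon deep designs rather than hiding it.

## Known limitations

* Connected components over-merge clusters on dense empirical networks;
  the external-clustering adapter exists precisely because map-equation
  partitions are preferable at that scale.
* The Mk model ignores the dependence between columns generated by a
  shared gene family or a shared rearrangement event; simulated data show
  the resulting inference is nevertheless accurate under even sampling,
  but long-branch configurations can mislead it (see above).
* NNI search can in principle stop at local optima on larger trees;
  SPR/TBR moves are out of scope.
* Bootstrap supports are plain nonparametric percentages; they are not
  comparable numerically to ultrafast-bootstrap values.
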
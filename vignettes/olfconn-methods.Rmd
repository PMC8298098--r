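---
title: "Methods: layers, polarity and stereotypy in connectome graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layers, polarity and stereotypy in connectome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfconn)
```

`olfconn` implements a family of analyses for neuron-level connectomes of
the insect olfactory system: assignment of information-flow *layers* by
probabilistic graph traversal, entropy-based synapse-segregation scores,
glomerular innervation and co-innervation statistics, kernel-density
reconstruction of glomerulus volumes, and across-dataset morphological
cell-type clustering. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the procedures were genuinely underdetermined.

## The graph traversal layer model

The input is a weighted directed graph whose nodes are neurons and whose
edge weights $w_{ij}$ are synapse counts, filtered by `build_graph()`:
duplicate records are summed, edges below `min_weight = 2` synapses are
dropped (single-synapse connections are reconstruction noise), and
within-class Kenyon-cell edges are dropped (considered false positives).

Starting from a seed pool (typically the receptor neurons), the model
proceeds in synchronous rounds. A neuron $j$ outside the pool is
traversed in a round with probability

$$P_j = \min\!\left(1,\; \frac{f_j}{c}\right), \qquad
  f_j = \frac{\sum_{i \in \text{pool}} w_{ij}}{\sum_k w_{kj}},$$

linear in the fraction $f_j$ of its total synaptic input that arrives
from the pool and saturating at the cap $c = 0.30$: a neuron receiving
30% or more of its input from the pool is traversed with certainty, one
receiving 10% with probability 1/3. Traversed neurons join the pool and
receive the round index as their step (seeds have step 1); the walk
continues until the set of neurons reachable from the seeds is exhausted,
which happens with probability one because every reachable candidate has
per-round probability greater than zero. A neuron's **layer** is the mean
step over many runs (`run_traversal()`, default 10,000), counting only
runs in which it was reached; the reach frequency is reported alongside
and never silently imputed. Seeds therefore sit at layer 1 exactly, and
every reachable non-seed has layer > 1.

Two readings of "each connection has an independent chance" are both
implemented and exposed as `mode`: the default `"aggregate"` draws one
Bernoulli per candidate per round using the pooled input fraction above;
`"per_edge"` lets every in-edge from the pool fire independently with
$\min(1, (w_{ij}/\sum_k w_{kj})/c)$ and the neuron joins if any fires.
The two agree exactly on saturated graphs and differ when several weak
edges pool; the aggregate mode is the package's reference reading because
it reproduces the published worked example (10% of input → 33.3%) on
pooled fractions. The cap is the model's only free parameter; absolute
layers depend on it, but rank order is expected to be stable — the test
suite verifies rank stability (Spearman ≥ 0.95) across caps 0.2–0.5 on
the synthetic connectome, and verifies the Monte-Carlo estimates against
exact expectations computed by exhaustive enumeration of the pool state
space on all fixture graphs with at most six nodes.

Derived quantities: `per_type_distances()` re-runs the model with one
seed group at a time (e.g. the receptor neurons of a single glomerulus),
giving each neuron a vector of distances to the seed types;
`lifetime_kurtosis()` summarises such a vector's sparseness as its excess
kurtosis under population moments, $\overline{((v-\bar v)/\sigma)^4}-3$;
`classify_early()` calls a neuron "early" when its layer rounds into a
window (default layers 3–4). Rounding of half-integers follows R's
`round()` (ties to even, so a layer of 4.5 rounds to 4 and is early under
the default window); the convention only matters for exact .5 layers and
is stated here because a half-up convention would flip that single case.

## Synapse segregation scores

`segregation_score()` quantifies how completely a neuron separates two
synapse categories between its compartments. The same formula serves two
uses: axon–dendrite polarity (categories input/output) and class
separation (categories input-from-projection-neurons vs
input-from-mushroom-body-output-neurons). For each compartment with
$n_k$ synapses of which a fraction $D_k$ belongs to category 1, the
compartment entropy is the symmetric binary entropy
$H(D_k) = -(D_k \log D_k + (1-D_k)\log(1-D_k))$; the neuron-level entropy
is the synapse-count-weighted mean $e = \sum_k n_k H(D_k) / \sum_k n_k$,
and the score is

$$S = 1 - e/c, \qquad c = H\!\left(\textstyle\sum_k n_k D_k / \sum_k n_k\right),$$

the entropy of the pooled composition. $S = 1$ iff every non-empty
compartment is pure while the pooled composition is mixed; $S = 0$
whenever each compartment mirrors the pooled composition. The base of the
logarithm cancels in $e/c$ (verified by computing in bases 2 and 10).
When the whole neuron is single-category, $c = 0$ and no separation is
measurable; the score is defined as 0 with a warning. Weighting uses the
total synapse count entering each compartment's composition, which for
the class-separation use means the input counts from the two classes;
this is configurable by what is passed as `counts`.

`glomerular_polarity_matrix()` restricts to neurons whose axo-dendritic
segregation index exceeds 0.1 (sufficiently polarised) and scores, per
glomerulus, the fraction of the neuron's axonic outputs placed there
minus the fraction of its dendritic inputs placed there, in $[-1, 1]$;
the rows are clustered with Ward linkage on Euclidean distances
(`cluster_ward()`, `hclust` method `ward.D2`).

## Glomerular innervation statistics

`cumulative_rank_curves()` summarises innervation breadth: per neuron the
per-glomerulus synapse counts are sorted descending, min-max normalised
to $[0,1]$ and cumulatively summed, so sparse neurons plateau within the
first ranks. Note a documented degeneracy of the min-max step: a neuron
with identical counts in every glomerulus collapses to the all-zero
curve.

`coinnervation_test()` asks which glomerulus pairs are co-innervated more
than chance. For every unordered pair and neuron, a co-occurrence
statistic is computed and summed over neurons. The procedure never
defines "co-occurring synapses" beyond the name, so the statistic is
pluggable: the default is $\min(c_{g_1}, c_{g_2})$, the number of
matchable synapses — bounded by the data and on the scale of synapse
counts — with product and binary-indicator alternatives behind a flag.
The null permutes, per neuron, that neuron's vector of per-pair
statistics across pairs (not per pair across neurons) and re-sums; the
raw p-value is the proportion of shuffles at or above the observed sum.
The plain proportion is the reference behaviour; an add-one correction
(`correction = "add_one"`) is available for strict Monte-Carlo validity.
Family-wise error is controlled by the Holm–Šídák stepdown
(`holm_sidak()`), adjusted $p_{(i)} = \max_{j\le i} 1-(1-p_{(j)})^{m-j+1}$,
which the tests verify against a brute-force stepdown oracle. A caveat
worth knowing: with heavily scaled-down shuffle counts the achievable
p-value granularity (1/B) can exceed the Šídák per-test threshold, at
which point only empirical p-values of exactly zero can be rejected and
the realised family-wise error is governed by discreteness
($\approx m/(B+1)$) rather than by the nominal level; at the reference
setting of 20,000 shuffles the granularity is fine enough for the
stepdown to operate as intended.

`input_output_segregation()` contrasts presynapse and postsynapse
placement: per neuron, glomeruli are ranked by total synapses and the
largest trailing set holding at most 5% of the synapses is pruned (ties
in rank broken by glomerulus label); the post-minus-pre differences of
the survivors are sorted descending and averaged across the neurons of a
type by rank position, positive ranks marking net input and negative net
output.

`intraglomerular_distance()` compares two arbours inside one glomerulus:
each skeleton is clipped to the region, excluded if under 80 µm of cable,
and otherwise every node is scored by the mean Euclidean distance to its
5 nearest nodes in the other arbour; node scores of both arbours are
pooled and the mean of the top 10% returned, making the measure symmetric
and sensitive to the worst-matched subregions. Because the neighbourhood
spans $k$ nodes, the score against an identical copy is bounded by a few
sampling steps rather than exactly zero; a pure translation by 2 µm of a
densely resampled arbour is recovered to within ±0.2 µm (the package's
translation oracle test).

## Glomerulus volumes from synapse clouds

`glomerulus_voxel_map()` reconstructs glomerulus volumes from labelled
synapse point clouds: a Gaussian kernel density estimate per glomerulus
(product kernel, Scott's-rule bandwidths $n^{-1/7}\hat\sigma_d$ per
dimension), evaluation on an isotropic 480 nm voxel grid, and assignment
of every voxel to its most likely glomerulus. Voxels whose best density
falls below a threshold become background; since no published threshold
value exists, the default is the 1st percentile of each glomerulus's own
point densities — i.e. a voxel must be at least as dense as the
glomerulus's own sparsest 1% of synapses — and both bandwidth and
threshold are configurable. Label masks are post-processed by one
6-connected binary erosion and hole filling (flood fill of the complement
from the grid border). Surfaces are exported by `write_voxel_obj()` as
voxel-boundary quad meshes in OBJ — a deliberately simple blocky
isosurface; smooth marching-cubes surfaces are out of scope.

## Across-dataset stereotypy

Skeletons are converted to *dotprops* (`make_dotprops()`): scaled to
micrometres, terminal twigs under 2 µm pruned (from the conventional
2–5 µm range; configurable), resampled at 1 µm steps, and each point
given a unit tangent from the principal direction of its 5-point
neighbourhood. The pairwise score (`similarity_score()`) is a simplified
parametric scorer behind a pluggable interface: the directed raw score
sums $\sqrt{|u\cdot v|}\,e^{-d^2/2\sigma^2}$ over query points against
the nearest target point ($\sigma$ = 3 µm), is self-normalised so a
perfect copy scores 1, and the pair score is the minimum of the two
directions, making the matrix exactly symmetric. Externally computed
similarity matrices are accepted by every downstream step, so the
clustering machinery does not depend on this particular scorer (the
trained-score-matrix scorer of the reference implementations is prior
work and deliberately not reproduced).

Clustering proceeds in two stages. `top_match_clusters()` adds, for every
entity and every other dataset, an undirected edge to its single best
match in that dataset and takes connected components; edges are
symmetrised by union, a choice made here because the directed reading
produces the same components. `refine_clusters()` then enforces a quality
floor: while any cluster contains a pair scoring below 0.4, the cluster
is split at the global minimum-weight cut of its similarity-weighted
graph (negative scores floored to zero as cut capacities) and the parts
are refined recursively; refinement only splits, never merges, so every
output cluster satisfies the floor. Users should expect mild
over-segmentation of types with many members — the top-match graph can
legitimately fall apart into disjoint reciprocal pairs — which is a
property of the published procedure itself, and on very small clusters
the minimum cut tends to strip weakly connected singletons rather than
bisect types.

Connectivity stereotypy uses `connectivity_cosine()`: connection
strengths signed by transmitter (GABA and glutamate negative), each
target column normalised by its maximum absolute strength, cosine
similarity between source profiles. `sister_comparison()` contrasts
same-type source pairs against cross-type pairs and against a shuffled
control in which every source's downstream type labels are independently
permuted before pooling, yielding random small out-of-type groupings.

## Rule-based classification

`classify_toon()` applies the third-order-neuron rule with inclusive
thresholds: at least 1% of total input (or else 10 connections) from a
single olfactory projection neuron, or 10% (or else 100 connections) from
all of them combined; the single-source clause is applied to any single
olfactory projection neuron as stated. `classify_lhn()` gates on the
TOON call plus at least 10 synapses in the lateral horn, so lateral-horn
neurons are a subset of third-order neurons by construction.
`transmitter_by_hemilineage()` propagates fast-acting transmitter
evidence within hemilineages, rejecting conflicting evidence at load
time.

## The synthetic connectome generator

All analyses are validated end-to-end against `synth_config()` /
`generate_connectome()` / `generate_innervation_matrix()` /
`generate_skeletons()`, which emulate the statistical structure the
analyses assume while planting known ground truth:

* **Layered graph** — five layers of 160/120/100/80/40 neurons
  (receptor-like seeds through descending neurons, about 500 total), each
  non-seed neuron drawing at least a `feedforward_fraction` (default 0.9)
  of its input weight from the previous layer, the remainder from random
  lateral partners. Edge weights are a discretised lognormal
  (meanlog 1, sdlog 0.8) — connectome edge weights are heavy-tailed, and
  heavy tails are what make the 30% input cap meaningful. Receptor
  neurons are assigned to 20 glomeruli, half of which (configurable) are
  bilateral.
* **Innervation matrix** — background innervation independent across
  glomeruli (each neuron innervates each glomerulus with probability 0.2,
  placing Poisson(15)+1 synapses), with planted pairs whose joint
  innervation probability is multiplied by an enrichment factor; factor 1
  reproduces the null exactly.
* **Skeletons** — each cell type has a random template tree (soma plus a
  dendritic and an axonal arbor, roughly 120 µm of cable) on a coarse
  grid of well-separated centres; members are the template plus 0.5 µm
  Gaussian node jitter, and dataset "B" members get an additional small
  global offset (0.5 µm by default) standing in for residual
  registration error — full bridging registrations between template
  spaces are out of scope, so both "datasets" live in one coordinate
  space. Planted polarised neurons carry inputs only on dendrites and
  outputs only on axons.
* **Reproducibility** — one root seed; every generator derives a child
  stream keyed by its operation name (`derive_seed()`), so adding an
  operation never perturbs the draws of another, and fixed seeds give
  bit-identical outputs.

What the generator does *not* emulate — realistic morphogenesis,
electron-microscopy reconstruction artefacts, polyadic synapse
multiplicity differences between reconstruction pipelines, or true
biological cross-animal variability — bounds what passing tests show:
they demonstrate that the procedures recover structure they are designed
to detect under the stated statistical assumptions, not that those
assumptions hold in any particular real dataset.

## Problem sizes and numerical choices

The validation suite runs at desk scale by choice: the layer-recovery
check uses the ~500-neuron default connectome with 400 traversal runs per
cap (the mean-step standard errors are far below the rank-resolution this
needs); oracle-equivalence checks use 10,000 runs on six-node graphs;
the co-innervation calibration uses 20 glomeruli × 60 neurons with 2,000
shuffles over a few hundred replicates; stereotypy recovery uses 50
fixtures of 20 types × 1–4 cells × 2 datasets. Degenerate inputs are
handled explicitly rather than silently: empty seed pools, all-zero
neuron columns, single-category neurons, sub-cable arbours and
over-threshold voxel grids each produce a documented error, warning or
exclusion. Ties are broken deterministically throughout (lowest index or
label order), so every function is reproducible given its inputs and
seed.
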
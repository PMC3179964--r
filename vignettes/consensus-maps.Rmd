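---
title: "Consensus genetic maps from directed acyclic graphs: model, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus genetic maps from directed acyclic graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagmap)
```

## The model

A linkage map for one linkage group is a sequence of *bins* — sets of
markers with no observed recombination among them — at nondecreasing cM
positions, anchored at 0. Different mapping populations segregate for
different marker subsets and estimate different local distances, so maps
of the same chromosome overlap partially and disagree numerically. A
consensus map integrates them.

`dagmap` represents the joint information as a directed graph:

* a **vertex** is a set of markers not separated by any map;
* a **directed edge** is one map interval: its *length* is the interval's
  cM distance and its *weight* the product of the marker counts its two
  endpoints contribute to the interval's flanking bins;
* a **zero-length edge** connects two markers some map placed in one bin.
  It expresses "these should be close", not an ordering, so it
  participates in the objective of the linearization but never in the
  order constraints.

### Merging

Maps are merged sequentially (`merge_linkage_maps()`). For each bin *v*
of the incoming map, in map order:

1. every existing vertex *w* sharing markers with *v* is split into
   *w∩v* and the remainder (unless *w ⊆ v*), with every directed edge in
   or out of *w* replicated for both parts — a split loses no previously
   recorded interval;
2. markers of *v* new to the graph form one new vertex;
3. after all bins are placed, each map interval adds directed edges from
   every vertex holding markers of its proximal bin to every vertex
   holding markers of its distal bin, weighted by the product of the
   contributed marker counts, so the total weight attributed to one map
   interval always equals the product of its bin sizes;
4. every unordered pair of co-binned markers is recorded as a zero-length
   edge, stored by marker name and resolved to vertices lazily (a later
   split can therefore never strand one on a stale vertex).

An induction argument shows that after merging a map, every vertex is
either contained in one of that map's bins or disjoint from the map —
which is what makes step 1 sufficient.

### Conflicts

Two maps that disagree on marker order create a directed cycle. Cycles
are found as strongly connected components with two depth-first searches
(the classical two-pass algorithm: DFS on the reversed graph, then
forward DFS in decreasing finish time). `assert_acyclic()` raises a
structured error of class `dagmap_conflict` carrying the offending
components; `export_dot(G, "conflicts")` renders each component as a
Graphviz cluster for manual curation. When there is no conflict, the
increasing finish-time order of the reverse-graph DFS is returned — it
is a valid topological order and fixes the vertex numbering used
everywhere downstream.

### Ordinal simplification

For presentation, the DAG is reduced to the smallest graph with the same
marker-level order relation (`ordinal_graph()`):

* **transitive reduction** (`reduce_edges()`): parallel edges are
  collapsed and an edge is dropped when its head is reachable from an
  earlier out-neighbour of its tail (out-neighbours scanned in
  topological order, reachability from a reverse-topological descendant
  sweep). For a DAG the transitive reduction is unique.
* **coalescing** (`coalesce_vertices()`): vertices with identical
  in-neighbour *and* out-neighbour sets cannot be path-connected, so they
  merge without changing any order relation. Iterated to a fixpoint, this
  re-unites bins that were split during merging only because two maps
  disagreed on distances.

The test suite certifies ordinal faithfulness on hundreds of random map
sets against a brute-force oracle: the transitive closure of the union of
per-map precedence pairs, computed by boolean matrix squaring.

## Linearization

Let `x` be the vector of vertex positions (columns in topological
order). Stacking one signed incidence row per directed edge (`A`) and
per zero-length edge (`B`) into `C = [A; B]`, with target lengths `d`
(zero for `B` rows) and weights `q`, the consensus map solves

```
minimize   sum_k q_k | c_k' x − d_k |^alpha
subject to A x >= 0,
```

with `alpha = 2` (weighted least squares, QP) or `alpha = 1` (weighted
least absolute deviation, LP). The constraints force every recorded
marker order; the objective trades distance agreement across maps.
Rows identical in (tail, head, length) are aggregated by summing their
weights before solving — this changes neither optimum nor objective and
substantially shrinks the systems the backends see.

Both problems are translation-invariant per weakly connected component
of the objective system, so one **anchor row** (a single +1, target 0)
is appended per component, placed on the component's first vertex in
topological order. For the QP this makes the quadratic form positive
definite, and `quadprog::solve.QP.compact()` (a dual active-set method)
returns the exact KKT point; `kkt_residuals()` verifies stationarity,
feasibility, and complementary slackness, and the acceptance tests
require them at 1e-6/1e-8.

### The LP solver

No linear-programming backend is part of the package's dependency set,
so the LP is solved with a purpose-built sparse first-order method:

* ADMM on the splitting `min g(y) s.t. y = Mx` with `M = [C̃; A]`, where
  `g` is the weighted L1 distance to `d` on objective rows and the
  indicator of nonnegativity on constraint rows. The x-update reuses one
  cached sparse Cholesky factor of `M'M`; the y-update is a
  soft-threshold / projection; the penalty parameter adapts to balance
  primal and dual residuals.
* **Active-set polishing**: periodically, the rows identified as active
  (absolute residual at the kink, or constraint at its bound) are solved
  as an equality least-squares system, which snaps the iterate onto the
  optimal face.
* **Monotone clamp**: every candidate is passed through a sweep in
  topological order that lifts each vertex to at least the largest of its
  constraint predecessors, so the returned positions satisfy `Ax >= 0`
  exactly, not merely to solver tolerance.

The default iteration budget is `max_iter = 6000` with an early exit
when two consecutive polishes agree to 1e-6 relative. On study-scale
instances (around 900 vertices and 5000 objective rows) the objective at
6000 iterations is within a few parts in 1e5 of the value after 80000
iterations and the resulting map length is identical at reported
precision; small instances converge to the exact optimum (verified
against exhaustive breakpoint search in the tests) in well under the
budget.

The weighted-L1 optimum is generically **non-unique**: the optimal face
of the LP can be large, and different optimal vertices can differ in
total map length even though every one minimizes the deviation
objective. `dagmap` reports the solution its solver converges to; see
"Known differences" below for the consequence.

### Rescaling and error

Both objectives shrink the consensus relative to its inputs (a weighted
compromise between disagreeing intervals is shorter than their longer
member, and zero-length rows pull markers together). `rescale()`
stretches the solved map so its total length equals the mean input map
length. `map_error()` scores a consensus against its inputs over
same-bin and adjacent-bin marker pairs (L1 or RMS, per pair or per
interval).

## The simulation study

`run_consensus_study()` evaluates accuracy end to end under a
doubled-haploid (DH) design:

* **True genome**: 1000 evenly spaced markers on 100 cM.
* **Polymorphism**: each marker segregates in each cross independently
  with probability 0.3 (an average parental identity of 70% enters only
  through this rate; parent haplotypes are not materialized).
* **Meiosis**: crossover counts are Poisson with mean 1 per Morgan (no
  interference), positions uniform, phase alternating from a random
  start; doubling makes individuals fully homozygous, so the genotype is
  the gamete. 200 individuals per cross.
* **Map estimation** (`estimate_map()`): adjacent markers with zero
  observed recombinants have *identical* genotype columns in a DH
  population and are collapsed into bins first — this is the defining
  property of a bin, and skipping this step understates binning and
  distorts both compression and error. Pairwise recombination fractions
  are estimated for all bin pairs within a sliding window of 4 adjacent
  bins, converted to cM with Haldane's function `d = −50 ln(1 − 2r)`,
  weighted by the DH likelihood-ratio LOD, and positions are fit by
  weighted least squares on the distance differences with the physical
  order fixed. Pairs with `r ≥ 0.5` are dropped; negative fitted
  intervals are clamped to zero, merging their flanking bins. The window
  width has little effect (3–5 behave similarly) and is exposed as a
  parameter.
* **Accuracy** (`map_accuracy()`): the consensus is rescaled to the mean
  linkage-map length and compared with the true positions of its markers
  after removing the best-fit translation; mean absolute and RMS errors
  are reported per replicate, then averaged with standard errors over 20
  replicates per condition. Child seeds are derived deterministically
  from one master seed, so any sub-grid reproduces identical replicates.

Translation alignment is a deliberate choice: an estimated map and the
truth share an origin convention only up to an offset, and without
removing the offset the RMS of an integrated random-walk error pattern
is inflated by a factor around 1.7. Published figures that do not state
their registration are therefore read as upper bounds on the aligned
error.

## Known differences and limitations

* **Error levels.** With translation alignment the measured errors run
  below the published values for this design (e.g. single-map RMS near
  3.5 cM against a published 4.7); the alignment convention explains the
  direction of the gap, so published error figures are read as upper
  bounds on the aligned error, and the error *contrasts* (QP versus LP
  on the same replicates) are the meaningful comparison.
* **LP degeneracy.** The weighted-L1 optimum is non-unique, so the LP
  map's exact positions (and to a small degree its total length) depend
  on which optimal vertex a solver converges to, even when the objective
  value is certified; the QP optimum is unique.
* The simulator covers DH populations only — no F2/RIL designs, no
  crossover interference, no genotyping-error model.
* Conflict resolution is manual by design: the package reports strongly
  connected components; it does not delete edges to break cycles.

## Problem sizes and runtime

On one CPU core: merging eight 1000-marker maps takes about a second;
the QP solves in under a second; the LP ADMM is the most expensive step
at a few seconds per instance with the default budget. The full
three-condition study (20 replicates each at g = 1, 2, 8) runs in a few
minutes.
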
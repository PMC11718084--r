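---
title: "Myopic MCES distances: model, bounds, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myopic MCES distances: model, bounds, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcesdist)
```

## The model

A molecular structure is represented as a node-labeled, edge-weighted
simple graph: heavy atoms carry their element symbol, bonds carry a weight
of 1 (single), 1.5 (aromatic) or 2 (double); hydrogens, formal charges,
isotopes and stereochemistry are deliberately ignored, so two structures
are "the same" exactly when their labeled graphs are isomorphic. Graphs
may be disconnected (multi-fragment structures stay one graph) and may
have no edges at all.

The weighted MCES distance between `M1` and `M2` is the minimum, over
common edge subgraphs, of

$$d(M_1,M_2) \;=\; \sum_{e \in E_c}\lvert b_1(e)-b_2(e)\rvert
  \;+\; \sum_{e \in E_1\setminus E_c} b_1(e)
  \;+\; \sum_{e \in E_2\setminus E_c} b_2(e),$$

an equivalent reformulation of "total bond weight of both graphs minus
twice the weight of the common part". The common subgraph is explicitly
allowed to be disconnected: requiring connectivity would make a single
displaced bond disqualify half a molecule from the common part. Atoms may
only map within their element; cross-element mapping is never allowed, and
the element alphabet is open-ended (any symbol is accepted).

Computing this distance is NP-hard. The package's position is that the
*small* distances are the informative ones: whether two structures are 2
or 8 edits apart matters, whether they are 42 or 48 apart does not. The
myopic scheme exploits this:

1. compute cheap, provably correct lower bounds; if a bound reaches the
   threshold `T`, report the bound (the pair is "at least `T` apart");
2. otherwise solve exactly with the threshold as a model constraint, and
   report `min{exact, T}`.

## The two lower bounds

**Weighted-degree bound.** Sort both node lists by weighted degree
(sum of incident bond weights), pair positionally, sum absolute
differences, add the degrees of leftover nodes, halve (every edge is seen
from both endpoints). This is the weight of a minimum matching between the
degree multisets, hence a pseudometric and a valid lower bound.

**Atom-type matching bound.** For each element, build a bipartite graph
between the atoms of that type on either side, padded to equal size. A
real-real edge costs the exact one-hop alignment of the two atoms'
incident-edge multisets: incident edges may pair only when the opposite
endpoints share an element (cost = bond-weight difference), unpaired
incident edges cost their weight. The bound is half the summed
minimum-weight perfect matchings. Two design points are not forced by the
construction and were fixed as follows:

* *Padding cost* equals the real atom's weighted degree, mirroring the
  leftover-node rule of the degree bound. Any not-larger choice would also
  be valid but weaker.
* *Neighborhood radius* is one hop, and incident-edge pairing is
  restricted by the opposite endpoint's element. This is the strongest
  reading that is still provably a lower bound (validated against the
  brute-force oracle over hundreds of random pairs in the test suite);
  enlarging the radius would cost more than it prunes.

The matching bound dominates the degree bound (a type-respecting matching
is also a degree matching), so the pipeline uses it by default; the degree
bound is available as an optional prefilter (`use_degree_prefilter`) —
mixing the two across pairs is safe for the metric property because both
are pseudometrics below the exact distance.

## Exact computation

`build_model()` materializes the optimization as an integer program:
binary node-map variables `y[i,k]` for type-compatible pairs; binary
edge-map variables for each compatible *orientation* of an edge pair
(costs `|b1 − b2|`); binary unmapped-edge variables (costs `b`).
Constraint families: node maps injective in both directions (2, 3); an
edge may map only consistently with its endpoints' node maps (4, 5); each
edge is mapped exactly once or marked unmapped (6, 7); optionally the
objective is bounded by `T` (8). Instantiating both orientations of an
edge pair, when both are endpoint-wise type-compatible, is behaviorally
equivalent at the objective level to any merged encoding; the choice is
gated by the oracle-equivalence tests.

`solve_exact()` solves this optimization with one of two backends:

* `"bb"` (default): a compiled depth-first branch-and-bound over injective
  type-consistent node mappings. The threshold enters as the search
  cutoff, which is precisely the role of constraint (8); accumulated cost
  plus a lookahead term (edge weight into already-abandoned nodes that no
  future decision can avoid) is an admissible bound. No external solver is
  required, and instances at the default `T = 10` resolve in milliseconds.
* `"scipy"`: the explicit integer program is handed to python's
  scipy/HiGHS MILP solver through a bundled helper script. This is the
  backend of choice for *unthresholded* exact distances on highly
  symmetric instances (see limitations), and serves as an independent
  cross-check of the branch-and-bound in the test suite.

Either way the reported objective is recomputed from the returned mapping
and verified, and `verify_solution()` re-checks every constraint family
directly against the graphs.

All distance arithmetic is carried out in integer quarter-units (values
scaled by 4): bond weights are multiples of 0.5 and both bounds divide by
two, so quarters are closed under every formula and all comparisons —
including the metric tests — are exact, with no floating-point
feasibility tolerances inside the model.

## Double thresholding and the metric property

Whenever the exact step runs, the reported value is `≤ T`; whenever only
bounds ran, it is `≥ T`. With both clamps in place the distance is a
metric: identity and symmetry are immediate, and the triangle inequality
follows because an exactly-computed side is capped at `T` while any
bound-derived side is at least `T`. Dropping the second clamp (reporting
raw exact values above `T`) breaks this: a pair can have a *weak* bound
(below `T`) yet a large true distance, while its two flanking pairs are
reported by bounds that underestimate. The test suite searches a seeded
family of ring systems — one large ring versus the same atoms partitioned
into several small rings, where every atom looks locally identical and the
matching bound is blind — and exhibits a concrete violating triple, then
confirms the clamped distance repairs it. If the seeded search budget is
exhausted without a violation the property test reports itself
inconclusive rather than failing, since it is existential.

`metric_closure()` offers the alternative repair for tables built without
clamping: an all-pairs shortest-path (Floyd–Warshall) pass that never
increases an entry and restores the triangle inequality exactly.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `T` | 10 | distance threshold (in bond-weight units, i.e. roughly "edge modifications"); larger values compute more pairs exactly at rapidly growing cost |
| `solver` | `"bb"` | exact backend; `"scipy"` requires python + scipy |
| `time_limit` | none | per-instance wall-clock cap in seconds for the exact step |
| `use_degree_prefilter` | `FALSE` | try the linear-time bound before the matching bound |
| `edge_cap` (oracle) | 7 | refuse brute-force enumeration beyond this size |

A hit time limit yields `min(best lower bound, T)` with provenance
`"bound"` and an `approximate` flag. Such values remain valid lower
bounds but are excluded from the metric guarantee, which is why they are
flagged rather than silently merged.

## The synthetic generator

`random_molecular_graph()` stands in for sampled biomolecular structures
in tests. It emulates the features the distance machinery is sensitive
to: a carbon-dominated element distribution (C 72%, O 12%, N 10%, S 3%,
Cl 2%, P 1% — typical heavy-atom frequencies in organic structure
collections), valence-capped degrees (≤ 4), mostly-tree topology with a
Poisson number of cycle-closing edges (rate 0.15 per atom), and aromatic
weights restricted to cycle edges, with double bonds in realistic
minority proportions. Node counts are whatever the caller requests; the
reference configuration in batch-shape tests uses 20–48 heavy atoms,
bracketing the ~34-atom average of curated biomolecular structure sets.
It does **not** emulate valence-correct chemistry, realistic ring-system
statistics, functional groups, or heteroatom positioning — so a green
test establishes correctness of the distance machinery on molecule-like
labeled graphs, not chemical validity of the generator. `perturb()`
applies random edits whose summed weight is, by construction, an upper
bound on the true distance to the original — an inequality the oracle
tests exploit. All generator randomness flows through one explicit seed
and never touches the caller's RNG state.

## Numerical and degenerate-input choices

* Triple bonds fall outside the classical weight set; they are accepted
  with weight 3 by default (`allow_triple = FALSE` rejects) — the
  machinery is weight-agnostic, and refusing common chemistry would
  cripple batch use.
* Zero-heavy-atom input (e.g. bare protons) yields an empty graph with a
  warning flag; distances against it degenerate gracefully to total bond
  weights.
* Matching and mapping tie-breaks are irrelevant by construction: only
  optimal values are consumed, and value-level results are
  backend-independent (mappings may differ between equally optimal
  solutions).
* Exact values equal to `T` are reported as `clamped`, keeping the
  strict `value < T ⇔ exact` dichotomy the metric argument uses.

## Known limitations

* Unthresholded exact solves on locally-symmetric instances (large ring
  systems, repeated substructures) can be very slow for the
  branch-and-bound, whose pruning feeds on type and degree asymmetry; the
  scipy/HiGHS backend handles these far better. At the default `T = 10`
  the threshold cutoff keeps the branch-and-bound fast across all tested
  regimes.
* The distance is absolute: it does not normalize by molecule size, and
  pairs of very different sizes are dominated by the size difference.
  Relative variants are intentionally out of scope.
* Bound-provenance values are lower bounds, not estimates: histograms of
  batch results show the characteristic censoring mass at `T`, and
  downstream consumers should treat `value ≥ T` as "at least this far".
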
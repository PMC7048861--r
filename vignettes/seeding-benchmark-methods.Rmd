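---
title: "Methods: benchmarking seeding strategies for SI spreading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking seeding strategies for SI spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seedbench` compares ten seed-node selection strategies by the time a
cascade susceptible–infected (SI) process needs to infect the whole
largest connected component (LCC) of an undirected social network.
This vignette documents the models, the parameters that matter, the
numerical choices behind them, and what the package's simulations can
and cannot say about real networks.

## The growth model

Networks are generated by growth with preferential attachment and
triad formation. The graph starts from `m` isolated nodes. Every new
node `v`:

1. draws a *candidate set* of `m` distinct existing nodes with
   probability proportional to degree (each initial node is also
   listed once in the attachment pool, so the first arrival connects
   to all of them and the graph stays connected);
2. attaches its first edge to the top candidate, which becomes the
   current *anchor*;
3. for each remaining edge, with probability `p_triad` performs a
   *triad-formation step* — connecting to a uniformly random
   not-yet-connected neighbour of the anchor, which closes a triangle —
   and otherwise attaches to the next candidate, which becomes the new
   anchor.

Candidates that are already neighbours (possible after triad steps)
are replaced by fresh degree-weighted draws, so the edge count is
exactly `(n − m)·m` for every realization; density is therefore a
deterministic function of `n` and `m`, and `choose_m_for_density()`
inverts it.

**Anchor discipline.** Candidates are consumed in a fixed cyclic
priority order: ascending `(id mod slots, id)`, with the slot budget
growing with `m` (8 slots for `m ≤ 4`, 32 to 19, 128 to 76, 512
above). This makes a stable minority of nodes the preferred triad
anchors across the whole growth process. The choice is deliberate:
with uniformly ordered candidates, triadic closure is spread over
ever-changing anchors and the attainable mean clustering collapses as
`m` grows (⟨C⟩ ≲ 0.22 at `n = 1000`, `m = 40` even at `p_triad = 1`),
and the graphs develop many small modules. Concentrating anchorship
reproduces the behaviour of reference implementations of this
generator family: high clustering remains attainable at large `m`
(⟨C⟩ ≈ 0.47 in the same setting) and the mesoscale organizes into a
few large communities around the anchor elite. The package's
acceptance tests pin the resulting ensemble statistics (community
count and modularity of calibrated batches).

**Calibrating clustering.** `calibrate_triad_probability()` estimates
the mean clustering coefficient (average local clustering, isolated
and degree-1 nodes counting 0) at `p_triad = 0` and `1`, then bisects.
All probe points reuse the same realization seeds (common random
numbers), so the calibrated probability is a deterministic, monotone
function of the target and the bracket endpoints are honest bounds.
The default probe budget is 5 realizations and the default tolerance
0.02 on ⟨C⟩; ensemble modularity moves roughly 0.3 points per point of
clustering in the sparse high-clustering regime, so analyses that
compare modularity across batches should calibrate tighter (the
acceptance suite uses tolerance 0.01 with 10 probes for exactly this
reason).

**Category targets.** Categories combine density and clustering
classes Low `[0, 0.1]`, Medium `(0.1, 0.2]`, High `(0.2, 1]`; three of
the nine combinations (MD-LC, HD-LC, HD-MC) cannot be realized as
connected growth networks and are rejected by
`generate_category_batch()` (though `categorize()` still labels such
measurements, flagged as out-of-model). Each (category, size) pair
carries a default (density, clustering) target pair — see
`category_targets()` — chosen as achievable interior points of the
class ranges for this generator. Range midpoints were rejected as
defaults because they are frequently infeasible: the Low-clustering
midpoint 0.05 lies below the `p_triad = 0` baseline for most `m`, and
the High-clustering midpoint 0.6 is unreachable at large `m`. Users
can override both targets per call.

## Community detection

`detect_communities()` runs multi-level (Louvain) modularity
optimization at resolution 1, once per network, on a seeded shuffle of
the vertex order; the shuffle makes runs reproducible and the recorded
seed travels with the partition. Modularity is recomputed by the
package's own `modularity_q()` — the Newman–Girvan sum
`Q = Σ_c [e_c/Ne − (d_c/2Ne)²]` evaluated directly on the edge list —
so the reported number is independent of the detector backend (the
test suite checks it against a brute-force double loop and against the
backend on small graphs). Edgeless graphs fall back to the singleton
partition with `Q = 0`.

## Seeding strategies

All strategies operate on the LCC and return an *ordered* seed set of
size `s`. For generated networks the default `s` is the number of
detected communities; for loaded empirical networks a proportion rule
(`s = round(p · N_LCC)`, half-up, minimum 1, for p in
{0.01, 0.04, 0.07, 0.10}) is available through `benchmark_config()`.

* **Centrality strategies** (degree, betweenness, closeness,
  PageRank): top-`s` nodes; score ties are resolved by a seeded
  uniform draw within the tied block, implemented as a random
  secondary sort key. PageRank uses the standard damping 0.85; the
  backend solves it to machine precision.
* **k-core**: `s` nodes drawn uniformly from the maximal k-core,
  falling back shell by shell when the core is smaller than `s`. Note
  that in growth networks with few triads the maximal core is
  typically the entire graph (every node has degree ≥ m), so this
  strategy then behaves like random seeding — visible as near-zero
  overlap with the other centralized strategies in sparse
  low-clustering batches.
* **Vote-Rank**: abilities start at 1; a node's score is the sum of
  its neighbours' abilities; the argmax is selected (seeded tie
  break), its ability zeroed, and each neighbour's ability reduced by
  `1/⟨k⟩`, floored at 0. `⟨k⟩` is fixed at the initial mean degree and
  not recomputed after selections, following the method as cited.
  Because abilities start equal, the first pick is always a
  maximum-degree node.
* **Ambassadors / community hubs**: communities sorted by decreasing
  size (ties by ascending id) are cycled, picking per community the
  unselected member with the highest external (resp. internal) degree;
  exhausted communities are skipped and cycling continues until `s`
  nodes are chosen, so every community is represented before any is
  revisited.
* **Random hubs**: repeatedly draw a uniform node and take its
  highest-degree *not-yet-selected* neighbour. The "not yet selected"
  qualifier matters: restricting the pick to unselected neighbours (as
  opposed to discarding duplicate picks) guarantees that `s = N`
  returns every node, which the package treats as an invariant of all
  strategies. Draws are capped at `50·s` before erroring.

## The SI cascade

Dynamics are synchronous with end-of-step commit: all transmissions in
a step are evaluated against the infected set at the start of the
step, and newly infected nodes become infectious the next step. Each
infected node transmits to each susceptible neighbour independently
with the probability of contagion `g ∈ (0, 1]`, so a susceptible node
with `k` infected neighbours is infected with probability
`1 − (1 − g)^k`. Infected nodes never recover, and the process runs
until the LCC is fully infected or `max_steps` (default 10⁶) is
reached; capped runs carry an `NA` spreading time, are reported with a
warning, and are excluded from rankings rather than silently dropped.

This per-neighbour transmission rule was chosen over the main
considered alternative — each susceptible node sampling a single
random neighbour per step and testing it against `g` — because the
sampled-neighbour rule makes spreading times depend on the *fraction*
rather than the presence of infected neighbours, and in particular
loses two properties this package relies on for verification: at
`g = 1` the front is no longer a breadth-first wave (a susceptible
node can sample an uninfected neighbour), and no closed-form oracle
remains for path-like fixtures. Under the implemented rule the test
suite checks exactly: `g = 1` spreading time equals the maximum
shortest-path distance to the seed set (exhaustive small-graph
oracle), and on a dyad the infection time is geometric with mean `1/g`
(moment and χ² goodness-of-fit checks at 10⁴ runs). Both rules agree
on graphs with at most one infected neighbour per susceptible node.

## Ranking and degeneracy

For each comparison cell (network × contagion probability × seed-size
rule × run), `outperformance_counts()` gives each strategy the number
of competitors with strictly larger spreading time; ties award nothing
to either side (the symmetric, conservative choice). With 10
strategies the per-cell counts sum to 45 minus the number of tied
pairs. `aggregate_ranking()` sums raw counts over all cells of a group
*before* ranking — pooling over contagion probabilities and seed sizes
first, then converting totals into ranks `k−1 … 0` (tied totals share
the better rank). Generated batches group by (category, size); loaded
networks by (network, `g`, `s`).

Seed-set similarity uses the degeneracy coefficient
`|A ∩ B| / |A ∪ B|`; `degeneracy_matrix()` averages it over networks
into a symmetric matrix with unit diagonal. Reproducibility is
end-to-end: every network, selection and run seed derives
deterministically from the master seed, and `write_results()` output
is byte-identical across repeated runs of the same configuration.

## Problem sizes used in the automated checks

The test suite validates ensemble statistics on batches of 30 networks
at 200 and 1000 nodes (community count and modularity of calibrated
sparse batches), seed-set overlap structure on 30-network batches at
all three sizes, and the ranking trend (strategy-based seeding beating
random on sparse low-clustering networks) on a reduced 5 networks × 5
runs design; the overlap statistics reported by
`scripts/acceptance.R` use the full 30-network batches at every size.
These sizes keep the default check run in the minutes range while
leaving the ensemble standard errors small against the tested bands.

## Limitations

* The generator emulates skewed degree distributions, tunable
  clustering and small-world distances, but not homophily, weighted or
  temporal ties, overlapping communities, or degree assortativity
  patterns of specific empirical systems; passing ensemble checks
  establishes fidelity to this model family, not to any particular
  real network.
* Spreading is simple contagion only — no recovery (SIR/SIS),
  thresholds, or continuous time.
* Louvain is a stochastic heuristic; partitions (and hence `s` and the
  community-based strategies) are reproducible under the recorded
  seed but not canonical.
* Networks beyond ~10⁴ nodes are out of scope; the pure-R generator
  and betweenness computations become the bottleneck there.
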
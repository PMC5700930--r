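---
title: "Trophic coherence and motif families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic coherence and motif families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicmotifs)
```

This vignette documents the models implemented in `trophicmotifs`, the
assumptions behind them, and the numerical and design choices made where
several defensible options existed.

## Food webs as directed graphs

A food web is stored as a simple directed graph with links pointing from
prey to predator. Two normalisations are applied on ingest and are worth
stating explicitly, because they change `q` on raw datasets that contain
them:

* **Self-loops (cannibalism) are removed**, with a warning. The
  trophic-level system `s_j = 1 + (1/k_in_j) Σ_i a_ij s_i` becomes
  ill-conditioned when a node's own level enters its prey average; removing
  the loop keeps the solve well-posed. The warning carries the count so the
  preprocessing is auditable.
* **Duplicate links collapse to one.** The formalism is a binary adjacency
  matrix; multiplicity has no meaning in it.

Node labels are held in C-locale lexicographic order, so matrix indexing,
seeds and outputs are reproducible across machines and locales. An optional
`#nodes:` header in the edge-list format preserves isolated nodes across
write/read round trips; without such a header an isolated node simply cannot
be expressed in an edge list.

Trophic levels are defined only when at least one basal (zero in-degree)
node exists and every node is reachable from the basal set;
`validate_trophic()` reports both conditions rather than raising, and the
computational entry points raise with the violated condition named.

## Trophic levels and the incoherence parameter

The level system is solved **exactly** by a direct sparse LU factorisation
of the reduced `(N − B) × (N − B)` system (package `Matrix`), not by
fixed-point iteration: small webs are the common case, exactness is cheap,
and the downstream quantity `q = sqrt(<x²> − 1)` is sensitive near `q = 0`.
Averages over link distances use the population form (divide by `L`), which
is what the defining formula states. Two numerical guards:

* The identity `<x> = 1` (provable by summing the level equation over
  nodes) is exposed in `mean_distance` and asserted to `1e-9` in the test
  suite over random and model-generated webs — it is a strong end-to-end
  check on the solver.
* The radicand `<x²> − 1` is clipped to zero when it lies within `1e-12` of
  zero. On perfectly layered webs the exact value is 0 and the solver noise
  is ~`1e-15`; the clip makes `q = 0` exact there, and no ecologically
  meaningful web has a true `q` below `1e-6`.

## Triad census and significance profiles

The census counts **induced** connected 3-node subgraphs, each unordered
triple once — the convention of the classic motif-detection tools. Two
independent code paths exist: the production path maps
`igraph::triad_census()`'s 16-class Davis–Leinhardt census onto the 13
connected classes (the mapping is derived at run time by running the census
on each class prototype), and a reference path classifies every node triple
via a canonical-form lookup table built by exhaustive enumeration of all 64
labeled 3-node digraphs. The two are asserted equal on hundreds of random
webs; permutation invariance of the classifier is checked exhaustively.

The five single-link classes follow the standard ecological reading (S1
chain, S2 omnivory/feed-forward, S3 cycle, S4 apparent competition, S5
direct competition). For the eight double-link classes no universally
agreed order exists in print; the package fixes a deterministic one
(increasing number of mutual dyads, then link count — see
`?triad_classes`). Every similarity, distance and family result is
invariant to a consistent permutation of the D block, so this choice
affects presentation only.

**Null model.** z-scores are computed against an ensemble of
degree-preserving randomizations, each an *independent* swap chain started
from the original web (`swaps_per_link × L` attempted double-edge swaps;
swaps creating self-loops or duplicate links are rejected and count as
attempted). Independent chains avoid the autocorrelation a single continued
chain would introduce between ensemble members. Defaults —
`ensemble_size = 1000`, `swaps_per_link = 10` — are chosen for convergence
on webs of tens to hundreds of species; the self-consistency test (z-scores
from 100- vs 600-network ensembles) guards the choice. Two modes exist
because published motif work differs silently on this point:

* `plain` (default): preserves in- and out-degree sequences only.
* `mutual`: additionally preserves the number of mutually predating pairs,
  swapping single links among single links and mutual dyads among mutual
  dyads. This stricter null changes z-scores on webs with double links, so
  the mode is recorded in the result object.

A triad whose count is constant across the null ensemble (`σ_rand = 0`)
gets `z = 0`: it carries no signal relative to this null, and the
alternative (±∞) would destroy profile comparability. The all-degenerate
case (e.g. a web that is the unique graph for its degree sequences) leaves
the normalized profile undefined, and the object says so.

## Comparing profiles and motif families

Profiles are compared by the sample Pearson coefficient of the unit-norm
z-vectors (n − 1 normalisation, exactly the printed formula — numerically
identical to `stats::cor`) and converted to the chord distance
`d = sqrt(2(1 − r))`, a Euclidean metric on unit-norm profiles. Clustering
is UPGMA via `stats::hclust(method = "average")`; tie-breaking therefore
follows `hclust`'s deterministic internal rule given input order, which the
hand-traced merge tests pin down. A family cut at threshold `d_c` keeps
clusters whose internal merges all lie strictly below `d_c`. The batch
classifier anchors family 1 to the cluster containing the lowest-`q` web,
so labels are stable across reruns regardless of input order.

For model-vs-data comparison the **raw z vectors** of the model ensemble
are averaged component-wise before correlating with the empirical z vector,
following the defining procedure; `use = "z_hat"` switches to averaging the
normalized profiles, since summaries of this kind are sometimes reported as
an "average TSP". The two differ when ensemble members vary strongly in
profile magnitude.

## The coherence-tunable generator

The generator's three stages and the reasoning behind the discretionary
choices:

1. **Skeleton.** `B` basal nodes at temporary level 1; each of the `N − B`
   subsequent nodes picks exactly one prey *uniformly among all existing
   nodes* — basal and non-basal alike, the literal reading of the assembly
   rule — giving `ŝ_j = ŝ_i + 1` and guaranteeing reachability from the
   basal set in every draw.
2. **Extra links.** Candidates are all ordered pairs `(i, j)` with `j`
   non-basal (keeping basal in-degree 0), `i ≠ j`, excluding skeleton links
   (so no duplicates can arise). Each is an independent Bernoulli event
   with probability `min(1, c·w_ij)`, `w_ij = exp(−(x̂_ij − 1)²/(2T²))`.
   The cap at 1 is needed because for small `T` and large `L` the
   unconstrained scaling can exceed 1; `c` is solved exactly from the
   piecewise-linear equation `Σ min(1, c·w_ij) = L − (N − B)`, so the
   *expected* final link count is exactly `L`. A target `L` beyond what the
   positive-weight candidates can supply is an error that reports the
   achievable maximum.
3. **Finalisation.** Trophic levels are recomputed from the assembled
   topology; they need not equal the temporary ones once extra links exist.

`T = 0` is implemented as the exact limit — only pairs at temporary
distance 1 are candidates, uniformly — avoiding `0/0` in the weight; at
`T = 0` the temporary and final levels coincide and `q = 0` exactly. The
large-`T` limit must coincide with a uniform extra-link model, and a test
checks the generated `q` distribution against an independently coded
uniform reference at `T = 50`.

**Temperature calibration** (`gppm_fit`) is stochastic root finding by
bracketing bisection on `T`: the ensemble-mean `q(T)` is monotone
non-decreasing, so bisection against noisy Monte-Carlo evaluations
converges provided the noise is small against the local slope. Evaluations
use 200 draws while the bracket is wide and escalate to 1000 once it
narrows below 0.04 in `T`; with per-draw `q` standard deviations of
0.05–0.15 this puts the standard error of an evaluation near 0.003–0.005,
well inside the default tolerance of 0.01 on mean `q`. Every evaluation is
logged in the returned object. Targets above the large-`T` plateau are
reported as infeasible together with the plateau estimate. Calibration runs
against two published `(B, N, L, q)` rows in the acceptance tests reproduce
the published temperatures within the asserted 0.05.

**The omnivory transition** (`gppm_s2_transition`) scans a temperature grid
at fixed basal ratio `B/N` and average non-basal degree, scores each
generated web's normalized S2 (feed-forward) z-score against the
degree-preserving null, and interpolates the first sign change of the
ensemble mean to locate the critical temperature `T_c` and incoherence
`q_c`. Grids without a sign change are flagged as an open interval, not an
error. The default test-scale settings (100 draws per grid point, null
ensembles of 30–50 per web) resolve the sign structure clearly; the
published-scale analysis simply raises these counts.

## What the synthetic fixtures do and do not show

`make_layered` (exact `q = 0` by construction), the toy motifs (hand-solved
levels), `make_random_dag` (exact `N`, `B`, `L`, acyclic) and model draws
give every analysis path inputs with known analytic properties, so the
suite runs with no external data. They emulate the *structural* features the
methods rely on — basal sets, layering, cross-level links, mutual dyads in
random digraphs — but not the biological texture of real webs: empirical
degree distributions, trophic-species aggregation conventions, sampling
effort, or habitat-specific wiring. Passing tests therefore demonstrate
correctness of the computations and the internal consistency of the model,
not that any particular empirical web will be well fit; indeed several
published webs are known to be poorly matched by coherence alone.

## Problem sizes and determinism

The test suite and reproduction script run at desk scale by choice: webs of
tens to a hundred species, null ensembles of 20–100, model ensembles of
100–400 draws, and two-point transition scans. These sizes keep the full
suite in a few minutes while leaving every stochastic assertion at least two
standard errors of headroom. All stochastic entry points accept a seed and
record it (batch runs derive per-web seeds from the master seed and the
input's content hash, so corpus order does not matter), and cached batch
results are keyed by content hash plus all null-model settings.

## Known limitations

* Trophic levels follow the prey-averaging definition only; shortest-chain
  or flow-based level definitions are out of scope.
* The census stops at 3-node motifs.
* UPGMA is the only linkage; no bootstrap support on dendrograms.
* The generator fits only `(B, N, L, q)`; it does not model interaction
  strengths, and webs whose motif structure is not determined by coherence
  will not be reproduced faithfully.
* Edge lists and dense CSV adjacency matrices are the only input formats;
  weighted or signed interactions are not supported.
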
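---
title: "The loop-tunnel transport model: assumptions, parameters, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The loop-tunnel transport model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model in one page

`termitesim` simulates food transport by a colony of identical termites on
a lattice tunnel: a straight main tunnel of `main_length` unit cells
(nest at cell 0, food site at the far end) carrying a two-segment loop
tunnel of `loop_length` cells.  The loop joins the main tunnel at nodes
*a* and *c*; a zero-time-cost separation edge joins the main tunnel's
middle node *b* to the loop's middle node *d* and splits the loop into two
equal segments.  Termites walk one unit-cost edge per timestep toward
their current goal, switch tunnels at the four nodes with probabilities
P₁–P₄, relay food by trophallaxis (probability 0.5 per head-on
carrier/empty meeting; both reverse on a transfer; no food is lost), pick
up at the food site (unlimited supply), deposit exactly one particle per
arrival at the nest, and jam — freeze for `jam_duration` steps — whenever
four termites occupy one cell with heading vectors summing to zero.

The model deliberately excludes pheromone signalling, tunnel curvature and
wall irregularity, variable walking speeds, and any individual
heterogeneity: the only spatial structure is the loop and its separation
tunnel, and the only interactions are trophallaxis and jamming.

Transport efficiency is the scaled running delivery rate per termite,
E(τ) = s·Σₜ₌₁^τ food(t)/(τ·N₀) with s = 10 000, summarized per run by the
mean of E(τ) over the final tenth of the horizon (4500 ≤ τ ≤ 5000 at the
default T = 5000, both endpoints included).  Because the numerator is a
cumulative count, E(τ)·τ·N₀/s is always a non-decreasing integer
sequence — a useful audit.

## Geometry conventions

The model fixes the loop's size (200 cells, split evenly) but not its
exact placement, so the package adopts these conventions:

* Nodes (*a*, *b*, *c*) sit at fractions (0.1, 0.2, 0.3), (0.4, 0.5, 0.6)
  or (0.7, 0.8, 0.9) of the main tunnel for δ = 1, 2, 3 — cells (50, 100,
  150), (200, 250, 300), (350, 400, 450) at the default length.  δ = 2 is
  symmetric about the tunnel centre; δ = 1 and δ = 3 are mirror images,
  matching the schematic geometry of the three scenarios.
* Loop cells are indexed from the *a* side to the *c* side; *d* is the
  last cell of the first segment, so each segment holds exactly
  `loop_length/2` cells.  (With an even cell count the midpoint node must
  sit on one side; the one-cell asymmetry of the two arc lengths —
  100 vs 101 steps at the default — is far below every effect studied.)
* Cell indices are 0-based; an edge is an unordered cell pair with an
  integer cost, 1 everywhere except 0 on *b*–*d*.

`build_network()` validates all of this; `shortest_path_length()` (Dijkstra
with the zero-cost edge honoured) confirms the nest–food distance of 499
unit moves that makes a first delivery before timestep 500 impossible.

## Behavioural rules and tie-breaks

Several micro-choices are under-determined by the verbal model; the
package resolves them as follows, once, and the tests pin the behaviour:

* **Phase order.** Move free termites → resolve encounters → detect jams →
  endpoint pickup/deposit → tick jam timers of termites that began the
  step jammed.  A termite jammed at step t therefore stands still for
  exactly `jam_duration` full steps and moves again at t + jam_duration + 1.
* **Zero-cost edge.**  A termite standing on *b* (or *d*) first crosses to
  *d* (or *b*) with probability P₂ (P₄), at most once per step, then makes
  its single unit-cost move from where it now stands.  This keeps "the
  separation tunnel costs no time" while preventing within-step
  oscillation.
* **No reversal at nodes.**  Branch choice never moves a termite away from
  its goal: P₁ applies to food-bound termites at *a*, P₃ to nest-bound
  termites at *c*, P₂/P₄ to both directions (the separation hop is
  goal-neutral).  Reversals happen only through transfers and endpoints.
* **Encounters.**  An encounter is co-location on one cell with opposite
  headings after the move phase, one carrier and one empty termite.  When
  a cell holds several candidates, pairs form in random order and each
  termite joins at most one encounter per step.  Carrier/carrier and
  empty/empty meetings never interact.  Jammed termites neither move nor
  trade.
* **Jams.**  Any cell with ≥ 4 free termites whose headings cancel jams
  *all* free termites on it.  Jammed termites do not block passage —
  termites can pass each other in a tunnel — they only lose time.
* **Initialization.**  N₀ termites are placed uniformly at random on
  main-tunnel cells with uniformly random headings and no food.  The loop
  is a feature met en route, not a spawning area.

## Parameters

| parameter | default | status |
|---|---|---|
| `main_length`, `loop_length` | 500, 200 cells | model constant |
| `steps` (T) | 5000 | model constant |
| `s` | 10 000 | fixed scaling of E |
| `transfer_prob` | 0.5 | fixed by the behavioural rule |
| `jam_size` | 4 | fixed by the jam rule |
| `p1..p4` | 0.1, 0.1, 0.4, 0.4 | swept in all experiments |
| `n0` (N₀) | 100 | free: colony size is not fixed by the model description |
| `jam_duration` | 5 steps | free: jam dissipation time is not fixed either |

The last two are genuine model inputs rather than derived quantities, and
both matter a great deal (see *Limitations*).  N₀ = 100 puts roughly one
termite per five main-tunnel cells — a sparse colony in which jams occur
but rarely; `jam_duration = 5` makes a jam cost each participant five
steps, a mild penalty of the same order as a short detour.  Both are
plain `sim_config()` arguments and every experiment helper accepts a
custom configuration.

## The experiment designs

`factorial_design()` enumerates the full factorial experiment — 10 probability
levels {0.1, …, 1.0} per parameter × 3 loop positions × 10 replicates =
300 000 runs — as an enumerated table with one deterministic seed per row
(an affine walk modulo a prime, so any subset or reordering of rows reruns
identically).  `run_sweep()` executes any such table, averages replicates,
and can journal finished rows to disk so an interrupted sweep resumes.
`lhs_design()` provides Latin-hypercube points for the sensitivity
analysis: one point per equal-probability stratum per dimension.

Executing all 300 000 runs is a cluster-scale job.  The package's own
test and reproduction material therefore uses scaled designs (fewer
levels and replicates, T = 2000, Latin-hypercube n = 100) — chosen as the
smallest sizes at which the qualitative quantities of interest (orderings,
PRCC signs) have stable estimates across seeds.

## The analysis stack

* **k-means** (`kmeans_lloyd()`): plain Lloyd iterations with random
  restarts (default 10) keeping the lowest within-cluster sum of squares;
  the objective is non-increasing across iterations, and on ≤ 8 points the
  tests compare the result with exhaustive search over all assignments.
  Efficiency grouping (`group_sorted_efficiencies()`) runs 1-D k-means on
  E with k = 3 and relabels groups by descending centroid, so group 1 is
  always the high-E group.  If the data hold fewer distinct values than k,
  the effective k shrinks rather than fabricating empty clusters.
* **Histograms and H/M/L codes**: per-parameter frequencies over ten
  equal bins of [0, 1], normalized to sum to one; path codes use the
  half-open bins [0, 0.33) = L, [0.33, 0.66) = M, [0.66, 1] = H, which
  cover the interval without overlap.
* **t-SNE** (`tsne()`): per-point Gaussian bandwidths σᵢ found by
  bisection (tolerance 1e-5 on the entropy) to match the target
  perplexity — default 30, or n/4 for small inputs; Student-t similarities
  in the plane; gradient descent with momentum, adaptive gains and brief
  early exaggeration on the KL divergence C.  One deliberate deviation
  from the bare conditional-probability formulation: the symmetrized pᵢⱼ
  are normalized to sum to one over all pairs (the standard joint-form
  t-SNE) rather than left unnormalized, which keeps the optimizer's
  gradient scale stable; the embedding is only ever read qualitatively.
  The analytic gradient is checked against central finite differences in
  the tests, and the degenerate all-identical input falls back to uniform
  affinities instead of dividing by zero.
* **PRCC** (`prcc()`): rank-transform all columns (average ranks on ties),
  regress each input's ranks and the output's ranks on the remaining
  rank-inputs, and report the Pearson correlation of the residuals.
  Agreement to 1e-10 with an independent `lm()`-based oracle is part of
  the tests, as is invariance under strictly monotone transforms of an
  input.  `prcc_sweep()` stratifies by loop position, which is how the
  sensitivity results are reported per δ.

Where the analysis input is ambiguous, the package makes the
simple choice and exposes it: clustering operates on the 1-D E values;
the t-SNE feature vector is the (P₁, P₂, P₃, P₄) combination of each group
member; PRCC accepts either the factorial grid or Latin-hypercube rows.

## What the synthetic fixtures emulate

`make_fixture()` generates the test scaffolding in code: a miniature
20 + 8-cell network that satisfies every geometric invariant, a
`null-sweep` table whose E is independent noise (PRCC should find
nothing), and a `signal-sweep` table with a planted linear effect
E = 1 − 0.5 P₃ − 0.5 P₄ + ε (PRCC must recover strong negative
coefficients for exactly those inputs).  These validate the analysis
machinery against known ground truth; they share no code path with the
simulator, so passing them says nothing about the behavioural rules —
those are covered by the hand-traced walker, conservation, and jam-timing
tests.

## Limitations

* **Density regime.**  The congestion-relief story — the separation tunnel
  redistributes termites and thereby raises efficiency — requires jams to
  be a first-order cost.  At the default sparse colony (N₀ = 100 on 700
  cells, short jams) jam events are rare, and the geometric cost of loop
  detours dominates: higher P₃ lowers E, and the d→b hop (P₄) acts as a
  beneficial shortcut out of the loop.  Orderings measured in a
  congested regime (e.g. which (P₃,P₄) setting maximizes E, or P₄'s
  negative sensitivity sign) can therefore invert at these defaults;
  absolute E values depend directly on the unspecified N₀ and
  jam-dissipation time and are not comparable across parameterizations.
  Users studying congestion effects should raise `n0` (and expect runtime
  to scale with it).
* **Identical agents, fixed geometry.**  No walking-speed or
  carrying-capacity variation, no tunnel growth, no pheromones, no offset
  separation tunnels — all excluded from the model's scope.
* **One particle per termite**, unlimited food supply, and single-cell
  spatial resolution for encounters and jams are modelling quanta, not
  measured quantities.
* **t-SNE and k-means are exploratory**: restarts and seeds are exposed
  precisely because their output is initialization-dependent; only
  seed-fixed runs are reproducible.

## Reproducibility

Every stochastic entry point takes a seed (`sim_config(seed=)`,
`lhs_design(seed=)`, `kmeans_lloyd(seed=)`, `tsne(seed=)`), sweep rows
carry their own derived seeds, and `run_sim()` is bitwise-reproducible
from its configuration.  The CLI writes a manifest (seed, configuration
echo, md5 per artifact) next to every output.
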
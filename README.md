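# termitesim

Subterranean termites move food from a foraging site back to the nest
through narrow underground tunnels.  Real tunnel networks frequently
contain *two-segment loop tunnels*: a loop that branches off the main
tunnel at two nodes and is cut into two segments by a short, wide
"separation tunnel".  `termitesim` is an individual-based, discrete-time
simulation of food transport through such a geometry, together with the
analysis stack needed to study it: efficiency statistics, factorial and
Latin-hypercube parameter sweeps, k-means grouping, t-SNE embedding, and
partial rank correlation coefficients (PRCC) for global sensitivity
analysis.

It is aimed at behavioural ecologists and collective-behaviour modellers
who want a reproducible, scriptable version of this class of
lattice transport model.

## The model

The tunnel is a lattice: a straight main tunnel of 500 unit grid cells from
the nest (cell 0) to the food site (cell 499), plus a 200-cell loop
attached at branching nodes *a* and *c*.  A separation tunnel joins the
main tunnel's middle node *b* to the loop's middle node *d*; it is so short
and wide that crossing it costs no time, and it divides the loop into two
equal 100-cell segments.  The loop sits near the nest (δ = 1), centred
(δ = 2), or near the food site (δ = 3).

Each timestep, every free termite advances one unit-cost edge toward its
current goal (food site or nest).  At the four nodes it may switch between
main and loop tunnel with probabilities P₁, P₂, P₃, P₄ (nodes *a*, *b*,
*c*, *d*); branch choice never reverses a termite relative to its goal.
Two behaviours couple the walkers:

* **Trophallaxis** — a carrier meeting an empty termite head-on passes its
  particle with probability 0.5; both then reverse, so the particle keeps
  moving toward the nest by relay.  No food is ever lost.
* **Traffic jams** — when 4 termites occupy one cell and their heading
  vectors (+1 toward food, −1 toward nest) sum to zero, all of them are
  immobilized for `jam_duration` steps.

Transport efficiency is

> E(τ) = s · Σₜ₌₁^τ food(t) / (τ · N₀),  s = 10 000,

with `food(t)` the nest deliveries during step t and N₀ the colony size;
the scalar E of a run is the mean of E(τ) over the last tenth of the
horizon (4500 ≤ τ ≤ 5000 at the default T = 5000).

PRCC quantifies each Pᵢ's monotone influence on E: all columns are rank
transformed, the linear rank effect of the other inputs is regressed out,
and the Pearson correlation of the residuals is reported.

## A worked example

```r
library(termitesim)

cfg <- sim_config(delta = 2, p3 = 0.4, p4 = 0.4, seed = 42)
res <- run_sim(cfg)
res
#> Termite transport simulation
#>   delta = 2, (P1,P2,P3,P4) = (0.10, 0.10, 0.40, 0.40), N0 = 100, T = 5000
#>   deliveries: 424 (first at t = 518); pickups: 473; jam events: 68
#>   steady-state efficiency E = 8.450 (mean E(tau), 4500 <= tau <= 5000)
```

The first delivery cannot happen before timestep 500: a particle must
traverse the 499 unit-cost edges of the main tunnel after being picked up
at the earliest at the end of step 1.  Here it arrives at t = 518; 424
particles reach the nest in 5000 steps while 49 are still in transit
(pickups = deliveries + in-transit, always).  `plot(res)` draws E(τ), which
is 0 until t ≥ 500, rises steeply, and flattens into the averaging window.

Sensitivity analysis on a synthetic sweep table with a planted effect
(E = 1 − 0.5·P₃ − 0.5·P₄ + noise):

```r
fx <- make_fixture("signal-sweep", seed = 1)
prcc(fx$table[, c("p1", "p2", "p3", "p4")], fx$table$mean_E)
#> PRCC (N = 200 samples)
#>   variable      prcc
#> 1       p1 -0.009175
#> 2       p2  0.027625
#> 3       p3 -0.973544
#> 4       p4 -0.970747
```

The planted drivers are recovered at near-unit magnitude; the inert inputs
stay near zero.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "termitesim", package = "termitesim")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","termitesim",package="termitesim"))')" \
  simulate --delta 2 --p3 0.4 --p4 0.4 --n0 100 --steps 5000 --seed 42 --out run.csv
```

Subcommands: `simulate`, `sweep` (factorial or `--lhs`, with a resumable
`--journal`), `analyze cluster|hist|tsne|prcc`, `fixture`, and
`reproduce-fig3`.  Every subcommand writes a JSON manifest with seeds and
checksums of its outputs.

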
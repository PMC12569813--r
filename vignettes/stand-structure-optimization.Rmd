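---
title: "Stand structure indexes and two-agent optimization: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand structure indexes and two-agent optimization: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(standopt)
```

This vignette is the package's own account of the science it implements:
the structural model of a circular plot, the objective and constraint
system, the two coordinated intervention agents, the growth-prediction
cycle, and the numerical and design choices made where the problem left
room. Nothing here states an empirical result that the test suite does
not itself compute.

## The structural model

A *stand* is a circular plot of radius 12–35 m with every living stem of
DBH ≥ 5 cm mapped in plot-centred Cartesian metres (y = north, azimuths
clockwise from north). Edge effects are handled by the buffer method: the
boundary is contracted inward 2 m, and trees in the buffer ring act only
as neighbours, never as reference trees. Spatial relationships come from
the Voronoi tessellation of all living stems; two trees are neighbours
when their cells — clipped to the plot disk — share an edge, so adjacency
through the plot exterior cannot occur. One *spatial structure unit* is a
core reference tree plus its neighbours.

Five per-tree indexes live on these units (all but CI bounded in [0, 1]):

* **Neighborhood comparison U** — fraction of neighbours with strictly
  larger DBH. Ties count as "not larger": the comparison the index
  encodes is strict dominance.
* **Complete mingling Mc** — `Mc = (M/2)·[(1 − Σ n_j²/(n+1)²) + n'/n]`
  where `M` is the heterospecific-neighbour fraction, `n_j` the neighbour
  count of species `j`, and `n'` the neighbour species richness. The
  reference tree enters only through the `(n+1)²` normalisation; a config
  switch (`mingling_include_reference`) adds it to the counts. The
  bracket rewards both mixing and the evenness of the mixture; a
  checkerboard of two species has `M = 1` but a much smaller bracket than
  a fine-grained seven-species mosaic.
* **Stratification index S** — vertical layers are thirds of the dominant
  height `H_d`; a tree's layer flag is −1/0/+1 with exact boundary
  heights assigned to the middle layer. `S = (z/3) ·` (fraction of
  neighbours in the reference's layer), `z` the number of distinct layers
  in the unit. `H_d` is the mean of `height + relative elevation` over
  the ⌊100·A⌋ tallest trees (A = plot area in ha): the terrain adjustment
  recognises that on a slope a shorter tree upslope can top the canopy.
  The printed layer rule uses height alone; `terrain_adjusted_layers`
  switches layers to `height + rel_elev` as well.
* **Crown competition index CI** — crowns are disks of diameter CW at the
  stem; `CI_i = Σ_j AO_ij · L_j / (L_i · Z_i)` with `L = H·CW·CL`,
  `Z_i` the reference crown projection area, and `AO_ij` the two-circle
  lens area. The source convention sets `AO = 1 m²` for disjoint crowns,
  which injects a unit of competition from arbitrarily distant
  neighbours; it is implemented literally but exposed as
  `no_overlap_value` (0 disables it) because the sentinel, not the lens
  geometry, then dominates sparse neighbourhoods.
* **Uniform angle index W** — the fraction of angular gaps between
  successive neighbour directions below the standard angle
  `α₀ = 360°/(n+1)`, each gap taken in its smaller form.

### Why W defaults to the four nearest neighbours

The classic W estimator uses the `k = 4` nearest neighbours and
`α₀ = 72°`; under complete spatial randomness its stand mean is ≈ 0.496,
which is precisely the reference constant the objective penalises
deviations from, and the ideal band [0.475, 0.517] is that estimator's
random-pattern interval. Evaluating W on Voronoi-unit neighbours with the
adaptive threshold instead centres the index near 0.38 under CSR, and —
because Voronoi adjacency is locally scale-invariant — clustered patterns
barely move it. Under that variant the reference constant 0.496, the
ideal band, and any pattern-sensitivity claim are unreachable, so the
package computes W over the 4 nearest living trees by default
(`index_config(w_neighbors = "nearest", w_k = 4)`); the Voronoi-unit
variant remains available as `w_neighbors = "unit"`, and the single-unit
function `uniform_angle_index()` scores whatever neighbour set the unit
carries. Measured on the package's own generator (500-tree stands): CSR
W̄ ≈ 0.49, jittered square planting lattice ≈ 0.0, tight cluster process
≈ 0.64.

## Objective and constraints

The stand objective multiplies the factors to be increased (mingling,
stratification) and divides by those to be suppressed (size dominance,
crown competition, deviation of W from 0.496), each scaled by the
population standard deviation of its per-tree values over the current
core trees (`δ_W` is taken over `|W − 0.496|`). A zero standard deviation
(degenerate uniform stand) is replaced by 1 so the factor reduces to
`1 + value` rather than dividing by zero. The deviations are recomputed
for every stand state; `freeze_deltas` evaluates candidate moves under
the pre-move deviations for stability inside the optimizer (both
behaviours are exact; the default follows the state-dependent reading).
The mean is taken over core reference trees — indexes exist only for
them, which resolves the summation-limit ambiguity in the printed form.

The constraint system compares three states — initial, after harvest,
after replanting — all non-strictly: no index mean may worsen under
harvest; diameter-class count `D` and species count `T` are preserved
(class width 2 cm from 6 cm; 5–6 cm replants occupy a pre-class 0 outside
`D`, so planting cannot break class preservation, and a tree that is the
last of its species is never drawn for felling); canopy density
(grid-union of crown disks at a fixed 0.25 m step, deterministic by
construction) stays ≥ 0.7 at the harvested and replanted states; at most
35% of the initial stems are removed; replanting must not worsen the
angle deviation, must not reduce mingling, and must land the final
density within [1667, 3333] stems/ha.

## Interventions

Felling candidates are drawn uniformly at random from the living core
trees (the selection rule that couples best with the learning solver).
Planting sites are the incenters of the largest Delaunay triangles —
canopy gaps — filtered to at least 1 m inside the core boundary and 0.5 m
from any stem, scored by the replanting foreground index
`RFI = (1 + DAA/δ_DAA)(1 + Mc/δ_Mc)(1 + U/δ_U)/(1 + CI/δ_CI)` of a
virtual 5 cm recruit at the site (DAA = containing-triangle area). The U
factor sits in the numerator as printed — a suppressed site scores
higher; `u_in_denominator` exposes the alternative reading. Species
rotate round-robin through the seven native species, keeping shares equal
to within ceiling arithmetic. Replants initialize at DBH 5 cm, age 5
years, with height/crown width/crown length from the species growth-curve
bank. Within a planting plan the index standard deviations are computed
once against the base stand: they move negligibly per stem, and
recomputing them each step would dominate planning cost.

The growth bank ships the published curves for the seven species. Rows
whose printed parameters do not reproduce the printed curve value at the
5 cm initialization diameter to two decimals carry an additive
calibration offset pinning the 5 cm output to the published value (the
offsets are visible in `growth_model_bank()`); those calibrated curves
are trusted at and near the initialization diameter only — projecting
established trees is the prediction module's job. The one structural
correction: the broadleaf birch height model is evaluated as
`H⁻¹ = a + b/DBH`, the unique reading that reproduces its published
5 cm value.

## The two agents

The harvest agent walks a positional counter 0 → 50, the replant agent
100 → 50; an episode ends when they meet (or a step guard of twice the
range fires). A harvest forward step proposes one random felling,
accepted only if every harvest-stage clause still holds against the
episode's initial stand, and rewarded by the objective-gain band; a
rejected proposal burns the move. A replant forward step performs one
curve-trend window move on the replant count — evaluate the objective at
`{c − s, c, c + s}`, slide toward an ascending trend, halve the spacing
at an interior maximum — and re-realizes the plan; a backward step
retracts the counter (and, for the replant agent, halves the spacing).
The initial spacing is a quarter of the replant cap, so the first window
spans three evenly spaced densities across the whole feasible range
before contracting. Positional moves always advance or retract the
counter; leaving the range or exceeding the 35% budget is an illegal
move. Planting-location sequences are append-only caches extended lazily
against the harvested stand current at extension time, so re-realizing a
plan at a smaller count is a prefix lookup.

Rewards follow the published schedule: +150 for terminal success (agents
meet, all clauses pass, objective above its initial value), −50 for a
constraint violation, +100/+50/+10/+1 for accepted moves improving the
objective by ≥ 5%/1%/0.1%/> 0 of its initial value, −1 for an accepted
move that did not improve it (the band for a zero change, which the
source leaves open, is folded into this value), −50 for an illegal move.
The event-to-value mapping is config-exposed and logged per step.

Both solvers share the episode mechanics. The tabular baseline keeps one
Q table per agent over (position × coarse objective-ratio bin) × {forward,
backward}. The deep solver approximates action values with a 3 × 24-unit
ReLU network per agent over a stand-summary observation (position, the
five index means, canopy density, density, budget fractions, objective
ratio — the network input is not specified by the source, and a
positional-only observation is an available ablation), trained by
experience replay (capacity 10 000, batch 32) against a target network
synced every 100 learner steps, with squared TD error under a Huber-style
clip (`td_clip = 10`) — plain SGD at the published learning rate diverges
on ±150-scale rewards without it. The value head initializes at zero so
initial action preferences are unbiased (ties break to "forward", exactly
as in the zero-initialized tabular baseline). ε = 0.9 is read as the
greedy rate (a 90% random-action rate would make learning irrelevant);
an optional linear decay is off by default. Every run tracks the best
fully feasible state ever evaluated, so the returned stand satisfies the
complete constraint system regardless of learning quality, and the null
intervention keeps the initial stand available whenever it is itself
feasible.

## Prediction and the dynamic loop

The prediction module assembles per-tree features (AGE, DBH, 1/DBH,
DBH², H, CW, CL, NT, SDI, SLO, ASP as an 8-sector ordinal, HDR, BAL,
HCI), screens multicollinearity by iterated VIF elimination above 10, and
fits one pluggable learner per task with the documented feature subsets:
diameter growth (target `ln(DGI + 1)`, inverted as `exp(·) − 1` clamped
at zero so DBH never shrinks), height, crown width, crown length, age,
and a mortality probability. The competition measures the source names
but does not define use the standard forestry forms: Hegyi
size-ratio/distance over Voronoi neighbours, basal area in strictly
larger trees (m²/ha), Reineke stand density index (reference 25 cm,
slope 1.605), height/diameter ratio. Default learners are random forests
for the height and crown-width tasks and gradient boosting elsewhere —
deliberately not the source's CNN/stacked-MLP architectures, whose
training data are unavailable; any object with the `fit`/`predict`
contract drops in, and the canonical-form PSO tuner (inertia 0.72,
cognitive/social 1.49) is available for hyperparameter search against
validation loss. One cycle advances the stand five years in the fixed
order age → DBH → height → mortality → crown width → crown length,
refreshing features between steps; a tree dies only if its predicted
mortality probability exceeds 0.5 *and* its Hegyi index exceeds 0.75;
ages advance deterministically by +5 by default (in simulation age is
known; the learned age model sits behind `predict_age`). The synthetic
reference law used to label training stands makes diameter increment
decline exponentially in DBH and linearly in BAL, takes allometry from
the dominant conifer's curves, and kills trees above a Hegyi index of 8 —
mortality must be a tail event, and Hegyi values in these densities run
2–6.

The dynamic loop optimizes, stops if the ideal state (Ū ≤ 0.5,
M̄c ≥ 0.75, 0.475 ≤ W̄ ≤ 0.517) is reached, otherwise advances five years
and repeats, for at most `max_cycles` advances (default 8, a 40-year
horizon); each cycle reseeds the solver from `seed + cycle`. Reported
"years" count growth advances only.

## What the generator emulates — and what it does not

`generate_stand()` reproduces the plot conditions the package targets:
radii 12–35 m, densities ~1400–3900 stems/ha, Weibull diameters
(shape 2.6) truncated at the 5 cm survey floor, dominant-conifer
allometry with lognormal noise for heights and crowns, a planar
slope/aspect ramp for relative elevation, and a spatial pattern dial from
jittered square planting lattice (−1) through CSR (0) to tight Thomas
clusters (+1); tree counts are exactly `round(density · area)`. It does
not emulate measurement error, within-plot site heterogeneity, species-
specific diameter distributions, or snags — so passing tests demonstrate
the machinery's correctness and the method's behaviour under controlled
conditions, not field performance. Degraded-stand benchmarks use a 90/6/4
species mix (mingling near zero, as in heavily pine-dominated secondary
stands) and moderate clustering (0.3–0.5), matching the published plots'
initial angle-index values of 0.21–0.56 rather than an idealised CSR
pattern; an idealised CSR start places W̄ so close to 0.496 that the
non-worsening clauses on `|W̄ − 0.496|` leave interventions no room,
which is a property of the constraint system, not a solver failure.

## Numerical choices and problem sizes

Geometry goes through exact closed forms (two-circle lens, shoelace
areas, side-length-weighted incenters) with the tessellation read from
`deldir` but all coordinates taken from the original stems; boundary ties
resolve inward (a tree at exactly the core radius is core); collinear or
sub-4-point configurations raise typed geometry errors. Canopy density
uses a fixed 0.25 m grid for reproducibility of the ≥ 0.7 check (worst-
case discretisation error ~1% at these crown sizes). The test and
benchmark problem sizes are deliberate package choices that keep the full
suite practical on one CPU: benchmark stands of 100–210 stems (radius
12–15 m), 6–14 learning episodes per solver run with positional ranges of
10–15 moves per agent, 2–3 candidate incenters per planting inside the
optimizer (10 for standalone planning), and 3–8 dynamic cycles; all are
`optimizer_config()` fields, and production use scales them up freely.

## Known limitations

* The replant clause `|W̄₂ − 0.496| ≤ |W̄₁ − 0.496|` binds hard once a
  stand's angle mean sits at the random-pattern value: gap-incenter
  planting regularises the pattern, so large replant counts in one cycle
  push W̄ below the band. Mingling therefore accumulates over several
  cycles rather than in one.
* The dynamic loop can fixate before the ideal thresholds. On the
  planted-lattice benchmark the first two cycles lift the angle mean from
  0.21 to ≈ 0.474 and mingling from ≈ 0.005 to ≈ 0.60, after which the
  best feasible objective state becomes a constrained local optimum:
  almost no single-tree move satisfies every non-worsening clause, and
  the few that do lower the objective, so further episodes reproduce the
  same state (verified at doubled episode counts). The objective only
  penalises `|W̄ − 0.496|` smoothly and knows nothing about the ideal
  band's edges, so its feasible argmax may sit arbitrarily close to — but
  outside — the band. Batch (per-episode) constraint evaluation instead
  of per-move gating could escape such optima, at the cost of changing
  the acceptance semantics of individual moves.
* Reward semantics for simultaneous terminal success and a final move's
  own band add the two rewards on the final transition.
* The positional state is a budget of micro-decisions, one tree per
  harvest step and one window move per replant step; the binding between
  counter positions and silvicultural meaning is a documented
  reconstruction, as the source never states one.
* Crown geometry is 2-D; no light-competition or 3-D crown model.
* The PSO tuner and the value-network trainer are single-threaded by
  design for reproducibility.
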
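---
title: "Modeling circular aggregate formation by gliding, contact-signaling rod cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circular aggregate formation by gliding, contact-signaling rod cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

*Myxococcus xanthus* cells glide on surfaces as flexible rods, periodically
reversing their direction of travel (head and tail swap roles).  When the
TraAB adhesins are overexpressed, cells stick to one another end-to-end and
side-by-side, sustained cell-cell contacts suppress reversals, and the
population self-organizes into macroscopic *circular aggregates* (CAs):
dense rotating discs in which cells circulate around a common center.
`myxosim` implements an agent-based biophysical model of this process — the
mechanics of individual gliding rods, slime-trail following, allele-aware
cell-cell adhesion, and a contact-gated reversal clock — together with the
analysis toolkit needed to detect CAs and score the emergent phenotypes of
wild-type (WT), adhesin-overexpressing (OE), and nonreversing (NR) strains
and their mixtures.

## The agent model

Each agent is a chain of $N = 7$ circular nodes of width $w = 0.5$ µm held
at fixed spacing $L/(N-1)$ by a length constraint, for a total length $L =
6$ µm.  Per node and per time step $dt$:

* **Propulsion.** Every node except the tail carries a force of magnitude
  $F_p = F_T/(N-1)$ directed toward its forward neighbor ($F_T = 55$ pN).
  The head node's force direction is steerable (below).
* **Drag.** Motion is overdamped: node velocity is net force divided by the
  drag coefficient $c = 22$ pN·min/µm.  The agent mass (Table value
  $1.2\times10^{-15}$ kg) is retained in the configuration for
  documentation only; at these forces the inertial timescale $m/c$ is some
  seventeen orders of magnitude below $dt$, so the first-order overdamped
  update reproduces the quasi-static limit of a Newtonian integration
  exactly.  An isolated straight agent glides at $v^* = F_T/(Nc) \approx
  0.357$ µm/min.
* **Bending.** Angular springs at interior joints exert restoring torque
  $-k_b\,\varphi$ ($k_b = 10$ pN·µm/rad) against deviation $\varphi$ from
  the straight configuration, applied as a momentum- and torque-free force
  triple.
* **Substrate adhesion.** Each node is tethered to a substrate anchor by a
  spring ($k_a = 100$ pN/µm) that resists only the displacement component
  transverse to the local body axis, so longitudinal gliding is unimpeded;
  at total displacement $d_{a,\max} = 0.5$ µm the anchor detaches and
  instantly reattaches at the node position.  Longitudinal gliding thus
  recycles every anchor roughly every 1.4 min, which is what ultimately
  permits slow body reorientation against the springs.
* **Collisions.** Agents are capsule chains (node circles plus rectangular
  spacers).  Overlapping segment pairs receive a linear penalty force along
  the closest-point normal, distributed to the segment end nodes by
  barycentric weights.  The stiffness (`k_rep`, default 1000 pN/µm) is a
  numerical parameter calibrated so that steady-state interpenetration
  stays below 10% of $w$; contacts are frictionless.
* **Length constraint.** After every update, node spacings are projected
  back to $L/(N-1)$ by six symmetric Gauss-Seidel sweeps (center of mass
  preserved), holding residuals far inside the 1% spacing contract; a
  slack projection measurably degrades the rotational coherence of dense
  aggregates, so the solver is deliberately kept tight.

The domain is a square of edge `L_sim` (200 µm at full scale) with periodic
boundaries; all distances use the minimum-image convention.

## Reversals, turns and steering

Each agent carries a reversal clock $r_t$.  Without contacts the clock
advances by $dt$ per step; when $r_t \ge \tau_r$ (8 min for WT/OE) the
agent reverses — head and tail swap, propulsion flips — and the clock
resets.  NR agents have the clock pinned at zero.  Every $\tau_t = 5$ min
an agent performs a random turn for 1 min: the head propulsion rotates 90°
(random sign) off the body axis, and the two joints behind the head adopt a
spontaneous bend (`turn_curvature`, default 45°/joint) — the cell actively
flexes its front to steer, which at these force scales is what makes a
commanded turn produce a visible change of course.

**Slime trails.** Gliding cells extrude slime; the tail node writes the
local body orientation (mod $\pi$ — trails are apolar) into a grid of
0.5-µm cells, latest writer wins.  The head pole senses trails in its own
and the eight surrounding cells and steers toward the nearest branch
($\hat e_s$ or $\hat e_s + \pi$) of the most reinforced fresh trail, with
the head propulsion direction rotating at up to `omega_s` per minute.
Three artifact-level choices matter here, all exposed in the configuration
and all resolved by calibration on the nonreversing control (the condition
the model must turn into rotating aggregates) *before* the acceptance
panel was scored:

* `omega_s = 360`°/min — effectively instantaneous alignment of the head
  *force* with the trail; the body still reorients slowly (its mobility,
  roughly 15-25°/min, is set by drag and the substrate springs), so this
  does not make cells jitter.  With slow force alignment (30°/min) cells
  cross thin trails before aligning and capture fails.
* `slime_max_age = 45` min — trails older than this are ignored.  Without
  decay, weeks-old crisscross trails steer as strongly as a freshly
  reinforced highway and the orientation noise prevents coherent swirls.
* `slime_min_visits = 2` — only trails deposited on at least two distinct
  passes (deposits separated by more than a body transit) steer.  This
  implements trail *reinforcement*: traffic concentrates on corridors,
  corridors that close into loops trap their traffic, and the loops become
  rotating aggregates.  Single-pass trails are treated as too faint to
  follow.

During an active random turn the turn overrides slime steering; the
steering state is reset on reversal.

## Cell-cell adhesion and contact signaling

Node pairs of different agents within reach form adhesion bonds:
*end-end* when one agent's head node meets another's tail node (reach
$d_{thr} = 1.5$ µm), *lateral* for every other node pair (reach 0.9 µm).
The bond force is the piecewise law $F_{adh} = k_{adh}\,\frac{d-w}{w}\,F_T$
for $w < d \le d_{thr}$ and zero otherwise, applied toward the partner
node.  The adhesion factor is allele-aware: matched OE pairs use 0.1,
OE pairs with incompatible adhesin alleles 0 (no bond forms, hence no
signaling), every other pairing 0.01.

A bond's age is tracked from formation; breaking (distance beyond reach,
or a head/tail role change after a reversal) resets it.  Bonds older than
$\tau_{thr} = 5$ min suppress the partner agents' reversal clocks:

$$ r_{t+1} = \max\!\Big[r_t + dt\Big(1 - \sum_{\text{end-end}} \delta R_e
   - \sum_{\text{lateral}} \delta R_l\Big),\, 0\Big], $$

with $\delta R_e = 1$ and $\delta R_l = 0.04$.  The sums run over *bonds*
(node pairs), so a flank-to-flank neighbor contributes several small
lateral terms; an alternative distinct-partner counting is available via
`suppression_count = "agent"`.  One aged end-end bond therefore freezes
the clock outright, while full lateral stalling needs about 25 aged bonds
— two tightly apposed cells in a dense aggregate reach that easily.  An
agent is flagged *suppressed* when its total suppression weight reaches 1,
i.e. when its clock is actually stalled or rewinding; merely touching one
aged lateral bond (weight 0.04) does not paint a cell as suppressed.
These flags are the blue/red coloring of `plot.myxo_sim()`.

## Initialization and the simulated conditions

Populations are initialized by rejection sampling: $M = \mathrm{round}
(\eta L_{sim}^2)$ straight agents ($\eta = 0.074$/µm²) at uniform random
positions and orientations, rejecting overlaps, with heads assigned by
fair coin, reversal clocks staggered uniformly in $[0, \tau_r)$ and turn
timers in $[0, \tau_t)$.  A budget of $100M$ attempts bounds the sampler.
Runs last 250 min with snapshots every minute; with $dt = 0.0067$ min a
snapshot lands within one step of each minute mark.  The engine owns a
seeded random stream with sub-streams per purpose, so a run is bit-for-bit
reproducible from `(config, seed)` and ablations do not shift unrelated
draws.

`phenotype_conditions()` packages the computational panel: reversing
agents with adhesion but no signaling (stream networks), nonreversing
agents with and without adhesion (CAs), nonreversing agents without slime
following (no CAs), the WT and OE defaults (no CAs with a minority
suppressed versus CAs with a majority suppressed), WT without the 5-min
gate (CAs return), and the three 1:1 mixtures (incompatible-allele OE
pairs, OE+WT, OE+NR).

## Detecting circular aggregates

`detect_aggregates()` clusters agent centroids with density-based
clustering (DBSCAN; neighborhood 3 µm, core density 8 neighbors —
recalibrated for rod centroids, whose local density is far lower than the
cell density itself) under the periodic metric, unwraps each cluster by
minimum image about a provisional centroid, and scores rotation about the
cluster center.  For member velocity directions $\hat v$ and unit tangents
$\hat t$, the *polar* rotational order is $|\langle \hat v \cdot \hat t
\rangle|$ and the *nematic* tangential order is $2\langle (\hat v \cdot
\hat t)^2 \rangle - 1$; the latter recognizes rings carrying two-way
traffic, which apolar trails readily produce.  Near-stationary members
(speed < 0.05 µm/min) have no meaningful direction and are excluded from
the averages.  The cluster radius is the 90th-percentile member distance
(robust to stragglers).

Because aggregate membership and order fluctuate snapshot to snapshot,
phenotype verdicts (`ca_verdict()`) score several check points over the
final 15 min with velocities measured over a 5-min baseline (a circulating
cell keeps a near-tangential chord; positional jitter averages out) and
call a run CA-positive when clusters of 20+ members reach polar order 0.6
in at least 2 of 4 checks.  The membership, order threshold, persistence
rule and velocity baseline were calibrated on constructed fixtures
(rotating rings, uniform noise) plus the two anchor conditions —
nonreversing agents (must be positive) and short-period reversing agents
(must be negative); transient collision mills flicker above threshold for
single checks, which is exactly what the persistence rule rejects.

## What the scaled-down runs do and do not show

The reference domain is 200 µm (2,960 agents).  The test suite and the
acceptance script shrink the domain — 100 µm for conditions whose
aggregates are large and merging (the OE default, adhesive nonreversing
agents, the OE+NR mixture), 70 µm for the weak-adhesion ablation and the
weakly coupled mixtures, 50 µm for the reversal/slime ablations and the
WT control, 40 µm for the reversal-period sweep — keeping density, time
step and duration at their reference values.  Aggregates are
local objects (radii 5-15 µm), so the phenotypes survive this reduction,
but two caveats apply: seed-to-seed variability grows as each domain holds
fewer nucleation sites, and conditions whose aggregates are weakest (the
gate-free WT ablation, the incompatible-allele mixture) sit close to the
detector threshold at reduced scale.  The radial-kinematics trends (speed
increasing, angular speed decreasing with distance from the aggregate
center) confirm that simulated CAs do not rotate as rigid bodies.

## Known limitations

* The simulation is strictly two-dimensional and single-layered;
  experimental CAs grow by cell layering and reach radii an order of
  magnitude larger than the simulated ones.
* Collisions are resolved by penalty springs rather than an impulse-based
  contact solver; the repulsion stiffness is a numerical tunable.
* In this implementation, slime-following populations condense into CAs
  only when reversals are essentially silenced (nonreversing agents, or
  reversal clocks stalled by contact signaling).  Sweeping the bare
  reversal period upward, aggregates do not yet appear by 100 min at the
  scales we run: reversing traffic makes every trail corridor two-way, and
  two-way corridors reinforce straight stream networks rather than the
  one-way loops that nucleate rotation.  The sweep machinery reports
  whatever onset its runs produce rather than a presumed value.
* The reversal detector is track-based; reversals of agents that are
  mechanically stalled (no centroid displacement) or that occur in the
  final snapshots of a recording are intrinsically invisible to it, as
  they would be to any experimental tracker.

## Reproducing the analyses

```{r, eval = FALSE}
library(myxosim)

# one strong-adhesion run at reduced scale, and its verdict
cfg <- myxo_config(L_sim = 100,
                   strains = data.frame(strain = "OE", allele = 1L,
                                        fraction = 1))
sim <- myxo_run(cfg, seed = 1)
ca_verdict(sim)

# the full phenotype panel (several CPU-hours at L_sim = 100)
pm <- phenotype_matrix(phenotype_conditions(L_sim = 100), seeds = 1:3)
attr(pm, "summary")

# reversal-period sweep
reversal_period_sweep(periods = c(8, 20, 40, 70, 100), seeds = 1:3,
                      L_sim = 100)
```

The repository's `scripts/acceptance.R` recomputes the headline numbers
(worked tracking example, gliding speed, OE aggregate statistics, WT
control, period sweep) from scratch at the reduced scales listed above.
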
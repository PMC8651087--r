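# myxosim

An agent-based biophysical simulator of *Myxococcus xanthus* gliding
motility and of the emergence of **circular aggregates (CAs)** — macroscopic
rotating discs of cells — from three local ingredients: slime-trail
following, allele-specific cell-cell adhesion, and contact-dependent
suppression of cellular reversals.  The package is aimed at researchers
studying collective bacterial motility who want a reproducible, scriptable
reimplementation of this model class, together with the trajectory-analysis
tools needed to score the emergent phenotypes.

## The model in brief

Each cell is a flexible rod of N = 7 nodes (length 6 µm, width 0.5 µm)
gliding on a periodic 2D substrate under overdamped dynamics:

* propulsion `F_p = F_T/(N−1)` per node toward its forward neighbor
  (total motor force `F_T` = 55 pN), balanced by viscous drag `c` = 22
  pN·min/µm per node, giving a free speed `v* = F_T/(N·c)` ≈ 0.36 µm/min;
* angular springs (`k_b` = 10 pN·µm/rad) and a length constraint keep the
  rod semi-flexible; substrate focal-adhesion springs (`k_a` = 100 pN/µm,
  break distance 0.5 µm) resist lateral displacement;
* an internal clock `r_t` triggers a reversal (head ↔ tail) when it reaches
  the reversal period `τ_r` (8 min); 90° random turns fire every `τ_t` =
  5 min; the head steers along slime trails deposited by cell tails;
* node pairs of nearby cells form adhesion bonds — end-end (reach 1.5 µm)
  or lateral (reach 0.9 µm) — with force `k_adh·(d−w)/w·F_T`, where
  `k_adh` is 0.1 between matched adhesin-overexpressing (OE) cells,
  0.01 for weak (WT-like) contacts and 0 between incompatible alleles;
* bonds older than `τ_thr` = 5 min suppress the clock:
  `r_{t+1} = max[r_t + dt(1 − Σ δR_e − Σ δR_l), 0]`
  with `δR_e` = 1 per end-end bond and `δR_l` = 0.04 per lateral bond.

Sustained adhesion → stalled clocks → effectively nonreversing cells →
their slime trails close into reinforced loops → rotating circular
aggregates.  The analysis layer detects these as dense clusters whose
members move tangentially about the cluster center (rotational order
parameter), scores rotation sense (CW/CCW), radial speed profiles,
reversal statistics and suppression summaries.

## A worked example

Nonreversing agents with slime-trail following but *no* adhesion
self-organize into rotating aggregates within 250 simulated minutes:

```r
library(myxosim)
cfg <- myxo_config(L_sim = 50, run_duration = 250,
                   k_adh_wt = 0, k_adh_oe = 0, k_adh_cross = 0,
                   strains = data.frame(strain = "NR", allele = 1L,
                                        fraction = 1))
sim <- myxo_run(cfg, seed = 1)
print(sim)
#> Gliding-agent simulation: 185 agents x 251 snapshots (t = 0..250.004 min)
#>   strains  : NR 185
#>   reversals: 0 logged events
#>   suppressed at end: 0.0% of agents

v <- ca_verdict(sim)
cat(sprintf("CA verdict: %s (best rotational order %.2f in %d/%d checks)\n",
            v$is_ca, v$best_order, v$hits, v$n_checks))
#> CA verdict: TRUE (best rotational order 0.70 in 4/4 checks)
v$aggregates[, c("n_members", "radius", "rotational_order", "rotation_sense")]
#>   n_members   radius rotational_order rotation_sense
#> 1        45 6.579505        0.6923123            CCW
#> 2        28 5.313969        0.4625002           none
```

The first cluster is a circular aggregate: 45 agents within a 6.6-µm
radius circulating counterclockwise with polar rotational order 0.69
(1 would be perfectly coherent one-way rotation; disordered clumps score
near 0).  `plot(sim)` renders the final snapshot, coloring
reversal-suppressed agents blue.

The package also reproduces the tracking arithmetic used for cells inside
experimental aggregates — 443 cells followed for 60 min with only 12
reversal events between them corresponds to one reversal per cell every

```r
mean_reversal_interval(443, 60, 12)
#> [1] 36.91667
```

hours, i.e. reversals are essentially shut off inside aggregates.

Higher-level drivers run whole computational experiments:
`phenotype_matrix()` scores the full strain/ablation panel (WT, OE, NR,
no-slime, no-gate, and 1:1 mixtures) over seeds, `reversal_period_sweep()`
scans the reversal period, and `adhesion_sweep()` maps suppression and
bond lifetimes against adhesion strength.  A thin command-line wrapper in
`inst/cli/myxosim` exposes `run`, `sweep` and `analyze` subcommands over
YAML configuration files and TSV trajectory tables.

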
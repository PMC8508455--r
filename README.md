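# radbreak

Desk-scale simulation of radiation-induced DNA damage and repair in a
human fibroblast nucleus.

Ionizing particles crossing a cell nucleus break DNA both *directly*, by
depositing energy in the sugar-phosphate backbone, and *indirectly*,
through hydroxyl radicals produced by water radiolysis that attack the
backbone chemically. The spatial clustering of those breaks — not just
their number — decides how repairable the damage is: two opposite-strand
breaks within d_DSB = 10 bp form a double-strand break (DSB), extra breaks
within 10 bp make a DSB+, and two DSBs within the fragment gap
d_s = 100 bp make a DSB++; complex clusters resist repair. `radbreak`
implements this whole chain for people who want to study damage-spectrum
questions (LET dependence, scavengeable fractions, fragment statistics,
repair kinetics) at laptop scale:

* **Genome geometry** — a fractal chromatin fiber threaded along a 3-D
  Hilbert curve through an ellipsoidal nucleus (semi-axes
  14.2 × 14.2 × 5 µm), carrying 6.4 Gbp in 46 chromosome territories.
  Molecular volumes (sugar, phosphate, base, histone spheres on a B-DNA
  double helix wound around a solenoidal fiber) are materialised lazily,
  only where a track passes.
* **Track fixture** — a parametric stand-in for a Monte Carlo
  track-structure engine: straight trajectories from a source plane,
  energy deposits at the linear density of a user-given LET (keV/µm),
  radiolysis species (•OH, e⁻aq, H•, …) spawned around deposits with
  configurable per-100 eV yields.
* **IRT chemistry** — the independent-reaction-time method: each
  species–target pair at separation r₀ reacts with ultimate probability
  R_eff/r₀ at a time drawn by inverting
  W(t) = (R_eff/r₀)·erfc((r₀−R_eff)/√(4 D t)), with a 9 nm radical kill
  distance, histone scavenging, optional radical–radical recombination,
  octree neighbour search, and dt_max = 0.5 ns synchronisation windows up
  to T_chem = 5 ns.
* **Damage scoring** — the linear direct-damage law (P = 0 below 5 eV,
  1 above 37.5 eV), P_OH = 40.5 % per •OH–backbone reaction, and the full
  SSB/SSB+/2SSB/DSB/DSB+/DSB++ complexity and direct/indirect/mixed/hybrid
  source taxonomy, plus fragment-length and distant-DSB analytics.
* **Repair kinetics** — dN₀/dt = α(L)·dD/dt − Σ V_p over pluggable pathway
  potentials (NHEJ/HR/SSA/micro-SSA/Alt-NHEJ; first-order defaults),
  irreparable yield N_ir = N_DSB+ + 2·N_DSB++, and peak-normalised
  γ-H2AX focus curves.
* **I/O** — YAML configuration with calibrated defaults, CSV event/break
  logs, SDD-style damage records, deterministic run splitting/merging, and
  an `exec/mdna` command-line driver.

## Worked example

A high-LET micro-irradiation of a small chromatin region (an iteration-1
fiber cube, 52.8 kbp, at roughly fibroblast chromatin density), 50 protons
at 80 keV/µm:

```r
library(radbreak)
cfg <- default_config()
cfg$geometry$hilbert_iteration <- 1L
cfg$geometry$nucleus_semi_axes_um <- c(0.22, 0.22, 0.1)
cfg$geometry$cytoplasm_semi_axes_um <- c(0.44, 0.44, 0.1)
cfg$geometry$bp_per_voxel <- 6600L
cfg$beam$let_keV_um <- 80
cfg$beam$n_primaries <- 50L
model <- config_genome(cfg)
res <- run_damage(model, cfg, seed = 1)
res$tally
#> <damage_tally> 101 strand breaks
#>   SSB  SSB+  2SSB   DSB  DSB+ DSB++
#>    14    11     5     1     4     8
#> sources:
#>   SSB_d   SSB_i   SSB_m   DSB_d   DSB_i   DSB_m DSB_hyb
#>       1      27       2       0      10       3       0
scavengeable_fraction(res$tally)   # 0.769
irreparable_yield(res$tally)       # 20
```

Of the 101 breaks most are indirect (radical-mediated), as expected when
the kill distance leaves only near-DNA radicals alive; at this high LET
the DSB clusters are heavily complex (8 DSB++ vs 1 simple DSB), so the
irreparable yield N_DSB+ + 2·N_DSB++ = 4 + 16 = 20 is large, and 77 % of
DSB-type clusters are scavenger-protectable (indirect or hybrid core).

Repair of a fibroblast-scale yield (25.9 DSB per cell per Gy, 15 %
irreparable) after 1 Gy:

```r
rp <- repair_params(alpha = 25.9, dose = 1, N_ir = 0.15 * 25.9)
state <- solve_repair(rp, t_end_h = 25)
foci <- gamma_h2ax_curve(state)     # peak-normalised gamma-H2AX curve
#> N0: 25.9 at t=0, 7.63 at 1 h, 3.89 (= N_ir) at 25 h
#> scaled foci peak at 1.75 h, 0.80 of peak remaining at 25 h
```

The remaining yield decays to the irreparable level with the fast
(NHEJ-like) and slow (homology-mediated) components, and the focus curve
rises, peaks within two hours and decays while irreparable damage keeps a
focus floor.

The CLI wraps the same chain:

```sh
exec/mdna build-geometry --config run.yaml --out out/
exec/mdna classify --config run.yaml --seed 1 --splits 4 --out out/
exec/mdna repair --config run.yaml --out out/
```

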
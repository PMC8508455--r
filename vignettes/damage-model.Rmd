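---
title: "The radbreak damage model: geometry, chemistry, scoring and repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The radbreak damage model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbreak)
```

`radbreak` simulates the chain from particle traversal to γ-H2AX focus
kinetics in a simplified human fibroblast: fractal genome geometry →
energy deposition → water-radiolysis chemistry → strand-break scoring and
complexity classification → repair kinetics. This vignette is the
package's own account of each model, its assumptions, the parameters that
matter, and what the bundled tests do and do not demonstrate.

## Genome geometry

The nucleus is an ellipsoid with semi-axes 14.2 × 14.2 × 5 µm inside an
ellipsoidal cytoplasm (28 × 28 × 5 µm). Chromatin is threaded along a 3-D
Hilbert curve: iteration $k$ visits the $(2^k)^3$ voxel grid in a single
continuous path whose consecutive cells are always face neighbours, so
the fiber never jumps. We generate the path with the transpose/Gray-code
(Skilling) formulation, vectorised over all cells, and verify
continuity, bijectivity and octant nesting by property tests rather than
against a second implementation.

The unit cube is stretched anisotropically onto the nucleus bounding box
(the flat ellipsoid cannot hold an isotropic cube), and voxels whose
**centres** fall outside the ellipsoid are masked away. The centre-in
test is deterministic and matches mask semantics; voxels cut by the
boundary are kept whenever their centre is inside, a deliberate
convention since the alternative (trimming) would break the path's
bp bookkeeping.

Each retained voxel hosts one chromatin segment: *straight* where the
path continues in the same direction, *turned* or *turned-twisted* (the
two alternate, cancelling net twist of the fiber frame) where it makes a
right angle. Within a voxel the DNA double helix — canonical B-DNA,
0.34 nm rise, 10 bp per turn, backbone sugar/phosphate spheres of van
der Waals radius 0.228/0.263 nm — is wound as a solenoid (fiber radius
12.5 nm) around the segment centreline so that the full helical contour
(`bp_per_voxel` × 0.34 nm) fits inside a few-hundred-nm voxel. The
12.5 nm radius was fixed once so adjacent solenoid turns clear the
backbone non-overlap invariant (centre distance ≥ 0.9 × the radius sum
for non-bonded same-strand neighbours) even in the flattest voxels.
One histone sphere (2.4 nm) per 200 bp sits on the fiber as a
scavenging target. Fiber frames are voxel-local: base-pair indices and
face-centre positions are continuous across joins, but the angular phase
of the winding restarts per voxel — a desk-scale simplification that
does not affect any scored quantity, since scoring depends on genomic
addresses and local geometry only.

**Calibration.** At the default iteration 7, the ellipsoid mask retains
1,099,136 of 2,097,152 voxels (deterministically). With 5823 bp per
voxel the genome totals 6,400,268,928 bp — the 6.4 Gbp diploid target to
within 0.004 %. The masked path is cut into 46 contiguous territories
with bp proportional to human chromosome lengths (diploid, XX;
`chromosome_partition = "equal"` is available). Note the distinction
between two densities: the *modelled* ellipsoid (volume ≈ 4.2 × 10³ µm³)
has ≈ 1.5 × 10⁻³ bp/nm³, while the *nominal* literature density — a
~6 Gbp genome in a ~500 µm³ nucleus — is 0.012 bp/nm³
(`nominal_bp_density()`). The flat ellipsoid is a geometric idealisation
of an adherent fibroblast, not a literal 500 µm³ nucleus.

Molecular volumes are only ever materialised inside a region of interest
(`materialize_region()`); a full-genome materialisation would be ~38
billion spheres. The damage pipeline materialises the corridor of voxels
around each track (kill distance + diffusion margin), memoising voxels
and their spatial indices across primaries.

## Track fixture

The fixture replaces a full Monte Carlo track-structure engine with a
parametric surrogate, which is the central caveat of the whole package:
its spectra are *inputs*, not physics. Primaries start on a plane
perpendicular to the beam axis, offset 3 µm beyond the nucleus surface
(the offset is surface-referenced so the plane never intersects the
nucleus), with entry points uniform over the nucleus' projected ellipse,
and travel in straight lines. Along the chord through the nucleus,
deposits are a Poisson process with mean spacing ⟨ε⟩/LET, so the
energy per unit path length converges to the configured LET (verified to
1 % in the tests); per-event energies follow a truncated-exponential
spectrum with mean ⟨ε⟩ = 45 eV on [5, 500] eV, and deposits are displaced
radially by an exponential penumbra (2 nm scale). Species counts per
deposit are Poisson with mean G·E/100 for per-100 eV yields G
(defaults: •OH 2.8, e⁻aq 2.8, H• 0.6, H₃O⁺ 2.8, …), positions
Gaussian-jittered (σ = 1 nm). ⟨ε⟩, the spectrum bounds, penumbra, yields
and diffusion coefficients are all configuration, and externally produced
event lists can replace the fixture via `read_external_events()`.
Consequently all *absolute* yields of the package depend on these
surrogates; the quantities worth trusting are comparative (trends with
LET, fractions, clustering statistics).

## Chemistry: IRT with a kill distance

Radiolysis species diffuse and react from 0 to T_chem = 5 ns. Species
born farther than the kill distance d_kill = 9 nm from the nearest DNA
sphere surface are removed at birth — they would be scavenged by the
bulk before reaching DNA. The two parameters cohere: the 3-D
mean-squared-displacement time for •OH (D = 2.8 nm²/ns) to cover 9 nm is
d²/6D = 4.82 ns ≈ T_chem (`consistency_check_kill_time()` warns beyond
50 % discrepancy). The boundary is exclusive: exactly at d_kill a
species survives.

Reactions use the independent-reaction-time method. Every channel is
treated as fully diffusion-controlled: a rate constant k (M⁻¹s⁻¹) maps
to an encounter radius R_eff = k/(4π D_rel N_A); for a pair at initial
separation r₀ the ultimate reaction probability is W∞ = R_eff/r₀ and,
conditional on reacting, the time inverts
W(t) = (R_eff/r₀)·erfc((r₀−R_eff)/√(4 D_rel t)). DNA moieties are
static (D_rel is the species' own D). The only break-producing channel
is •OH + backbone (default R_eff 0.2 nm, a configurable surrogate —
published rate tables can be supplied through the channel list); histone
contact removes a species without damage; radical–radical recombination
channels (•OH+•OH, •OH+e⁻aq, e⁻aq+e⁻aq, …, with standard aqueous rates)
ship disabled and are switched on for LET-trend studies.

The stage is split into windows of at most dt_max = 0.5 ns. Within a
window, candidate pairs come from octree queries with a search radius
R_eff + 8·√(D_rel·dt) (beyond which the in-window reaction probability
is negligible); sampled events earlier than the window end are processed
earliest-first with reactant consumption; survivors take one Gaussian
diffusion step (variance 2·D·dt per axis) and the next window re-pairs
from the new positions. How dt_max and IRT interact is genuinely
underdetermined in this model family; re-pairing with position
resampling is our reading, and it makes the window length a
physical-fidelity knob rather than a pure optimisation.

A design choice worth noting: every species owns a private RNG substream
from which its pair deviates and diffusion steps are drawn in canonical
order. Chemistry against static targets is then independent across
species, which gives a strong determinism property — at a fixed master
seed, enlarging d_kill (a superset of survivors) can only add DNA-hit
events while species–species channels are off. The tests assert this
exactly, not statistically.

## Damage scoring and classification

**Direct.** A deposit counts toward a backbone site (chromosome, strand,
bp) when within R_direct = 0.35 nm of the site's sugar *or* phosphate
centre (hydration-shell-inclusive radius); it counts once per site but
fully toward each of several sites in reach (no energy splitting — the
simplest deterministic rule). Site energies accumulate across the
primary's deposits, and one uniform draw per site applies the linear
law: P = 0 at ≤ 5 eV, 1 at ≥ 37.5 eV, linear between. Per-site (rather
than per-deposit) sampling follows the lineage of linear-threshold
damage models.

**Indirect.** Each •OH–backbone reaction independently breaks the site
with P_OH = 0.405; repeat hits on a broken site add nothing. When a site
is hit both directly and indirectly, the direct label wins (the physical
stage precedes the chemical one).

**Classification** is per primary particle ("simultaneous" damage means
the same primary; cross-primary clustering is off). Per chromosome:
(1) opposite-strand breaks within d_DSB = 10 bp are paired into the
*maximum* number of DSBs, leftmost-first among optima — the greedy
earliest-partner matching, which the test suite proves equal to
exhaustive enumeration on a boundary-covering set of all ≤ 4-break
configurations and hundreds of random dense ones; (2) leftover breaks
within d_DSB of a DSB core attach as accessory damage; (3) DSBs within
d_s = 100 bp pair into DSB++ clusters (counted once), remaining DSBs are
DSB+ if they carry accessories, else DSB; (4) unassigned breaks pair
within d_s into SSB+ (same strand) or 2SSB (opposite strands — such
pairs are always farther than d_DSB apart, otherwise the matching would
have absorbed them), the rest are SSBs. Boundary conventions are
inclusive (|Δbp| ≤ d_DSB pairs; ≤ d_s clusters). A DSB's genomic
position is the floor of its core-pair midpoint. Source labels: d/i/m
for pure-direct, pure-indirect, mixed; DSB_hyb is reserved for an
all-indirect core with at least one direct accessory, so the
scavengeable (protectable) fraction (DSB_i + DSB_hyb)/(all DSB-kind
clusters) counts every cluster whose core an •OH scavenger could have
prevented; `include_hyb = FALSE` gives the stricter ratio. With zero
DSBs the fraction is NA, never 0.

Fragment lengths are successive differences of sorted DSB positions per
chromosome including both end fragments; `distant_dsb_count()` merges
DSBs closer than 10 kbp into one detectable cluster, mimicking
gel-electrophoresis resolution ("at least 10 kbp" separation keeps
clusters distinct, so the merge condition is strictly-less-than).

## Repair kinetics and γ-H2AX

The remaining DSB yield follows
$dN_0/dt = \alpha(L)\,dD/dt - \sum_p V_p$ with the induction term active
only during irradiation (default: instantaneous dose at t = 0, so
N₀(0) = α·D; tabulated dose-rate functions are accepted). The pathway
potentials are pluggable; the built-in default is first-order kinetics
$V_p = k_p f_p (N_0 - N_{ir})$ with a fast NHEJ-like component
(fraction 0.75, half-life 0.3 h) and slower homology-mediated components
(HR/SSA 4 h, micro-SSA/Alt-NHEJ 8 h). These fractions and half-lives are
surrogates standing where a full multi-equation pathway system would
plug in; they reproduce the canonical biphasic repair shape, not any
specific dataset. The irreparable yield N_ir = N_DSB+ + 2·N_DSB++ never
enters any potential, so N₀(∞) → N_ir. Integration uses
`deSolve::ode` (lsoda, rtol = atol = 10⁻⁹); conservation
(N₀ + Σ repaired = induced) holds to 10⁻⁶ relative in the tests.

Foci follow dF/dt = k_on·N₀ − k_off·max(F − F_floor, 0) with a 1:1
focus:DSB baseline; defaults k_on = 8 h⁻¹, k_off = 0.4 h⁻¹ give a rise
over ~1–2 h and slow decay. The output curve is peak-normalised —
"scaled" is not defined more precisely in this model family, and peak
normalisation is the interpretation that makes curves comparable across
doses. Time is hours here and nanoseconds in chemistry; the modules
convert at their boundary.

## Randomness, determinism and run splitting

Every primary owns an RNG stream seeded from (master seed, primary id)
(`primary_seed()`), and every species a substream of its primary's. A
run split into k jobs therefore reproduces the unsplit run *exactly* —
merging is associative bookkeeping, refused across differing
configuration hashes. All seeds stay below 2³¹.

## Numerical choices and degenerate inputs

Inclusive octree query boundary (distance ≤ r); r = 0 finds exact
matches; empty trees return empty results. IRT contact (r₀ ≤ R_eff)
reacts at t = 0. Empty break sets give zero tallies; zero DSBs give NA
fractions; empty masks count 0 bp. The truncated-exponential rate is
solved by `uniroot` per call. erfc/erfc⁻¹ are expressed through
`pnorm`/`qnorm`.

## Problem sizes used by the bundled tests

The unit and acceptance tests run at desk scale by design: geometry
checks materialise iteration ≤ 3 models; the classifier oracle
enumerates 12,950 boundary-covering configurations (positions
{0, 9, 10, 11, 20, 99, 100, 101, 110, 200, 399} on both strands of a
400 bp duplex — every distance relation the rules depend on — rather
than the astronomically many raw ≤ 4-break position sets); the IRT
sampler is checked with 10⁵ draws against the closed form and against a
10⁵-walker walk-on-spheres Brownian absorption oracle (exact harmonic
measure, ε-shell bias ≈ 0.4 %); the LET-trend property uses an
iteration-1 fiber cube (52.8 kbp) with 1000 primaries at 15 keV/µm
against 150 at 250 keV/µm, recombination channels on — sizes chosen for
stable statistics across seeds.

## Known limitations

* The track fixture is a surrogate: absolute break yields per Gy track
  the configured deposit spectrum and species yields, so comparisons to
  measured absolute yields are out of reach by construction; trends and
  fractions are the meaningful outputs.
* Only •OH induces indirect breaks; base damage is not scored (bases are
  geometric obstacles and kill-distance reference only).
* All channels are fully diffusion-controlled; partially
  diffusion-controlled corrections and G-value time-evolution validation
  need a real physics stage.
* The repair defaults are illustrative first-order kinetics; α(L) and
  pathway constants should be supplied when quantitative repair curves
  are wanted.
* Chromosome territories are contiguous path runs, not spatially
  reconstructed territories; cytoplasm content is not modelled.
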
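---
title: "The Dynamic Loop polymer model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Dynamic Loop polymer model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynloop)
```

## The model

Interphase chromatin is modelled as a totally flexible, self-avoiding
lattice polymer whose non-adjacent monomers form transient bonds — loops —
when diffusion brings them into contact. Each monomer coarse-grains tens of
kilobases of chromatin fibre (well above the persistence length, which is
why bending rigidity can be neglected), and the balance between *short-range*
and *long-range* looping controls the large-scale compaction of the chain.
The counter-intuitive headline behaviour the model exhibits is that removing
short-range loops *condenses* the polymer: fewer short loops mean less
entropic intra-chain repulsion, distant chain sections intermingle more, more
long-range loops form, and the net volume shrinks. Conversely, removing
long-range loops always expands the chain.

### Lattice dynamics

The chain evolves by the three-dimensional bond fluctuation method: each
monomer occupies a 2×2×2 cube of lattice sites, no site is shared between
monomers, and every bond — backbone or loop — must be one of the 108 allowed
vectors (squared lengths 4, 5, 6, 9, 10). An elementary move displaces one
randomly chosen monomer by one lattice unit in one of the six axis
directions and is accepted only if excluded volume and all incident bond
constraints remain satisfied. The excluded squared length 8 together with
unit-step moves makes chain crossing impossible, so topology is preserved
without any explicit check. One Monte Carlo step (MCS) is `N` attempted
moves. The lattice is periodic with edge `L` chosen large enough (default
500 at full scale) that periodic images never interact; positions are stored
unwrapped so observables need no image corrections.

### Loop dynamics

After each MCS, expired loop bonds dissociate and every currently *proximal*
pair — separation vector itself an allowed bond vector — undergoes a
Bernoulli formation trial. The formation probability is

* `p_short` when the contour separation is at most the short cutoff
  (50 monomers at full scale, i.e. just under 5% of the 1050-monomer chain),
  `p_long` otherwise (the *adapted* rule); or
* `p_short` inside a looped domain, `p_long` between looped domains, and 0
  for linker monomers under the *domain-adapted* rule, which tiles the chain
  with 21 alternating 50-monomer blocks (11 linkers, 10 looped domains) to
  mimic topological domains; or
* a single constant for the homogeneous warm-up phase.

A formed bond draws a Poisson lifetime with mean `t_bond = 8000` MCS and
carries an absolute expiry time. Backbone bonds never break.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `N` | monomers | 1050 (105 in test presets) | chain length; 1050 = 21 × 50 so the domain layout closes on a linker |
| `L` | lattice sites | 500 (64 in tests) | box size; ≥ 4 radii of gyration recommended |
| `p_short`, `p_long` | per encounter per MCS | study variable | the model's control dials |
| `short_cutoff` | monomers | `round(0.05 N)` | short/long boundary; 50 at full scale |
| `t_bond` | MCS | 8000 | mean loop lifetime |
| `max_bonds_per_monomer` | – | 1 | one binding site per monomer; configurable for sensitivity analysis |

The proximity criterion is deliberately the allowed-vector set itself: any
wider cutoff would nominate pairs whose bond could not be represented on the
lattice.

## Simulation protocol

A run starts from a freshly grown random self-avoiding walk, equilibrates
first under homogeneous looping at `(p_short + p_long) / 2` (a neutral warm
start; the value is configurable), then under the target rule, and finally
samples conformations every `save_interval` MCS. Snapshot independence is
controlled through the autocorrelation time of the squared radius of
gyration: τ_ac is fitted retrospectively from the production Rg² trace
(weighted log-linear fit of the autocorrelation down to 0.05), and the run
is flagged with thinning guidance — not aborted — when the spacing is below
5 τ_ac, since the full-scale schedule fixes the spacing a priori. All
randomness flows from one base seed through hashed sub-seeds per phase, so
every run, scan cell and fixture is bitwise reproducible.

Full-scale study conditions (shipped as the `full_scale` preset) are two
10⁸-MCS equilibrations, snapshots every 10⁷ MCS and at least 1000
conformations — cluster-scale work. The package's own analyses and tests use
reduced presets; see below for what that implies.

## Observables

`msd_profile()` computes the mean square spatial distance ⟨R²⟩ between
monomers `s` apart, pooled over all pairs and conformations; the standard
error is taken over conformation-level means because pairs within one
conformation are strongly correlated. The *plateau* of this curve is the
compaction readout. Since the saturation level has no canonical estimator,
the package fixes one by definition: the pair-count-weighted mean of ⟨R²⟩
over the top tercile of separations (`s ≥ ⌈2N/3⌉`), with coverage up to
0.8 N required. `heatmap_scan()` maps the plateau over a
`(p_short, p_long)` grid with per-cell hashed seeds, incremental TSV output
and resume support. `mean_long_loop_count()` tracks the indirect rise of
long-range loops when short-range looping is depleted.

On the measurement side, `msd_vs_genomic()` aggregates probe-pair distance
tables (genomic distance in Mb, 3D distance in µm) into ⟨R²⟩-versus-g
profiles with per-point counts, and `radial_position()` computes the
normalised radial nuclear position p_n = r_o / r_n. The package does not
process images: tables of pre-measured distances are the input unit, with
segmentation and chromatic-aberration correction considered upstream steps.

## The synthetic probe-pair generator

`synthesize_fish_table()` bridges simulation and measurement-style data: for
each conformation and probe pair it converts contour separation to genomic
distance (Mb per monomer), scales lattice distances to µm, and adds
isotropic Gaussian localisation noise per axis (default SD 0.05 µm,
matching sub-50-nm localisation accuracy). With zero noise the table
reproduces simulated distances exactly — the unit round-trip the tests
assert; with noise, `E[R²]` picks up the `3 σ²` term the law of total
variance predicts. What the generator does *not* emulate: segmentation
failures, outlier mislocalisation, probe size (a BAC spans hundreds of kb,
not a point), chromatic offsets between channels, and cell-to-cell
variation in nuclear size. Tests passing on these tables therefore validate
the analysis arithmetic, not robustness to real microscopy artefacts.

## Numerical choices and degenerate inputs

* **SAW growth** places monomers sequentially with shuffled candidate bond
  vectors and restarts from scratch when trapped; repeated failure (dense
  lattice) is an explicit error, never a silent invalid state.
* **Event order within an MCS**: moves, clock increment, dissociations
  (expiry ≤ clock), then formation trials over a freshly shuffled candidate
  list. The shuffle makes saturation under `max_bonds_per_monomer` unbiased;
  a pair that stays proximal is re-tried every MCS.
* **Lifetimes are absolute expiry times**, not per-MCS decay trials; a
  `t_bond = 0` bond lives to the next MCS and then dissociates.
* **τ_ac fitting** needs ≥ 50 samples and a non-constant series, else it
  errors; a series that decorrelates within one interval reports `dt / 2`.
  The log-space fit is weighted by the squared correlation because the
  sampling noise of the autocorrelation is roughly lag-independent, making
  the variance of its logarithm blow up as the correlation decays.
* **Plateau estimator** errors rather than extrapolates when the profile
  stops short of 0.8 N.
* **RNG**: the C++ engine uses its own xoshiro256++ stream with a
  splitmix64-seeded state and hand-rolled Poisson samplers (Knuth below mean
  30, Hörmann's PTRS above), so trajectories are reproducible bit for bit
  across platforms regardless of C++ standard-library implementation
  details.

## Design decisions that were genuinely open

* **Monomer footprint.** Single-site monomers with point excluded volume
  would also give a self-avoiding chain, but the bond fluctuation method
  proper defines monomers as 2×2×2 cubes, and only that variant guarantees
  non-crossing in combination with this bond-vector set. The package
  implements the classic cubes; large-scale compaction trends should be
  robust to this choice.
* **Domain-mode linkers.** One reading lets any inter-domain pair loop at
  `p_long`; the stricter one allows long-range loops only *between looped
  domains*, leaving linkers inert. The package defaults to inert linkers and
  exposes `linkers_inert = FALSE` for the permissive reading.
* **Reduced-scale cutoff.** The short/long boundary generalises as 5% of
  the chain (50/1050), so test-scale chains of 105 monomers use a cutoff
  of 5.
* **Warm-up probability.** Unspecified; `(p_short + p_long) / 2` keeps the
  phase-1 state neutral between the two target regimes.

## Problem sizes used by the tests and analyses

The bundled checks run at N = 105 (and N = 200 for the scaling-limit check)
on an L = 64–96 lattice. The compaction-trend analyses equilibrate
5×10⁴ + 7×10⁵ MCS — the second phase spans roughly 90 bond lifetimes, which
stationarity diagnostics showed is needed for the short/long loop
composition to relax away from the warm-start state (shorter equilibrations
leave occasional expanded metastable states that dominate the plateau
variance) — and sample 60 conformations every 2.5×10³ MCS, with 5–8
independent seeds per parameter cell. At this reduced chain length the
plateau's response to `p_long` saturates above roughly 0.035, so the
trend analyses place their `p_long` cells in the responsive range
(0.02–0.035); the `p_short` response is resolvable across 0.02–0.05. These
sizes were chosen as the smallest at which the model's equilibrium trends
are statistically resolvable; they are far below the full-scale study
conditions, so quantitative plateau values are not comparable to full-scale
runs, only the directions and ratios of the responses are.

## Known limitations

* Chain lengths around 10³ monomers and the reduced test scale probe the
  mechanism, not chromosome-scale quantitative structure.
* Loop anchors are sequence-agnostic: no motif-positioned anchors, no
  energy-based (Metropolis-weighted) formation, no binder concentration
  field.
* The plateau at reduced N has large seed-to-seed variance (global
  conformation decorrelates slowly); trend tests therefore average over
  seeds and use resampling rather than point comparisons.
* No hydrodynamics, bending rigidity, or parallel tempering; full-scale
  runs are supported but compute-bound.
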
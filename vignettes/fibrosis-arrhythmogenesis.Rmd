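---
title: "Fibrosis texture, spatial entropy and ventricular arrhythmogenesis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibrosis texture, spatial entropy and ventricular arrhythmogenesis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

Myocardial fibrosis replaces working myocytes with poorly coupled,
electrically remodeled tissue. Both the *amount* of fibrosis and its
*spatial texture* — scattered single-site (diffuse), strand-like
(patchy), or dense scar-like (compact) — shape how electrical wavefronts
slow, fragment and re-enter. `fibroarrhythm` is a simulation pipeline
that makes this question quantitative on synthetic tissue sheets:

1. generate seeded binary fibrosis label maps of the three textures at
   exact fibrotic fractions (10–50%);
2. quantify each map's local fibrotic/normal intermingling with a
   Shannon *fibrosis entropy* (FE) and its tissue mean (MFE);
3. simulate monodomain action-potential propagation with a full human
   ventricular ionic model, with fibrotic-region ionic remodeling and
   reduced local conductivity;
4. induce reentry with an S1–S2 cross-field reset protocol, classify
   whether the induced activity is sustained across a conduction-velocity
   scan, and count phase singularities (PS) by topological charge;
5. aggregate (MFE, mean PS, sustainability) across an ensemble and
   correlate spatial disorder with electrical instability.

# The electrophysiological model

## Single cell

Each node carries the ten Tusscher–Panfilov 2006 human ventricular
myocyte model: 12 Hodgkin–Huxley-type gating variables, a ryanodine-
receptor adaptation variable, and ionic concentrations in the cytosol,
dyadic subspace and sarcoplasmic reticulum; the total membrane current
is the sum of twelve currents (I_Na, I_K1, I_to, I_Kr, I_Ks, I_CaL,
I_NaCa, I_NaK, I_pCa, I_pK, I_bCa, I_bNa). Parameter values are the
published epicardial set (endocardial and mid-myocardial variants are
selectable; the tissue model is epicardial throughout, since the study
design treats the tissue as electrically uniform apart from fibrosis).

Gates advance by the Rush–Larsen exponential update — an unconditionally
bounded contraction toward the voltage-dependent steady state — and the
membrane potential and concentrations by forward Euler. The default
`dt = 0.02` ms is standard for this model family; the paced APD90 at
this step differs from a `dt = 0.001` ms reference by about 0.1 ms
(`pace_single_cell()` reports APD90, maximal upstroke velocity and
calcium-transient amplitude per beat). The resting initial state is the
published one and is a fixed point to ≈ 0.06 mV of drift per second.

Stimuli are external current densities added to the membrane equation,
negative-depolarizing, default −52 pA/pF for 1 ms (a twice-threshold
convention).

## Fibrotic remodeling

Fibrotic-region myocytes keep full ionic machinery but are remodeled:
I_K1 reduced by 50%, I_CaL by 50%, I_Na by 40% (`fibrosis_remodeling()`);
local tissue conductivity is reduced by 30%. Measured single-cell
consequences at 600-ms pacing: APD90 292.7 → 256.6 ms and maximal upstroke
velocity 373 → 254 mV/ms. An alternative `obstacle_mode` treats fibrotic
nodes as non-conducting inclusions (classical percolation-style
fibrosis); it is *not* the default because the study's own model
description remodels rather than removes fibrotic cells.

## Tissue

Propagation follows the isotropic monodomain equation. Conductivity,
surface-to-volume ratio and membrane capacitance are lumped into one
scalar diffusion coefficient `D` (mm²/ms); absolute values are never
needed because `calibrate_diffusion()` pins the physiology: a secant
iteration (seeded by the cable-theory scaling CV ∝ √D) adjusts `D`
until a plane wave on a fibrosis-free 100×10 strip propagates at the
requested conduction velocity to within 1%. Space is discretized on a
regular grid (5-point Laplacian, no-flux boundaries, default
dx = 0.25 mm); inter-node edge diffusivities are harmonic means of the
node diffusivities (serial-resistance convention), which is also how the
30% fibrotic conductivity reduction enters. Operator splitting is
reaction-then-diffusion per step, and the explicit diffusion step is
guarded by the dt ≤ dx²/4D stability bound.

Two numerical notes. First, the ionic kernel used for tissue runs
tabulates all voltage-dependent gate steady states, Rush–Larsen decay
factors and current prefactors on a 0.05-mV lattice with linear
interpolation, and refreshes the slowly varying reversal potentials
every 16 steps; the table path agrees with the exact scalar evaluation
to sub-millivolt accuracy across a propagating upstroke and to ≈ 10⁻³ mV
elsewhere (this equivalence is a test). Second, at dx = 0.25 mm the
measured CV sits a few percent below a dx = 0.125 mm reference (the
suite measures both resolutions on the default strip) — ordinary
discretization bias for this model at this resolution. Because every
simulation is run at the same dx it is calibrated at, the bias cancels; quantities that compare CVs across different `D` (the √D
scaling check) are therefore measured in the resolved regime
(dx = 0.125 mm, dt = 0.005 ms).

# Fibrosis generation

All generators hit `round(amount × n_nodes)` fibrotic nodes exactly and
are fully determined by `(pattern, amount, seed, params, geometry)`;
seeding never perturbs the caller's RNG stream.

* **Diffuse** — uniform sampling without replacement.
* **Patchy** — the source study placed its strand-like regions manually;
  here a seeded procedural generator rasterizes near-parallel strands
  (one orientation per map ± 0.15 rad jitter, length 30–60 nodes,
  thickness 2, so length ≥ 5× thickness) and punches embedded normal
  nodes by keeping each strand node with probability `gap_fill = 0.85`,
  reproducing the "loosely interconnected myocytes" texture. Strands are
  added, and the last one trimmed, to the exact count.
* **Compact** — `n_clusters` (default 3) dense scar regions, each a
  filled, hole-free elliptical ball (random center, orientation, aspect
  ≤ 2) grown to its share of the target count; clusters are re-seeded if
  they would touch, so the fibrotic set has exactly `n_clusters`
  4-connected components.

`generate_ensemble()` with defaults reproduces the full study grid:
3 patterns × 5 amounts (10–50%) × 5 replicates = 75 maps, with per-map
seeds derived from one base seed and a CSV-ready manifest.

# Fibrosis entropy

For node *i*, `P_i` is the fraction of its neighbors (Moore
8-neighborhood by default; von Neumann selectable; grid nodes stand in
for the original study's tetrahedral-mesh elements) whose label differs
from node *i*'s. The published formula for FE is internally inconsistent
(its prose swaps the definitions of the symbols and the displayed form
averages only −P ln P), so the package defines local FE as the full
binary Shannon entropy

FE_i = −[P_i ln P_i + (1 − P_i) ln(1 − P_i)],  with 0 · ln 0 ≡ 0,

which realizes the stated intent (a bounded, label-flip-symmetric
measure of local intermingling, maximal at P = 1/2); the literal
one-term form is available as `fe_mode = "one_term"`. MFE averages over
all nodes (the study averaged over all nodes, and then over the five
replicates of each cell).

A consequence worth stating plainly: under *any* neighbor-disagreement
entropy, a uniformly random (diffuse) map sits near the maximum
(P ≈ 2f(1−f)), while dense hole-free scars score near zero away from
their perimeter. On this package's generators the group ordering at
equal amount is therefore diffuse > patchy > compact (e.g. at 30%:
0.54, 0.27, 0.04 nats), which is the *reverse* of the ordering the
source study reports for its manually constructed 3D maps. The
acceptance suite states the study's ordering as the expectation and
documents the discrepancy rather than redefining the metric to force
agreement; no local-disagreement statistic can rank dense compact scars
above uniform scatter at equal amount.

# Reentry induction and sustainability

`build_s1s2()` implements the cross-field protocol: three S1 stimuli at
600-ms cycle length on a 3-node-thick bottom-edge ("apex-analog")
strip; when the final wavefront first crosses −20 mV anywhere on the
mid-height sensing line — i.e. has traveled half way across the sheet —
every cell in the left half-domain is instantaneously restored to the
full resting state. (The full 19-variable state is reset, not the
membrane potential alone, to avoid nonphysical internal-state
gradients. The half-way trigger is the operationalization of the
study's "wavefront reached half of the ventricle".)

`detect_sustained()` classifies a run as sustained when the final
200 ms of the post-reset observation window still contains any snapshot
with spatial max Vm > −40 mV. The study observed 10 s post-reset at
full scale; the desk default window is 2 s, configurable. The 10-s
clock is started at the reset trigger. `cv_scan()` repeats induction
across a CV grid (default 53–100 cm/s in 3 cm/s steps, each CV pinned
by a fresh strip calibration) and reports the boolean grid and the
boundary of its sustained region.

## What desk-scale sheets can and cannot show

The reentrant wavelength at 79 cm/s is CV × APD90 ≈ 0.79 mm/ms ×
293 ms ≈ 23 cm — larger than any desk-scale 2D sheet. Empirically
(6–15 cm sheets, CV 25–79 cm/s): the reset creates a broken wavefront
that completes at most one reentrant loop before annihilating, and the
time-delay-embedding winding number records no persistent singularity,
because a broken front whose waveback is a full wavelength away carries
no complete phase cycle around its tip. A persistent free end would
need a domain of roughly twice the wavelength (~0.5 m of tissue). The
source study's sustained reentry lives on a 3D biventricular anatomy
whose circumferential path length exceeds the wavelength — geometry a
2D sheet cannot emulate. Consequently, at desk scale, sustained-reentry
and PS-burden comparisons against the study's figures are reported as
expectations that fail, with this analysis, rather than silently
rescaled; the machinery itself (induction, reset confinement, phase
winding, sustainability classification) is validated by analytic
oracles and by obstacle-mode simulations, in which dense non-conducting
fibrosis visibly fragments the wavefront into transient vortex pairs
that the detector counts.

# Phase analysis

Phases come from time-delay embedding,
θ_i(t) = atan2(Vm_i(t+τ) − V*, Vm_i(t) − V*), wrapped to (−π, π], with
τ = 6 ms and V* = −40 mV by default (τ must be a multiple of the
snapshot cadence; the defaults pair with the 2-ms cadence used in the
simulation profiles; only the method citation, not its parameters, is
fixed by the source study). A phase singularity is a 2×2 plaquette
around which the four wrapped phase differences sum to ±2π (tolerance
10⁻⁶); the charge is the sign. Ties at exactly π wrap to +π. Detection
is per frame; `mean_ps_count()` averages counts over frames sampled
every 10 ms without trajectory linking, matching a "mean number of PS"
readout. The detector satisfies the discrete Stokes identity (total
enclosed charge equals the boundary winding) exactly, which the suite
checks on random smooth fields, alongside closed-form vortex cases.

# Ensemble orchestration

`run_ensemble()` drives map → MFE → calibration → S1–S2 → PS/
sustainability for every (pattern, amount, replicate) cell, caches
per-run rows (and the shared strip calibration) on disk keyed by the
full run configuration so interrupted ensembles resume without
re-simulation, records per-run failures without aborting the ensemble,
and derives group aggregates plus per-pattern Pearson correlations
between per-model MFE and mean PS (pooled across amounts within each
pattern; correlations are only defined for ≥ 3 models with variance in
both coordinates). `write_report()` emits four byte-stable CSV tables:
MFE by pattern/amount, mean PS by pattern/amount, the sustainability
grid, and the correlation table.

The desk profile used by the acceptance artifacts is stated where it is
used: 96×96 nodes at dx = 0.6 mm, 30% fibrosis, one replicate per
pattern, CV 79 cm/s, 800-ms post-reset window. Recordings persist via R
serialization (`write_recording()`); activation maps and PS tables
export as CSV.

# Known limitations

* 2D sheets (and 3D slabs for generation/entropy only) replace the
  patient-specific ventricular mesh; anatomical reentry around cavities
  is out of reach, with the consequences described above.
* The electrical model is isotropic; fiber architecture is ignored.
* No mechanics: the pipeline's hand-off is the per-node calcium
  transient recording (`record_cai = TRUE`), suitable as input to an
  external contraction solver; stroke-volume analyses are out of scope.
* Restitution, alternans and ERP characterization are deliberately not
  part of the surface.
* The patchy generator is a procedural stand-in for manually drawn
  strands; only its qualitative texture, not the original maps, is
  reproducible.
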
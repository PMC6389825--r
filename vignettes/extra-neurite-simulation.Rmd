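---
title: "Simulating extra-neurite cellularity and its NODDI signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating extra-neurite cellularity and its NODDI signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

The orientation dispersion index (ODI) of the NODDI model was conceived to
quantify how dispersed neurite orientations are. But the extra-neurite
space is not empty: glia — microglia in particular — occupy it, and their
density changes dramatically during neuroinflammation. `noddimc` provides
the machinery to ask, *in silico*, whether ODI responds to the density of
cells in the extra-neurite space even when the neurites themselves do not
disperse at all, and to analyze depletion–repopulation experiments in which
microglial density is manipulated pharmacologically (CSF1R inhibition)
while ODI is measured.

The package chains four stages, each usable on its own:

1. **substrate** — a periodic 40 µm voxel containing a coherent bundle of
   six undulating cylinders (axons) and 0–25 impermeable spheres of radius
   5 µm (microglia) placed at random in the extra-neurite space;
2. **random walk** — lattice-free Monte Carlo diffusion with elastic
   specular reflection at all membranes;
3. **acquisition** — virtual pulsed-gradient spin-echo (PGSE) signals for a
   two-shell NODDI protocol, with Gaussian noise at SNR 50;
4. **models and statistics** — from-scratch NODDI and diffusion-tensor
   fitting, Kendall's tau-b, pooled t tests, and particle counting, plus
   seeded synthetic-data generators for every input.

## Geometry

Each axon is a cylinder of radius 1 µm whose centerline is displaced
sinusoidally along x: `x(z) = A sin(2 pi z / P)` with amplitude A = 2 µm
and exactly one period over the 40 µm voxel (P = 40 µm). The arc length of
one period divided by the straight length defines the undulation ratio
λ; numerical quadrature gives λ = 1.024 for this geometry
(`undulation_ratio(2, 40)`). The period is chosen so that the printed
λ emerges from the stated amplitude, and an integer number of periods
makes the periodic boundary seamless. All six cylinders undulate in phase
on a hexagonal lattice (pitch 13 µm, two rows of three — the widest pitch
that keeps the bundle, including its 3 µm lateral excursion, inside the
voxel), so the non-touching condition reduces to a constant offset check.
There is no orientation dispersion by construction: any nonzero fitted ODI
is contributed by the geometry of the extra-neurite space, which is the
point of the experiment.

Cell bodies are analytic spheres of radius 5 µm. Mesh icospheres in the
original rendering pipeline are a faceting of the same shape, so collision
and classification mathematics use the exact sphere. Spheres are placed by
rejection sampling (10,000 attempts per sphere), never overlapping each
other or the cylinders, wholly inside the voxel, and with their surfaces
kept 0.5 µm clear of the periodic wrap planes so a reflection and a wrap
can never occur within one 0.13 µm step.

Cylinder membership uses the implicit surface
`sqrt((x - A sin(2 pi z / P))^2 + y^2) = r`, i.e. a circular cross-section
in the plane perpendicular to the main axis rather than to the local
centerline. This gives exact, smooth normals for reflection; at the
working undulation slope (2πA/P ≈ 0.31) the shape differs from a true tube
by a few percent of the radius at the steepest points.

With this geometry the axon bundle occupies ≈1.2% of the voxel and 5/15/25
spheres occupy ≈4.1/12.3/20.5%. Printed occupancy figures elsewhere
(2.7% for the bundle; up to 31.5% for spheres) are mutually proportional
but cannot be reconciled with radius-1 µm cylinders and radius-5 µm
spheres in a 40³ µm³ box; the package implements the stated geometry and
reports its own Monte Carlo fractions (`volume_fractions()`).

## The random walk

Spins take fixed-length steps `sqrt(6 d dt)` in uniformly random 3-D
directions — the standard lattice-free scheme of Monte Carlo diffusion
simulators — with free diffusivity d = 0.6e-9 m²/s and, at study scale,
100,000 spins and 5,000 steps. The walk duration equals the echo time
(24.17 ms), so dt ≈ 4.83 µs and each step is ≈0.13 µm. Membranes are
fully impermeable (the model's non-exchanging assumption): a step crossing
a surface is reflected specularly, repeatedly if necessary (budget 10,
then the step is rejected and counted), which preserves step-length
statistics near walls. Compartment conservation is asserted in the test
suite at every recorded time point.

Spins are initialized uniformly over the whole voxel, so intra-axonal,
intra-sphere and extracellular water all contribute to the ensemble
signal in proportion to their volume; `extra_only` initialization is
available. Periodic boundaries wrap only the membership test — positions
are kept unwrapped so phase accrual never sees a spurious jump.

`simulate_walk()` records full trajectories (memory-bound; for tests and
small studies). `simulate_dwi()` fuses the walk with phase accumulation
and needs only O(n_spins) memory at identical draws, which is how
study-scale runs are executed.

## Signal synthesis and noise

The two rectangular gradient lobes (δ = 4 ms, Δ = 12 ms by default —
timings chosen to fit inside TE = 24.17 ms and exposed as arguments) are
placed symmetrically about the virtual 180° pulse; the second lobe carries
the flipped effective polarity. Phase is accrued by the discrete sum
`phi = gamma Σ_k g(t_k) · x(t_k) dt` (finite-pulse, piecewise-constant
gradient — the narrow-pulse approximation is not used since δ is not
small against Δ), and the measurement signal is the magnitude of the
ensemble mean of `exp(i phi)`, exactly 1 at b = 0. Per-shell directions
come from a deterministic electrostatic-repulsion optimization, and
gradient amplitudes are solved from `b = gamma² G² δ² (Δ − δ/3)`; the test
suite checks the back-substitution to 1e-6.

Noise is zero-mean Gaussian on the magnitude signal with
σ = mean(b0)/SNR at SNR 50, as quoted relative to the b = 0 signal. A
Rician channel is not simulated; at SNR 50 the difference is far below
the effects of interest.

## NODDI and tensor fitting

The tissue signal mixes Watson-dispersed sticks (fraction `v_ic`,
concentration κ, orientation μ) with an extracellular zeppelin whose
perpendicular diffusivity follows the tortuosity rule
`d_perp = d_par (1 − v_ic)`; free water attenuates as `exp(−b d_iso)`; and
the ex-vivo variant nests a non-attenuating, isotropically restricted
fraction `v_dot` inside the tissue term:
`S = (1 − v_iso)((1 − v_dot)(v_ic S_ic + (1 − v_ic) S_ec) + v_dot) +
v_iso S_iso`. `ODI = (2/π) atan(1/κ)`. Fixed diffusivities default to
`d_par = 0.6e-9` m²/s (the simulation's free diffusivity, appropriate for
fixed tissue) and `d_iso = 2.0e-9` m²/s; both are arguments, since the
presets used by any particular toolbox installation are not recoverable.

Watson spherical means reduce, by axial symmetry, to a one-dimensional
integral with a Bessel-I₀ kernel that is evaluated by Gauss–Legendre
quadrature with the large eigenvalue factored out, making the ratio stable
for κ up to ~10³ (and the density itself for κ ≤ 128). Exported functions
default to 1001 nodes; the fitter uses 201, which agrees with 4001-node
references to ~1e-14 over the κ range reachable during fitting — the
quadrature order is not the accuracy bottleneck anywhere.

Fitting is deterministic two-stage least squares: a coarse grid over
`v_ic` (10 values) × ODI (10) × `v_iso` (5) (× `v_dot` (5), ex-vivo), with
μ seeded from the principal eigenvector of a low-b tensor fit and ties
broken by lowest residual then lowest `v_iso`; then Nelder–Mead refinement
(fixed iteration cap) of all free parameters under logit/angle transforms
that enforce the bounds. A derivative-free simplex was chosen over a
quasi-Newton scheme because the objective is cheap but its numerical
gradient would multiply the cost sevenfold per iteration for no accuracy
gain in practice.

Noise-free self-consistency recovers ODI to better than 0.02 across a
27-point grid, and the mean recovered ODI over 100 SNR-50 replicates stays
within 0.05 of truth (both asserted in the test suite). These round trips
use the matched (in-vivo, `v_dot = 0`) variant: on signals that contain no
restricted isotropic water the dot compartment is nearly degenerate with
high dispersion at this b-range, which is a known identifiability limit of
the ex-vivo model, not a fitting defect. The sweep over sphere counts fits
the ex-vivo variant, matching the preprocessing of the experiment it
emulates.

The tensor is fitted by weighted linear least squares on `ln S` (one OLS
pass, one reweighting by the squared predicted signal), by default on
b = 0 and the 800 s/mm² shell only to limit non-Gaussian bias; negative
noisy signals are clamped at 1e-6 before the log, and eigenvalues are
clamped at zero for the FA/MD summaries.

## The sphere-count experiment

`run_sweep()` ties the stages together: for each (count, repetition) cell
it derives a seed from `base_seed`, places the spheres, runs the fused
walk + acquisition, adds SNR-50 noise, and fits both models, recording
every seed alongside the results. At study scale (counts 0/5/15/25, 10
repetitions, 100,000 spins) the mean fitted ODI rises with sphere count,
and the dispersion-free bundle alone already yields nonzero ODI. The test
suite asserts the directional claim at a desk scale of 10,000 spins, 5,000
steps and 3 repetitions of the extreme conditions (0 vs 25 spheres), where
the effect is already far larger than the repetition scatter; the absolute
box-plot values of the original figure are figure-only quantities and are
not asserted anywhere.

## Synthetic study data

The repopulation generator emulates the design of a CSF1R
depletion–repopulation experiment: two arms (control / treated) × days
0, 1, 3, 7 post-withdrawal × 6 animals. Treated microglial counts are
drawn at declared fractions of the control mean (0.02, 0.15, 0.5, 0.95 by
day — values chosen once so that the qualitative significance pattern of
such experiments emerges: days 1–3 clearly depleted, day 7
indistinguishable from control), neurons and astrocytes carry no day
effect, and mean ODI couples linearly to count
(`ODI = 0.45 + 2.5e-4 (count − 300) + N(0, 0.015)`). The linear-Gaussian
coupling is the weakest structure sufficient for a rank-correlation
analysis; none of these numbers are claims about any real data set, whose
per-animal distributions are not recoverable from published figures. The
real-data correlation printed in that literature (τ = 0.386) is likewise
not a target: only the sign and significance pattern are.

Cell-field images are non-overlapping bright discs on Gaussian background
noise — enough structure for threshold-and-count validation, with no
attempt at PSF blur, ramified morphology, or intensity variation. Passing
particle-count tests therefore validates the counting operation, not
robustness to real microscopy artifacts.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is bit-reproducible;
sweeps derive per-cell seeds so any row can be regenerated in isolation.
The test suite runs the free-diffusion calibration at the full study scale
(100,000 spins × 5,000 steps, recovering MD within 2% with FA < 0.02) and
the sphere sweep at the desk scale above; fitter-recovery experiments use
the full 85-measurement scheme. Trajectory-recording runs in tests are
kept to a few hundred spins; statistical calibrations use 100–200 seeded
draws.

## Known limitations

* The voxel is small (40 µm) and contains a single coherent bundle at
  ≈1.2% volume fraction — far leaner than real white matter; absolute
  fitted parameters should not be read as tissue values.
* Membranes are impermeable and relaxation is ignored; no exchange, T2
  weighting, or surface relaxivity.
* Cylinder cross-sections are defined perpendicular to the bundle axis
  (see Geometry), a small-slope approximation of a true tube.
* The ex-vivo dot compartment is weakly identified at b ≤ 2000 s/mm² with
  d_par = 0.6e-9 m²/s; its estimates scatter even on clean signals.
* Gaussian (not Rician) noise, rectangular gradient lobes, and idealized
  timing; no imaging artifacts of any kind.
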
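# noddimc

Monte Carlo diffusion MRI simulation and NODDI fitting for studying how
cell density in the **extra-neurite space** shapes multi-compartment
diffusion measures.

## The scientific problem

Multi-compartment diffusion MRI models describe the measured signal as a
mixture of compartment signals,

    S = S0 * sum_i w_i S_i ,

and NODDI in particular as three non-exchanging pools,

    S = (1 - v_iso) * (v_ic * S_ic + (1 - v_ic) * S_ec) + v_iso * S_iso ,

with Watson-dispersed intra-neurite sticks (`S_ic`), a tortuous
extracellular Gaussian (`S_ec`, perpendicular diffusivity
`d_par * (1 - v_ic)`), and free water (`S_iso`). The orientation
dispersion index `ODI = (2/pi) * atan(1/kappa)` summarizes the Watson
concentration `kappa`. ODI was designed to measure neurite dispersion —
but the extra-neurite space also contains glia, and microglia change
density dramatically during neuroinflammation. This package provides
everything needed to test, in silico, whether ODI responds to
extra-neurite cellularity even with perfectly coherent axons, and to
analyze depletion–repopulation experiments where microglial density is
the manipulated variable:

* a periodic tissue voxel of hexagonally packed **undulating cylinders**
  (axons; radius 1 µm, undulation amplitude 2 µm, path-length ratio
  λ = 1.024) plus randomly placed impermeable **spheres** (microglia,
  radius 5 µm);
* a compiled lattice-free **Monte Carlo walker** (fixed steps
  `sqrt(6 d dt)`, elastic specular reflection, periodic boundaries);
* virtual **PGSE signal synthesis** for a two-shell NODDI protocol
  (10 b = 0, 25 directions at b = 800 s/mm², 50 at b = 2000 s/mm²,
  TE = 24.17 ms) with Gaussian noise at SNR 50 of the b = 0 signal;
* from-scratch **NODDI** (in-vivo and ex-vivo variants, the latter with an
  isotropically restricted "dot" fraction) and **DTI** (FA/MD) fitting;
* the study statistics — **Kendall's tau-b** (exact p for small untied
  samples), pooled two-tailed **t tests**, threshold-and-count
  **particle counting** — and seeded **synthetic-data generators** for
  DWI truth sets, repopulation tables, and cell images.

Intended users: researchers in diffusion-microstructure imaging and
neuroinflammation who want a transparent, fully reproducible substitute
for the usual simulator + toolbox pipeline.

## Worked example

Simulate the densest condition of the sphere sweep — 25 microglia-sized
spheres among six coherent axons — and fit both models:

```r
library(noddimc)

substrate   <- wm_substrate()        # 6 undulating axons in a 40 um voxel
substrate25 <- place_spheres(substrate, 25, radius = 5, rng_seed = 1)
substrate25
#> <substrate_spec> voxel 40 um, 6 cylinder(s), 25 sphere(s), d = 6e-10 m^2/s
round(volume_fractions(substrate25, n_samples = 2e5, rng_seed = 1), 4)
#> intra_cylinder   intra_sphere          extra
#>         0.0115         0.2051         0.7834

scheme <- make_noddi_scheme()        # 10 b0 + 25 @ b800 + 50 @ b2000
cfg    <- walk_config(n_spins = 20000, n_steps = 5000, rng_seed = 7)
sim    <- simulate_dwi(substrate25, cfg, scheme)   # fused walk + acquisition
signal <- add_noise(sim$signal, scheme, snr = 50, rng_seed = 8)

fit_noddi(signal, scheme, variant = "ex_vivo")
#> <noddi_params> v_ic = 0.138, ODI = 0.479 (kappa = 1.07), v_iso = 0.000, v_dot = 0.000
#>   mu = (0.252, -0.247, 0.936), d_par = 6e-10, d_iso = 2e-09 m^2/s
fit_dti(signal, scheme)
#> <tensor_fit> MD = 4.739e-10 m^2/s, FA = 0.0742
```

The fitted ODI of 0.48 comes from a substrate whose axons have *zero*
orientation dispersion: crowding of the extra-neurite space alone drives
it. The same pipeline on the sphere-free substrate returns ODI ≈ 0.14
(nonzero, but far lower), which is the directional effect the in-silico
experiment is designed to expose; `run_sweep()` automates the full
(0/5/15/25 spheres × repetitions) grid with per-cell derived seeds. MD
sits below the free diffusivity (6e-10 m²/s) because a fifth of the water
is trapped in spheres.

The methods vignette (`vignettes/extra-neurite-simulation.Rmd`) documents
the geometry, the walker, the fitting machinery, all fixture parameters,
and known limitations.

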
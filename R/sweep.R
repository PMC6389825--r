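#' Run the sphere-count sweep: simulate, acquire, fit
#'
#' For each (sphere count, repetition) pair: place spheres in the base
#' substrate with a derived seed, run the fused Monte Carlo walk + PGSE
#' acquisition, add Gaussian noise at the requested SNR, and fit both the
#' NODDI model and the diffusion tensor. The defaults reproduce the study
#' conditions: 0/5/15/25 spheres of radius 5 um, 10 repetitions each,
#' 100,000 spins and 5,000 steps per run, SNR 50.
#'
#' Seeds are derived deterministically from `base_seed` (one offset per
#' condition-repetition cell, with fixed sub-offsets for placement, walk
#' and noise), so an identical call reproduces the table bit for bit.
#'
#' @param base_substrate substrate holding the axon bundle (no spheres),
#'   e.g. [wm_substrate()].
#' @param sphere_counts integer vector of sphere counts.
#' @param reps repetitions per count.
#' @param config a [walk_config()]; its `rng_seed` is overridden per run.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @param snr signal-to-noise ratio for [add_noise()] (`Inf` = noise-free).
#' @param sphere_radius sphere radius, um.
#' @param base_seed integer; root of the derived seed tree.
#' @param variant NODDI variant passed to [fit_noddi()].
#' @return data frame of class `sweep_result` with one row per run:
#'   `sphere_count`, `repetition`, `seed`, `odi`, `fa`, `md`, `v_ic`,
#'   `v_iso`, `v_dot`, `n_rejected`.
#' @export
run_sweep <- function(base_substrate, sphere_counts = c(0, 5, 15, 25),
                      reps = 10, config = walk_config(),
                      scheme = make_noddi_scheme(), snr = 50,
                      sphere_radius = 5, base_seed = 1,
                      variant = "ex_vivo") {
  rows <- list()
  cell <- 0L
  for (cnt in sphere_counts) {
    for (rep_i in seq_len(reps)) {
      cell <- cell + 1L
      seed <- base_seed + 1000L * (cell - 1L)
      sub <- place_spheres(base_substrate, cnt, radius = sphere_radius,
                           rng_seed = seed)
      cfg <- config
      cfg$rng_seed <- seed + 1L
      sim <- simulate_dwi(sub, cfg, scheme)
      sig <- add_noise(sim$signal, scheme, snr = snr, rng_seed = seed + 2L)
      nfit <- fit_noddi(sig, scheme, variant = variant,
                        d_par = base_substrate$diffusivity)
      tfit <- fit_dti(sig, scheme)
      rows[[cell]] <- data.frame(
        sphere_count = cnt, repetition = rep_i, seed = seed,
        odi = nfit$odi, fa = tfit$fa, md = tfit$md,
        v_ic = nfit$v_ic, v_iso = nfit$v_iso, v_dot = nfit$v_dot,
        n_rejected = sim$n_rejected)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
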
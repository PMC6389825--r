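#' Random-walk configuration
#'
#' Settings for the lattice-free Monte Carlo walk: fixed-length steps of
#' `sqrt(6 * d * dt)` in uniformly random 3-D directions with elastic
#' specular reflection off impermeable membranes. The defaults follow the
#' in-silico study conditions: 100,000 spins, 5,000 time steps, and a total
#' walk duration equal to the virtual sequence's echo time (24.17 ms).
#'
#' @param n_spins number of random walkers (>= 1).
#' @param n_steps number of time steps (>= 1).
#' @param total_time walk duration, s; equals the echo time of the virtual
#'   PGSE sequence so every recorded step can contribute phase.
#' @param rng_seed integer seed; governs spin initialization and every step
#'   direction, so runs are bit-reproducible.
#' @param initialization `"uniform_voxel"` seeds spins uniformly over the
#'   whole voxel (all compartments contribute to the ensemble signal);
#'   `"extra_only"` restricts starts to the extra-cellular space.
#' @param max_reflect reflection budget per step; a step needing more
#'   reflections is rejected and the spin stays put.
#' @return object of class `walk_config`.
#' @export
walk_config <- function(n_spins = 1e5, n_steps = 5000,
                        total_time = 24.17e-3, rng_seed = 1,
                        initialization = c("uniform_voxel", "extra_only"),
                        max_reflect = 10) {
  stopifnot(n_spins >= 1, n_steps >= 1, total_time > 0)
  structure(list(n_spins = as.integer(n_spins),
                 n_steps = as.integer(n_steps),
                 total_time = total_time,
                 rng_seed = as.integer(rng_seed),
                 initialization = match.arg(initialization),
                 max_reflect = as.integer(max_reflect)),
            class = "walk_config")
}

# the walker's geometry kernels assume the canonical frame
check_canonical <- function(substrate) {
  for (cyl in substrate$cylinders) {
    if (any(abs(cyl$axis - c(0, 0, 1)) > 1e-9) ||
        any(abs(cyl$plane_normal - c(0, 1, 0)) > 1e-9))
      stop("simulation requires cylinders with axis +z and undulation in ",
           "the x-z plane")
    if (abs(cyl$length - substrate$voxel_edge) > 1e-9)
      stop("simulation requires cylinder length equal to the voxel edge ",
           "(periodic continuation)")
    n_per <- cyl$length / cyl$period
    if (abs(n_per - round(n_per)) > 1e-9)
      stop("undulation period must divide the cylinder length for a ",
           "seamless periodic geometry")
  }
  invisible(TRUE)
}

#' Initialize spin positions and compartment labels
#'
#' @param substrate a [substrate_spec()].
#' @param config a [walk_config()].
#' @return list with `positions` (n x 3 matrix, um) and `labels` (integer
#'   compartment codes: 0 extra, 1..n_cyl per cylinder, then per sphere)
#'   plus `compartment` (factor as in [classify_point()]).
#' @export
initialize_spins <- function(substrate, config) {
  g <- as_geom(substrate)
  n <- config$n_spins
  pos <- withr::with_seed(config$rng_seed, {
    p <- matrix(runif(3 * n, 0, substrate$voxel_edge), ncol = 3)
    if (config$initialization == "extra_only") {
      repeat {
        code <- classify_cpp(p, g$cyl, g$sph, g$edge)
        bad <- which(code != 0)
        if (length(bad) == 0) break
        p[bad, ] <- matrix(runif(3 * length(bad), 0, substrate$voxel_edge),
                           ncol = 3)
      }
    }
    p
  })
  code <- classify_cpp(pos, g$cyl, g$sph, g$edge)
  ncyl <- nrow(g$cyl)
  lab <- ifelse(code == 0, "extra",
                ifelse(code <= ncyl, "intra_cylinder", "intra_sphere"))
  list(positions = pos, labels = code,
       compartment = factor(lab, levels = COMPARTMENTS))
}

# shared driver behind simulate_walk() and simulate_dwi(); wsign is the
# per-time-point PGSE gradient polarity (NULL -> no phase accumulation)
walk_driver <- function(substrate, config, wsign = NULL, record = FALSE) {
  check_canonical(substrate)
  g <- as_geom(substrate)
  dt <- config$total_time / config$n_steps
  step_len_um <- sqrt(6 * substrate$diffusivity * dt) * 1e6
  init <- initialize_spins(substrate, config)
  accumulate <- !is.null(wsign)
  if (accumulate) stopifnot(length(wsign) == config$n_steps + 1)
  res <- withr::with_seed(config$rng_seed + 1L,
    walk_cpp(g$cyl, g$sph, g$edge, init$positions, init$labels,
             config$n_steps, step_len_um, config$max_reflect, record,
             if (accumulate) as.numeric(wsign) else numeric(0), accumulate))
  list(init = init, res = res, dt = dt, step_len_um = step_len_um)
}

#' Simulate spin diffusion through a substrate
#'
#' Runs the Monte Carlo walk and records every spin's unwrapped position at
#' every time step. Memory grows as `n_spins * (n_steps + 1) * 3` doubles;
#' for study-scale runs (100,000 spins, 5,000 steps) use [simulate_dwi()],
#' which accumulates gradient phase on the fly instead of storing paths.
#'
#' @param substrate a [substrate_spec()].
#' @param config a [walk_config()].
#' @return object of class `trajectory_ensemble`: a list with `positions`
#'   (array `n_spins x (n_steps + 1) x 3`, um, unwrapped so periodic wraps
#'   never inject jumps), `dt` (s), `labels`/`compartment` at t = 0, the
#'   substrate, and `n_rejected` (steps rejected after the reflection
#'   budget).
#' @export
simulate_walk <- function(substrate, config) {
  out <- walk_driver(substrate, config, wsign = NULL, record = TRUE)
  pos <- array(out$res$traj,
               dim = c(config$n_spins, config$n_steps + 1L, 3L))
  structure(list(positions = pos, dt = out$dt,
                 labels = out$init$labels,
                 compartment = out$init$compartment,
                 substrate = substrate, config = config,
                 n_rejected = out$res$n_rejected),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "<trajectory_ensemble> %d spins x %d steps, dt = %.3g s, %d rejected step(s)\n",
    d[1], d[2] - 1L, x$dt, x$n_rejected))
  invisible(x)
}

#' Mean squared displacement of a trajectory ensemble
#'
#' @param traj a [simulate_walk()] result.
#' @param spins optional index vector restricting the ensemble.
#' @return numeric vector of MSD (um^2) at each recorded time point.
#' @export
msd <- function(traj, spins = NULL) {
  pos <- traj$positions
  if (!is.null(spins)) pos <- pos[spins, , , drop = FALSE]
  disp2 <- (pos - pos[, rep(1, dim(pos)[2]), , drop = FALSE])^2
  apply(disp2, 2, function(m) mean(rowSums(matrix(m, ncol = 3))))
}
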
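#' Stejskal-Tanner b-value for rectangular gradient lobes
#'
#' `b = gamma^2 G^2 delta^2 (Delta - delta / 3)`, returned in s/mm^2.
#'
#' @param G gradient amplitude, T/m.
#' @param delta pulse width, s.
#' @param Delta pulse separation, s.
#' @return b-value, s/mm^2.
#' @export
stejskal_tanner_b <- function(G, delta, Delta) {
  GAMMA_H^2 * G^2 * delta^2 * (Delta - delta / 3) * 1e-6
}

#' Gradient amplitude that realizes a requested b-value
#'
#' @param b b-value, s/mm^2.
#' @inheritParams stejskal_tanner_b
#' @return gradient amplitude G, T/m.
#' @export
g_from_b <- function(b, delta, Delta) {
  sqrt(b * 1e6 / (GAMMA_H^2 * delta^2 * (Delta - delta / 3)))
}

#' Evenly spread gradient directions by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of `n` antipodally symmetric point pairs on
#' the unit sphere by projected gradient descent from a deterministic
#' Fibonacci-spiral start, so the same `n` always yields the same table.
#'
#' @param n number of directions (>= 1).
#' @param n_iter descent iterations.
#' @param step_size descent step.
#' @return n x 3 matrix of unit direction vectors.
#' @export
electrostatic_directions <- function(n, n_iter = 400, step_size = 0.005) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n                     # upper hemisphere start (antipodal sym)
  s <- sqrt(pmax(0, 1 - z^2))
  x <- cbind(s * cos(phi), s * sin(phi), z)
  if (n == 1) return(x)
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    for (sgn in c(1, -1)) {
      dx <- outer(x[, 1], sgn * x[, 1], "-")
      dy <- outer(x[, 2], sgn * x[, 2], "-")
      dz <- outer(x[, 3], sgn * x[, 3], "-")
      r3 <- pmax(dx^2 + dy^2 + dz^2, 1e-12)^1.5
      diag(r3) <- Inf                 # no self / self-antipode force
      frc <- frc + cbind(rowSums(dx / r3), rowSums(dy / r3),
                         rowSums(dz / r3))
    }
    x <- x + step_size * frc
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' Build a two-shell NODDI acquisition scheme
#'
#' Generates the virtual PGSE scheme: `n_b0` non-diffusion-weighted
#' measurements plus one electrostatically spread direction set per shell.
#' Gradient amplitudes are solved from the requested b-value and the pulse
#' timing; the defaults reproduce the ex-vivo protocol (10 b = 0 images, 25
#' directions at b = 800 s/mm^2, 50 at b = 2000 s/mm^2, TE = 24.17 ms).
#'
#' @param n_b0 number of b = 0 measurements.
#' @param shells list of `c(b_value, n_directions)` pairs (b in s/mm^2).
#' @param delta gradient pulse width, s.
#' @param Delta gradient pulse separation, s.
#' @param TE echo time, s; the two lobes are placed symmetrically about the
#'   virtual 180-degree pulse at TE/2.
#' @return data frame of class `acquisition_scheme` with one row per
#'   measurement: `bval` (s/mm^2), unit direction `gx, gy, gz`, amplitude
#'   `G` (T/m), `delta`, `Delta`, `TE` (s), and `shell` (0 for b = 0).
#' @export
make_noddi_scheme <- function(n_b0 = 10,
                              shells = list(c(800, 25), c(2000, 50)),
                              delta = 4e-3, Delta = 12e-3, TE = 24.17e-3) {
  if (delta <= 0 || Delta <= 0 || delta >= Delta)
    stop("need 0 < delta < Delta")
  if (delta + Delta > TE)
    stop("infeasible timing: delta + Delta exceeds TE")
  rows <- list()
  if (n_b0 > 0) {
    rows[[1]] <- data.frame(bval = 0, gx = 0, gy = 0, gz = 1, G = 0,
                            delta = delta, Delta = Delta, TE = TE,
                            shell = 0L)[rep(1, n_b0), ]
  }
  for (k in seq_along(shells)) {
    b <- shells[[k]][1]
    nd <- shells[[k]][2]
    stopifnot(nd >= 1, b > 0)
    dirs <- electrostatic_directions(nd)
    rows[[length(rows) + 1]] <- data.frame(
      bval = b, gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
      G = g_from_b(b, delta, Delta), delta = delta, Delta = Delta, TE = TE,
      shell = k)
  }
  scheme <- do.call(rbind, rows)
  rownames(scheme) <- NULL
  class(scheme) <- c("acquisition_scheme", "data.frame")
  scheme
}

# effective gradient polarity (+1 / -1 / 0, sign already flipped for the
# 180-degree pulse) at each recorded walk time point t_k = k * dt
pgse_weights <- function(delta, Delta, TE, dt, n_steps) {
  if (TE > dt * n_steps + 1e-12)
    stop("trajectory duration is shorter than the echo time")
  t <- (0:n_steps) * dt
  s1 <- (TE - Delta - delta) / 2
  s2 <- s1 + Delta
  w <- numeric(n_steps + 1)
  w[t >= s1 & t < s1 + delta] <- 1
  w[t >= s2 & t < s2 + delta] <- -1
  w
}

# scheme rows must share pulse timing for the single-pass phase accumulator
check_uniform_timing <- function(scheme) {
  if (length(unique(scheme$delta)) > 1 ||
      length(unique(scheme$Delta)) > 1 || length(unique(scheme$TE)) > 1)
    stop("all measurements must share delta/Delta/TE")
  invisible(TRUE)
}

# phases (n_spins x n_meas) from per-spin weighted position sums T (um)
phases_from_T <- function(Tsum, scheme, dt) {
  dirs <- as.matrix(scheme[, c("gx", "gy", "gz")])
  proj <- Tsum %*% t(dirs)                       # um
  sweep(proj, 2, GAMMA_H * scheme$G * dt * 1e-6, "*")
}

signal_from_phases <- function(phases) {
  apply(phases, 2, function(ph)
    sqrt(mean(cos(ph))^2 + mean(sin(ph))^2))
}

#' Synthesize the PGSE signal from recorded spin trajectories
#'
#' Accumulates, per spin and measurement, the phase
#' `phi = gamma * sum_k g(t_k) . x(t_k) * dt` over the two rectangular
#' gradient lobes (polarity flipped after the virtual 180-degree pulse at
#' TE/2) using unwrapped coordinates, and returns the magnitude of the
#' ensemble-average transverse magnetization. b = 0 measurements return
#' exactly 1.
#'
#' @param traj a [simulate_walk()] result.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @param spins optional index vector restricting the ensemble (e.g. to one
#'   compartment's spins).
#' @return numeric vector of normalized signals, one per measurement.
#' @export
synthesize_signal <- function(traj, scheme, spins = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  check_uniform_timing(scheme)
  n_steps <- dim(traj$positions)[2] - 1L
  w <- pgse_weights(scheme$delta[1], scheme$Delta[1], scheme$TE[1],
                    traj$dt, n_steps)
  pos <- traj$positions
  if (!is.null(spins)) pos <- pos[spins, , , drop = FALSE]
  n <- dim(pos)[1]
  Tsum <- vapply(1:3, function(c3)
    as.numeric(matrix(pos[, , c3], nrow = n) %*% w), numeric(n))
  if (n == 1) Tsum <- matrix(Tsum, nrow = 1)
  signal_from_phases(phases_from_T(Tsum, scheme, traj$dt))
}

#' Simulate diffusion and synthesize the DWI signal in one pass
#'
#' Fused walker + acquisition: gradient phase is accumulated while the
#' spins diffuse, so study-scale runs (100,000 spins x 5,000 steps) need
#' only O(n_spins) memory. Identical seeds give the same walk as
#' [simulate_walk()] followed by [synthesize_signal()].
#'
#' @param substrate a [substrate_spec()].
#' @param config a [walk_config()]; `total_time` must be >= the scheme TE.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @return list with `signal` (noise-free normalized signal per
#'   measurement), `signal_by_compartment` (matrix, one column per
#'   compartment present at t = 0), `n_spins_by_compartment`,
#'   and `n_rejected`.
#' @export
simulate_dwi <- function(substrate, config, scheme) {
  check_uniform_timing(scheme)
  dt <- config$total_time / config$n_steps
  w <- pgse_weights(scheme$delta[1], scheme$Delta[1], scheme$TE[1],
                    dt, config$n_steps)
  out <- walk_driver(substrate, config, wsign = w, record = FALSE)
  phases <- phases_from_T(out$res$T, scheme, dt)
  comp <- out$init$compartment
  by_comp <- sapply(levels(comp)[table(comp) > 0], function(lv)
    signal_from_phases(phases[comp == lv, , drop = FALSE]))
  list(signal = signal_from_phases(phases),
       signal_by_compartment = by_comp,
       n_spins_by_compartment = table(comp),
       n_rejected = out$res$n_rejected)
}

#' Add Gaussian measurement noise scaled to an SNR target
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `mean(b0 signal) / snr` to every measurement, the convention used when
#' quoting SNR relative to the non-diffusion-weighted signal.
#'
#' @param signal numeric vector of signals.
#' @param scheme the matching acquisition scheme (identifies b = 0 rows).
#' @param snr signal-to-noise ratio (> 0); `Inf` returns the input.
#' @param rng_seed integer seed.
#' @return noisy signal vector.
#' @export
add_noise <- function(signal, scheme, snr = 50, rng_seed = 1) {
  stopifnot(length(signal) == nrow(scheme), all(is.finite(signal)), snr > 0)
  if (!is.finite(snr)) return(signal)
  sigma <- mean(signal[scheme$bval == 0]) / snr
  signal + withr::with_seed(rng_seed, rnorm(length(signal), 0, sigma))
}

#' Write / read an acquisition scheme as FSL bval + bvec files
#'
#' @param scheme an acquisition scheme.
#' @param bval_path,bvec_path output (or input) file paths.
#' @return `write_scheme_fsl` returns the paths invisibly;
#'   `read_scheme_fsl` returns a list with `bvals` and a 3 x n `bvecs`
#'   matrix.
#' @export
write_scheme_fsl <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(scheme$bval, collapse = " "), bval_path)
  m <- t(as.matrix(scheme[, c("gx", "gy", "gz")]))
  writeLines(apply(m, 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_scheme_fsl
#' @export
read_scheme_fsl <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  stopifnot(length(bvals) == ncol(bvecs))
  list(bvals = bvals, bvecs = bvecs)
}

#' Write a Camino-style scheme table
#'
#' Plain-text table with one row per measurement: direction (3 columns),
#' gradient amplitude |G| (T/m), Delta, delta and TE (s).
#'
#' @param scheme an acquisition scheme.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scheme_camino <- function(scheme, path) {
  m <- cbind(scheme$gx, scheme$gy, scheme$gz, scheme$G, scheme$Delta,
             scheme$delta, scheme$TE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("VERSION: STEJSKALTANNER", con)
  utils::write.table(format(m, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
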
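#' Undulating cylinder (model axon)
#'
#' A cylinder of radius `r` whose centerline is displaced sinusoidally:
#' the centerline at height `z` sits at
#' `base_point + A * sin(2 * pi * (z - base_z) / P)` along the undulation
#' direction. The cylinder runs along `axis` for a length `L`. The
#' undulation path-length ratio `lambda` (arc length of one centerline
#' period over the straight length) is computed at construction.
#'
#' The simulator assumes the canonical orientation: `axis = c(0, 0, 1)` and
#' undulation displacement along +x (so the undulation plane is x-z and its
#' normal is +y). The constructor stores arbitrary unit vectors but
#' [simulate_walk()] only accepts the canonical frame.
#'
#' @param base_point numeric length-3, um; a point on the centerline at the
#'   start of the cylinder.
#' @param radius cylinder radius, um.
#' @param length cylinder length along the axis, um.
#' @param amplitude undulation amplitude `A`, um (0 gives a straight
#'   cylinder).
#' @param period undulation period `P`, um.
#' @param axis unit 3-vector, cylinder axis.
#' @param plane_normal unit 3-vector normal to the undulation plane.
#' @return object of class `undulating_cylinder`.
#' @seealso [undulation_ratio()], [build_axon_bundle()]
#' @export
undulating_cylinder <- function(base_point, radius, length, amplitude,
                                period,
                                axis = c(0, 0, 1),
                                plane_normal = c(0, 1, 0)) {
  stopifnot(is.numeric(base_point), length(base_point) == 3,
            all(is.finite(base_point)))
  if (radius <= 0) stop("cylinder radius must be > 0")
  if (length <= 0) stop("cylinder length must be > 0")
  if (amplitude < 0) stop("undulation amplitude must be >= 0")
  if (period <= 0) stop("undulation period must be > 0")
  if (abs(sum(axis^2) - 1) > 1e-8) stop("axis must have unit norm")
  if (abs(sum(plane_normal^2) - 1) > 1e-8)
    stop("plane_normal must have unit norm")
  structure(list(base_point = as.numeric(base_point),
                 axis = as.numeric(axis),
                 radius = radius, length = length,
                 amplitude = amplitude, period = period,
                 plane_normal = as.numeric(plane_normal),
                 lambda = undulation_ratio(amplitude, period)),
            class = "undulating_cylinder")
}

#' Undulation path-length ratio
#'
#' Arc length of the sinusoidal centerline `x(z) = A * sin(2 * pi * z / P)`
#' over one period, divided by the period. Equals 1 for a straight fiber
#' and grows with the amplitude-to-period ratio; for the default axon
#' geometry (A = 2 um, P = 40 um) it is 1.024.
#'
#' @param A undulation amplitude, um (>= 0).
#' @param P undulation period, um (> 0).
#' @return the dimensionless ratio `lambda >= 1`, by adaptive quadrature to
#'   better than 1e-6 relative error.
#' @examples
#' undulation_ratio(2, 40)   # ~ 1.024
#' undulation_ratio(0, 40)   # exactly 1
#' @export
undulation_ratio <- function(A, P) {
  if (!is.numeric(P) || length(P) != 1 || !is.finite(P) || P <= 0)
    stop("undulation period P must be a positive number")
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A < 0)
    stop("undulation amplitude A must be a non-negative number")
  if (A == 0) return(1)
  k <- A * 2 * pi / P
  f <- function(z) sqrt(1 + k^2 * cos(2 * pi * z / P)^2)
  stats::integrate(f, 0, P, rel.tol = 1e-9)$value / P
}

#' Sphere obstacle (model cell body)
#'
#' @param center numeric length-3, um.
#' @param radius sphere radius, um (> 0).
#' @return object of class `sphere_obstacle`.
#' @export
sphere_obstacle <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 3, all(is.finite(center)))
  if (radius <= 0) stop("sphere radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_obstacle")
}

#' Tissue substrate: a periodic voxel of impermeable obstacles
#'
#' Bundles the geometry the walker diffuses through: a cubic voxel with
#' periodic boundaries containing undulating cylinders (axons) and spheres
#' (cells) with impermeable membranes, plus the free diffusivity of the
#' medium. Construction validates that no obstacles overlap and that all
#' spheres lie wholly inside the voxel.
#'
#' @param voxel_edge edge of the cubic voxel, um.
#' @param cylinders list of [undulating_cylinder()] objects.
#' @param spheres list of [sphere_obstacle()] objects.
#' @param diffusivity free diffusivity of water in the medium, m^2/s.
#' @return object of class `substrate_spec`.
#' @export
substrate_spec <- function(voxel_edge, cylinders = list(), spheres = list(),
                          diffusivity = 0.6e-9) {
  if (voxel_edge <= 0) stop("voxel_edge must be > 0")
  if (diffusivity < 0) stop("diffusivity must be >= 0")
  stopifnot(all(vapply(cylinders, inherits, TRUE, "undulating_cylinder")),
            all(vapply(spheres, inherits, TRUE, "sphere_obstacle")))
  s <- structure(list(voxel_edge = voxel_edge,
                      cylinders = cylinders, spheres = spheres,
                      diffusivity = diffusivity,
                      boundary_mode = "periodic"),
                 class = "substrate_spec")
  validate_substrate(s)
  s
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf(
    "<substrate_spec> voxel %g um, %d cylinder(s), %d sphere(s), d = %g m^2/s\n",
    x$voxel_edge, length(x$cylinders), length(x$spheres), x$diffusivity))
  invisible(x)
}

# internal: substrate -> plain matrices for the compiled geometry kernels
as_geom <- function(substrate) {
  cyl <- matrix(0, 0, 6)
  if (length(substrate$cylinders) > 0) {
    cyl <- t(vapply(substrate$cylinders, function(cc)
      c(cc$base_point, cc$amplitude, cc$period, cc$radius), numeric(6)))
  }
  sph <- matrix(0, 0, 4)
  if (length(substrate$spheres) > 0) {
    sph <- t(vapply(substrate$spheres, function(s)
      c(s$center, s$radius), numeric(4)))
  }
  list(cyl = cyl, sph = sph, edge = substrate$voxel_edge)
}

# minimum in-plane distance from point p (um) to a cylinder's centerline,
# scanned over a z-window (conservative for gentle undulation)
min_dist_to_cylinder <- function(p, cyl, z_halfwidth) {
  zs <- seq(p[3] - z_halfwidth, p[3] + z_halfwidth, length.out = 21)
  cx <- cyl$base_point[1] +
    cyl$amplitude * sin(2 * pi * (zs - cyl$base_point[3]) / cyl$period)
  min(sqrt((p[1] - cx)^2 + (p[2] - cyl$base_point[2])^2)) - cyl$radius
}

validate_substrate <- function(s) {
  e <- s$voxel_edge
  for (sp in s$spheres) {
    if (any(sp$center < sp$radius - 1e-9) ||
        any(sp$center > e - sp$radius + 1e-9))
      stop("sphere at (", paste(signif(sp$center, 4), collapse = ", "),
           ") does not lie wholly inside the voxel")
  }
  ns <- length(s$spheres)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
      d <- sqrt(sum((s$spheres[[i]]$center - s$spheres[[j]]$center)^2))
      if (d < s$spheres[[i]]$radius + s$spheres[[j]]$radius - 1e-9)
        stop("spheres ", i, " and ", j, " overlap")
    }
  }
  for (i in seq_along(s$spheres)) for (j in seq_along(s$cylinders)) {
    sp <- s$spheres[[i]]
    if (min_dist_to_cylinder(sp$center, s$cylinders[[j]], sp$radius) <
        sp$radius - 1e-9)
      stop("sphere ", i, " overlaps cylinder ", j)
  }
  nc <- length(s$cylinders)
  if (nc > 1) {
    for (i in seq_len(nc - 1)) for (j in seq(i + 1, nc)) {
      check_cylinder_pair(s$cylinders[[i]], s$cylinders[[j]], i, j)
    }
  }
  invisible(s)
}

# cylinders built by build_axon_bundle undulate in phase, so centerline
# separation is the constant lattice offset and the non-touching condition
# is a single distance check
check_cylinder_pair <- function(a, b, i, j) {
  off <- a$base_point[1:2] - b$base_point[1:2]
  same_phase <- isTRUE(all.equal(a$amplitude, b$amplitude)) &&
    isTRUE(all.equal(a$period, b$period)) &&
    isTRUE(all.equal(a$base_point[3], b$base_point[3]))
  gap <- if (same_phase) {
    sqrt(sum(off^2)) - a$radius - b$radius
  } else {
    # out-of-phase worst case: centerlines can close by up to A_i + A_j in x
    sqrt(max(0, abs(off[1]) - a$amplitude - b$amplitude)^2 + off[2]^2) -
      a$radius - b$radius
  }
  if (gap <= 0)
    stop("cylinders ", i, " and ", j, " touch (surface gap ",
         signif(gap, 3), " um)")
  invisible(TRUE)
}

#' Build a hexagonally packed bundle of undulating cylinders
#'
#' Places `n_cylinders` parallel cylinders (axis +z, in-phase sinusoidal
#' undulation along +x) with centers on a hexagonal lattice, mimicking a
#' coherent white-matter tract with no orientation dispersion. Lattice rows
#' of 3 are stacked with the usual half-pitch offset.
#'
#' @param n_cylinders number of cylinders (>= 1).
#' @param r cylinder radius, um.
#' @param L cylinder length, um.
#' @param A undulation amplitude, um.
#' @param P undulation period, um.
#' @param spacing lattice pitch (center-to-center), um. Must exceed `2 * r`
#'   for in-phase undulation or the bundle self-intersects.
#' @param center x-y coordinates of the bundle centroid, um.
#' @return list of [undulating_cylinder()] objects.
#' @examples
#' bundle <- build_axon_bundle(6, r = 1, L = 40, A = 2, P = 40, spacing = 13,
#'                             center = c(20, 20))
#' @export
build_axon_bundle <- function(n_cylinders, r, L, A, P, spacing,
                              center = c(0, 0)) {
  stopifnot(n_cylinders >= 1)
  n_row <- 3
  idx <- seq_len(n_cylinders) - 1L
  row <- idx %/% n_row
  col <- idx %% n_row
  xy <- cbind((col + 0.5 * (row %% 2)) * spacing,
              row * spacing * sqrt(3) / 2)
  xy <- sweep(xy, 2, colMeans(xy))          # center the lattice
  xy <- sweep(xy, 2, center, "+")
  cyls <- lapply(seq_len(n_cylinders), function(i)
    undulating_cylinder(c(xy[i, 1], xy[i, 2], 0), radius = r, length = L,
                        amplitude = A, period = P))
  if (n_cylinders > 1) {
    for (i in seq_len(n_cylinders - 1)) for (j in seq(i + 1, n_cylinders))
      check_cylinder_pair(cyls[[i]], cyls[[j]], i, j)
  }
  cyls
}

#' White-matter voxel substrate with default axon geometry
#'
#' Convenience constructor for the simulation voxel: a 40 um periodic cube
#' holding 6 hexagonally packed undulating cylinders (radius 1 um, length
#' 40 um, undulation amplitude 2 um over one 40 um period, path-length
#' ratio 1.024) in a medium with free diffusivity 0.6e-9 m^2/s.
#'
#' @param voxel_edge voxel edge, um.
#' @param n_cylinders number of axons.
#' @param r,A,P cylinder radius, undulation amplitude and period, um.
#' @param spacing hexagonal lattice pitch, um.
#' @param diffusivity free diffusivity, m^2/s.
#' @return a [substrate_spec()].
#' @export
wm_substrate <- function(voxel_edge = 40, n_cylinders = 6, r = 1, A = 2,
                         P = 40, spacing = 13, diffusivity = 0.6e-9) {
  cyls <- build_axon_bundle(n_cylinders, r = r, L = voxel_edge, A = A,
                            P = P, spacing = spacing,
                            center = c(voxel_edge / 2, voxel_edge / 2))
  substrate_spec(voxel_edge, cylinders = cyls, diffusivity = diffusivity)
}

#' Add randomly placed spheres to a substrate
#'
#' Rejection-samples `n` sphere centers uniformly in the voxel interior so
#' that no sphere overlaps a cylinder, an existing sphere, or another new
#' sphere. Centers are kept at least `radius + margin` from every voxel
#' face so obstacle surfaces stay clear of the periodic wrap planes.
#' Deterministic for a fixed seed.
#'
#' @param substrate a [substrate_spec()].
#' @param n number of spheres to add (>= 0).
#' @param radius sphere radius, um.
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling budget per sphere.
#' @param margin extra clearance from the voxel faces, um.
#' @param max_restarts configurations abandoned and restarted before the
#'   packing is declared infeasible (greedy rejection sampling can dead-end
#'   at feasible densities).
#' @return a new [substrate_spec()] with the spheres added.
#' @export
place_spheres <- function(substrate, n, radius = 5, rng_seed = 1,
                          max_attempts = 10000, margin = 0.5,
                          max_restarts = 10) {
  stopifnot(inherits(substrate, "substrate_spec"), n >= 0)
  if (n == 0) return(substrate)
  e <- substrate$voxel_edge
  lo <- radius + margin
  hi <- e - radius - margin
  if (hi <= lo)
    stop("packing failed: sphere radius ", radius,
         " does not fit in a ", e, " um voxel (placed 0 of ", n, ")")
  centers <- matrix(NA_real_, n, 3)
  best_placed <- 0L
  withr::with_seed(rng_seed, {
    done <- FALSE
    for (restart in seq_len(max_restarts)) {
      placed <- 0L
      for (i in seq_len(n)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          p <- runif(3, lo, hi)
          if (placed > 0) {
            d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)
            if (any(d2 < (2 * radius)^2)) next
          }
          clear <- TRUE
          for (cyl in substrate$cylinders) {
            if (min_dist_to_cylinder(p, cyl, radius) < radius) {
              clear <- FALSE; break
            }
          }
          if (!clear) next
          centers[i, ] <- p
          placed <- placed + 1L
          ok <- TRUE
          break
        }
        if (!ok) break
      }
      best_placed <- max(best_placed, placed)
      if (placed == n) { done <- TRUE; break }
    }
    if (!done)
      stop("packing failed: placed ", best_placed, " of ", n,
           " spheres within the attempt budget")
  })
  spheres <- c(substrate$spheres,
               lapply(seq_len(n), function(i)
                 sphere_obstacle(centers[i, ], radius)))
  out <- substrate
  out$spheres <- spheres
  validate_substrate(out)
  out
}

#' Classify points by tissue compartment
#'
#' Maps each point into the periodic voxel and tests it against every
#' obstacle. Membership in a cylinder uses the implicit tube surface (a
#' circular cross-section in the plane perpendicular to the main axis).
#'
#' @param p numeric length-3 vector or an n x 3 matrix of points, um.
#' @param substrate a [substrate_spec()].
#' @return factor with levels `intra_cylinder`, `intra_sphere`, `extra`.
#' @export
classify_point <- function(p, substrate) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3, all(is.finite(p)))
  g <- as_geom(substrate)
  code <- classify_cpp(p, g$cyl, g$sph, g$edge)
  ncyl <- nrow(g$cyl)
  lab <- ifelse(code == 0, "extra",
                ifelse(code <= ncyl, "intra_cylinder", "intra_sphere"))
  factor(lab, levels = COMPARTMENTS)
}

#' Monte Carlo compartment volume fractions
#'
#' Uniformly samples the voxel and classifies each point; the returned
#' fractions sum to 1 exactly and converge to the analytic obstacle volume
#' fractions at the usual 1/sqrt(n) Monte Carlo rate.
#'
#' @param substrate a [substrate_spec()].
#' @param n_samples number of uniform samples (>= 1).
#' @param rng_seed integer seed.
#' @return named numeric vector of fractions for `intra_cylinder`,
#'   `intra_sphere`, and `extra`.
#' @export
volume_fractions <- function(substrate, n_samples = 1e5, rng_seed = 1) {
  stopifnot(n_samples >= 1)
  pts <- withr::with_seed(rng_seed,
    matrix(runif(3 * n_samples, 0, substrate$voxel_edge), ncol = 3))
  lab <- classify_point(pts, substrate)
  tab <- table(lab)
  setNames(as.numeric(tab[COMPARTMENTS]) / n_samples, COMPARTMENTS)
}
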
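test_that("undulation ratio matches quadrature oracle and known values", {
  # independent oracle: dense midpoint Riemann sum of the arc-length integrand
  riemann_lambda <- function(A, P, n = 2e5) {
    z <- (seq_len(n) - 0.5) * P / n
    k <- A * 2 * pi / P
    mean(sqrt(1 + k^2 * cos(2 * pi * z / P)^2))
  }
  expect_equal(undulation_ratio(2, 40), 1.024, tolerance = 1e-3)
  expect_identical(undulation_ratio(0, 40), 1)
  expect_equal(undulation_ratio(1, 40), riemann_lambda(1, 40),
               tolerance = 1e-7)
  expect_equal(undulation_ratio(1, 40), 1.0061, tolerance = 1e-4)
  expect_equal(undulation_ratio(3.7, 11), riemann_lambda(3.7, 11),
               tolerance = 1e-7)
  # monotone non-decreasing in amplitude at fixed period
  lams <- vapply(seq(0, 4, by = 0.5), undulation_ratio, 0, P = 40)
  expect_true(all(diff(lams) >= 0))
  expect_error(undulation_ratio(2, 0), "period")
  expect_error(undulation_ratio(-1, 40), "amplitude")
})

test_that("axon bundles are hexagonally packed and never touch", {
  bundle <- build_axon_bundle(6, r = 1, L = 40, A = 2, P = 40,
                              spacing = 4.5)
  expect_length(bundle, 6)
  # in-phase undulation: surface gap is the constant lattice offset - 2r
  xy <- t(vapply(bundle, function(cc) cc$base_point[1:2], numeric(2)))
  dmin <- min(dist(xy))
  expect_gt(dmin - 2, 0)
  # all share the +z axis (no dispersion)
  for (cc in bundle) expect_equal(cc$axis, c(0, 0, 1))

  straight <- build_axon_bundle(1, 1, 40, 0, 40, spacing = 4.5)
  expect_identical(straight[[1]]$lambda, 1)

  expect_error(build_axon_bundle(3, 1, 40, 2, 40, spacing = 2.0),
               "cylinders 1 and 2 touch")
})

test_that("sphere placement is collision-free, seeded, and fails when full", {
  s <- wm_substrate()
  expect_identical(place_spheres(s, 0, 5, rng_seed = 1), s)

  s25a <- place_spheres(s, 25, 5, rng_seed = 1)
  s25b <- place_spheres(s, 25, 5, rng_seed = 1)
  expect_identical(s25a, s25b)
  expect_length(s25a$spheres, 25)
  centers <- t(vapply(s25a$spheres, function(x) x$center, numeric(3)))
  expect_gt(min(dist(centers)), 10)       # radius-5 spheres never overlap
  expect_true(all(centers > 5 & centers < 35))

  s25c <- place_spheres(s, 25, 5, rng_seed = 2)
  expect_false(identical(s25a$spheres, s25c$spheres))

  expect_error(place_spheres(s, 2000, 5, rng_seed = 1), "packing failed")
})

test_that("point classification is correct and periodic", {
  s <- place_spheres(wm_substrate(), 5, 5, rng_seed = 3)
  cyl <- s$cylinders[[1]]
  on_axis <- c(cyl$base_point[1], cyl$base_point[2], cyl$base_point[3])
  expect_identical(as.character(classify_point(on_axis, s)),
                   "intra_cylinder")
  expect_identical(as.character(classify_point(s$spheres[[1]]$center, s)),
                   "intra_sphere")
  empty <- empty_substrate()
  expect_identical(as.character(classify_point(c(0, 0, 0), empty)), "extra")

  # invariance under translation by integer multiples of the voxel edge
  set.seed(7)
  pts <- matrix(runif(300, 0, 40), ncol = 3)
  shift <- matrix(sample(c(-2, -1, 1, 3), 300, TRUE) * 40, ncol = 3)
  expect_identical(classify_point(pts, s), classify_point(pts + shift, s))
})

test_that("volume fractions sum to one and converge to analytic values", {
  empty <- empty_substrate()
  vf0 <- volume_fractions(empty, 1e4, rng_seed = 1)
  expect_identical(unname(vf0["extra"]), 1)
  expect_equal(sum(vf0), 1)

  one_sphere <- substrate_spec(40, spheres = list(
    sphere_obstacle(c(20, 20, 20), 5)))
  vf1 <- volume_fractions(one_sphere, 2e5, rng_seed = 1)
  analytic <- (4 / 3) * pi * 5^3 / 40^3      # 0.00818
  expect_equal(sum(vf1), 1)
  expect_equal(unname(vf1["intra_sphere"]), analytic, tolerance = 0.15)

  s25 <- place_spheres(wm_substrate(), 25, 5, rng_seed = 1)
  vf25 <- volume_fractions(s25, 2e5, rng_seed = 2)
  expect_equal(unname(vf25["intra_sphere"]), 25 * analytic,
               tolerance = 0.02)
  expect_equal(sum(vf25), 1)
  # reproducibility
  expect_identical(vf25, volume_fractions(s25, 2e5, rng_seed = 2))
})

test_that("substrate constructors reject invalid geometry", {
  expect_error(sphere_obstacle(c(0, 0, 0), -1), "radius")
  expect_error(undulating_cylinder(c(0, 0, 0), radius = 0, length = 40,
                                   amplitude = 2, period = 40), "radius")
  expect_error(substrate_spec(40, spheres = list(
    sphere_obstacle(c(2, 20, 20), 5))), "inside the voxel")
  expect_error(substrate_spec(40, spheres = list(
    sphere_obstacle(c(20, 20, 20), 5),
    sphere_obstacle(c(24, 20, 20), 5))), "overlap")
})
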
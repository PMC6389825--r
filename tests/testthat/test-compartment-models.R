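test_that("the Watson density is normalized, symmetric, and peaked at mu", {
  mu <- c(0, 0, 1)
  # kappa = 0: uniform density 1/(4 pi)
  set.seed(2)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_equal(watson_density(dirs, mu, 0), rep(1 / (4 * pi), 100))
  # peak at +/- mu
  d16 <- watson_density(rbind(mu, -mu, dirs), mu, 16)
  expect_true(all(d16[1] >= d16))
  expect_equal(d16[1], d16[2])
  # integral over the sphere = 1 (product spherical quadrature oracle)
  gl <- pracma::gaussLegendre(200, -1, 1)
  nphi <- 100
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  total <- 0
  for (k in seq_len(nphi)) {
    st <- sqrt(pmax(0, 1 - gl$x^2))
    n_vec <- cbind(st * cos(phi[k]), st * sin(phi[k]), gl$x)
    total <- total + sum(gl$w * watson_density(n_vec, mu, 16)) * 2 * pi / nphi
  }
  expect_equal(total, 1, tolerance = 1e-4)
  expect_error(watson_density(mu, mu, -1), "kappa")
})

test_that("ODI-kappa mapping has the right limits and inverse", {
  expect_equal(odi_from_kappa(1e12), 0, tolerance = 1e-10)
  expect_equal(odi_from_kappa(1), 0.5)
  expect_identical(odi_from_kappa(0), 1)
  odi_grid <- seq(0.01, 1, by = 0.01)
  expect_equal(odi_from_kappa(kappa_from_odi(odi_grid)), odi_grid,
               tolerance = 1e-10)
  # strictly decreasing in kappa
  expect_true(all(diff(odi_from_kappa(c(0, 0.5, 1, 2, 8, 64))) < 0))
})

test_that("predicted signals hit the analytic limits", {
  sch <- make_noddi_scheme()
  b <- sch$bval * 1e6
  # pure free water
  p1 <- noddi_params(v_ic = 0.5, kappa = 2, v_iso = 1)
  expect_equal(predict_signal(p1, sch), exp(-b * 2e-9))
  # coherent stick along mu: S = exp(-b d cos^2(angle))
  p2 <- noddi_params(v_ic = 1, kappa = 1e4, v_iso = 0, mu = c(0, 0, 1))
  expect_equal(predict_signal(p2, sch), exp(-b * 0.6e-9 * sch$gz^2),
               tolerance = 1e-3)
  # b = 0 measurements are exactly 1 for any parameter set
  p3 <- noddi_params(0.37, 3.2, v_iso = 0.11, v_dot = 0.08,
                     mu = c(1, 2, -1))
  expect_identical(unname(predict_signal(p3, sch)[sch$bval == 0]),
                   rep(1, 10))
  # bounded mixture
  expect_true(all(predict_signal(p3, sch) >= 0 &
                    predict_signal(p3, sch) <= 1))
})

test_that("Watson spherical means match an independent product quadrature", {
  sch <- make_noddi_scheme(n_b0 = 1, shells = list(c(800, 5), c(2000, 7)))
  mu <- c(0.3, -0.5, 1); mu <- mu / sqrt(sum(mu^2))
  for (kappa in c(0.5, 4, 16, 64)) {
    prm <- noddi_params(v_ic = 1, kappa = kappa, v_iso = 0, mu = mu)
    mine <- predict_signal(prm, sch)
    oracle <- vapply(seq_len(nrow(sch)), function(i)
      quadrature_stick_oracle(kappa, sch$bval[i] * 1e6 * 0.6e-9,
                              c(sch$gx[i], sch$gy[i], sch$gz[i]), mu),
      numeric(1))
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
  # and the full three-compartment mixture against the same oracle
  vic <- 0.6; viso <- 0.1; kappa <- 4
  prm <- noddi_params(v_ic = vic, kappa = kappa, v_iso = viso, mu = mu)
  dperp <- 0.6e-9 * (1 - vic)
  oracle_mix <- vapply(seq_len(nrow(sch)), function(i) {
    g <- c(sch$gx[i], sch$gy[i], sch$gz[i])
    bd <- sch$bval[i] * 1e6
    sic <- quadrature_stick_oracle(kappa, bd * 0.6e-9, g, mu)
    # zeppelin mean-tensor: tau1 by 1-D quadrature on the Watson weight
    gl <- pracma::gaussLegendre(400, 0, 1)
    w_un <- exp(kappa * (gl$x^2 - 1))
    tau1 <- sum(gl$w * gl$x^2 * w_un) / sum(gl$w * w_un)
    ct2 <- sum(g * mu)^2
    gDg <- dperp + (0.6e-9 - dperp) * (tau1 * ct2 + (1 - tau1) * (1 - ct2) / 2)
    (1 - viso) * (vic * sic + (1 - vic) * exp(-bd * gDg)) +
      viso * exp(-bd * 2e-9)
  }, numeric(1))
  expect_equal(predict_signal(prm, sch), oracle_mix, tolerance = 1e-3)
})

test_that("the NODDI fitter recovers noise-free parameters", {
  sch <- make_noddi_scheme()
  truth <- noddi_params(v_ic = 0.5, kappa = 2, v_iso = 0.05,
                        mu = c(0.2, -0.1, 1))
  fit <- fit_noddi(predict_signal(truth, sch), sch, variant = "in_vivo")
  expect_lt(abs(fit$odi - truth$odi), 0.02)
  expect_lt(abs(fit$v_ic - truth$v_ic), 0.05)
  expect_lt(abs(fit$v_iso - truth$v_iso), 0.05)
  expect_gt(abs(sum(fit$mu * truth$mu)), 0.99)
  # deterministic
  fit2 <- fit_noddi(predict_signal(truth, sch), sch, variant = "in_vivo")
  expect_identical(fit$odi, fit2$odi)
})

test_that("pure free water is identified as the isotropic compartment", {
  sch <- make_noddi_scheme()
  sig <- exp(-sch$bval * 1e6 * 2e-9)
  fit <- fit_noddi(sig, sch, variant = "in_vivo")
  expect_gte(fit$v_iso, 0.95)
})

test_that("the fitter rejects degenerate inputs", {
  sch <- make_noddi_scheme()
  expect_error(fit_noddi(rep(0, nrow(sch)), sch), "degenerate b = 0")
  expect_error(fit_noddi(rep(NA_real_, nrow(sch)), sch), "non-finite")
  sch1 <- make_noddi_scheme(n_b0 = 2, shells = list(c(800, 25)))
  expect_error(fit_noddi(rep(1, nrow(sch1)), sch1), "two.*shells")
})

test_that("tensor fitting recovers analytic tensors", {
  sch <- make_noddi_scheme()
  b <- sch$bval * 1e6
  # isotropic signal at the free diffusivity
  sig_iso <- exp(-b * 0.6e-9)
  tf <- fit_dti(sig_iso, sch)
  expect_equal(tf$md, 0.6e-9, tolerance = 1e-6)
  expect_lt(tf$fa, 0.01)
  # diagonal tensor with known FA
  lam <- c(1.7, 0.2, 0.2) * 1e-9
  g <- as.matrix(sch[, c("gx", "gy", "gz")])
  sig_t <- exp(-b * (g^2 %*% lam))
  tf2 <- fit_dti(as.numeric(sig_t), sch)
  md <- mean(lam)
  fa_expect <- sqrt(1.5 * sum((lam - md)^2)) / sqrt(sum(lam^2))  # 0.870
  expect_equal(tf2$fa, fa_expect, tolerance = 1e-4)
  expect_equal(fa_expect, 0.870, tolerance = 1e-3)
  expect_equal(tf2$md, md, tolerance = 1e-4)
  # S == 1 everywhere: zero tensor, FA -> 0 by convention
  tf3 <- fit_dti(rep(1, nrow(sch)), sch)
  expect_equal(tf3$md, 0)
  expect_identical(tf3$fa, 0)
})

test_that("FA and MD are invariant under global rotation", {
  sch <- make_noddi_scheme()
  b <- sch$bval * 1e6
  g <- as.matrix(sch[, c("gx", "gy", "gz")])
  D <- diag(c(1.4, 0.5, 0.3) * 1e-9)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  sig <- exp(-b * rowSums((g %*% D) * g))
  sch_rot <- sch
  g_rot <- g %*% t(R)
  sch_rot$gx <- g_rot[, 1]; sch_rot$gy <- g_rot[, 2]; sch_rot$gz <- g_rot[, 3]
  sig_rot <- exp(-b * rowSums((g_rot %*% (R %*% D %*% t(R))) * g_rot))
  f1 <- fit_dti(sig, sch)
  f2 <- fit_dti(sig_rot, sch_rot)
  expect_equal(f1$fa, f2$fa, tolerance = 1e-6)
  expect_equal(f1$md, f2$md, tolerance = 1e-6)
})
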
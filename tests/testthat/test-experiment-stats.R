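test_that("Kendall's tau matches brute-force pair counting", {
  expect_equal(kendall_tau(1:5, c(2, 1, 4, 3, 5))$statistic, 0.6)
  expect_equal(kendall_tau(1:8, (1:8)^3)$statistic, 1)
  expect_equal(kendall_tau(1:8, -(1:8))$statistic, -1)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    x <- if (i %% 2) rnorm(n) else sample(1:6, n, TRUE)
    y <- if (i %% 3) rnorm(n) else sample(1:6, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$statistic, brute_tau(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("Kendall's tau agrees with the reference implementation", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    ties <- i %% 2 == 0
    x <- if (ties) sample(1:5, n, TRUE) else rnorm(n)
    y <- if (ties) sample(1:5, n, TRUE) else rnorm(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- kendall_tau(x, y)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = !ties && n <= 10))
    expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-10)
    if (ties || n <= 10) {   # same p-value method in these regimes
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Kendall's tau is invariant under monotone transforms", {
  set.seed(13)
  x <- rnorm(15); y <- rnorm(15)
  base <- kendall_tau(x, y)
  expect_equal(kendall_tau(exp(x), y)$statistic, base$statistic)
  expect_equal(kendall_tau(x, rank(y))$statistic, base$statistic)
  expect_equal(kendall_tau(2 * x + 7, y^3 + y)$statistic, base$statistic)
})

test_that("the pooled t-test matches hand and reference computations", {
  r0 <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r_shift <- t_test_unpaired(c(1, 2, 3), c(101, 102, 103))
  expect_lt(r_shift$p_value, 0.001)
  # hand computation of the pooled formula
  a <- c(2.1, 2.5, 1.9, 2.3); b <- c(3.0, 3.4, 2.8)
  sp2 <- (3 * var(a) + 2 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  r <- t_test_unpaired(a, b)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:100) {
    aa <- rnorm(sample(3:12, 1)); bb <- rnorm(sample(3:12, 1), mean = 0.5)
    mine <- t_test_unpaired(aa, bb)
    ref <- stats::t.test(aa, bb, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # degenerate zero-variance conventions
  expect_warning(rz <- t_test_unpaired(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(rz$p_value, 0)
})

test_that("particle counting finds discs above threshold and size", {
  img <- matrix(0, 60, 60)
  draw_disc <- function(img, cx, cy, r, val = 10) {
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
      if ((i - cx)^2 + (j - cy)^2 <= r^2) img[i, j] <- val
    img
  }
  img <- draw_disc(img, 12, 12, 4)
  img <- draw_disc(img, 30, 40, 4)
  img <- draw_disc(img, 50, 15, 4)
  expect_equal(count_particles(img, threshold = 5, min_size = 10), 3)
  # a single small disc below min_size is filtered out
  img2 <- draw_disc(matrix(0, 60, 60), 20, 20, 1)   # 5 px
  expect_equal(count_particles(img2, threshold = 5, min_size = 10), 0)
  expect_equal(count_particles(img2, threshold = 5, min_size = 3), 1)
  # translation invariance
  img3 <- matrix(0, 60, 60)
  img3[10:48, 5:43] <- img[12:50, 12:50]
  expect_equal(count_particles(img3, threshold = 5, min_size = 10), 3)
  # 8-connectivity joins diagonal neighbours into one particle
  img4 <- matrix(0, 10, 10)
  img4[3, 3] <- 10; img4[4, 4] <- 10; img4[5, 5] <- 10
  expect_equal(count_particles(img4, threshold = 5, min_size = 1), 1)
  lab4 <- label_components(img4 > 5, connectivity = 4)
  expect_equal(max(lab4), 3)
})

test_that("density-ODI correlation extracts treated post-withdrawal animals", {
  tab <- generate_repopulation_study(effect_model(), rng_seed = 5)
  res <- correlate_density_odi(tab)
  expect_equal(res$n, 18)
  expect_gt(res$statistic, 0)
  # monotone transform of counts gives tau = 1
  tab2 <- tab[tab$group == "treated" & tab$day %in% c(1, 3, 7), ]
  tab2$mean_ODI <- sqrt(tab2$microglia_count + 1)
  expect_equal(correlate_density_odi(tab2)$statistic, 1)
  # shuffling breaks the association on average
  set.seed(6)
  taus <- replicate(50, {
    t3 <- tab2
    t3$mean_ODI <- sample(tab$mean_ODI, nrow(t3))
    correlate_density_odi(t3)$statistic
  })
  expect_lt(abs(mean(taus)), 0.15)
  # missing day errors
  expect_error(correlate_density_odi(tab[tab$day != 3, ]), "day")
  # per-group means variant uses the three day means
  expect_equal(correlate_density_odi(tab, per_group = TRUE)$n, 3)
})
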
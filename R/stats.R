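#' Kendall's rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation computed by direct pair counting:
#' `tau_b = (C - D) / sqrt((n0 - n_t)(n0 - n_u))` with `n0 = n(n-1)/2` and
#' the usual tie sums. The p-value (two-sided against tau = 0) is exact by
#' enumeration of the null permutation distribution when `n <= 10` and
#' neither vector has ties, and uses the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return object of class `stat_result`: list with `statistic` (tau_b),
#'   `p_value`, `n`, and `method`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Kendall's tau is undefined for a constant input vector")
  ij <- utils::combn(n, 2)
  dx <- sign(x[ij[1, ]] - x[ij[2, ]])
  dy <- sign(y[ij[1, ]] - y[ij[2, ]])
  S <- sum(dx * dy)                      # concordant minus discordant
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  nt <- sum(tx * (tx - 1) / 2)
  nu <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - nt) * (n0 - nu))
  has_ties <- nt > 0 || nu > 0
  if (!has_ties && n <= 10) {
    # exact: enumerate the null distribution of the discordant-pair count
    # (inversion count of a random permutation)
    d_obs <- (n0 - S) / 2
    pd <- inversion_distribution(n)
    lower <- sum(pd[seq_len(d_obs + 1)])
    upper <- sum(pd[seq(d_obs + 1, length(pd))])
    p <- min(1, 2 * min(lower, upper))
    method <- "Kendall tau-b, exact enumeration"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- 2 * pnorm(-abs(z))
    method <- "Kendall tau-b, normal approximation"
  }
  structure(list(statistic = tau, p_value = p, n = n, method = method),
            class = "stat_result")
}

# probabilities of 0..n(n-1)/2 inversions in a uniform random permutation
# (classic DP over the Mahonian triangle)
inversion_distribution <- function(n) {
  counts <- 1
  for (m in 2:n) {
    new_len <- length(counts) + m - 1
    acc <- numeric(new_len)
    for (j in 0:(m - 1)) {
      acc[seq_along(counts) + j] <- acc[seq_along(counts) + j] + counts
    }
    counts <- acc
  }
  counts / sum(counts)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4f, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Two-tailed unpaired Student's t-test (pooled variance)
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a `stat_result` with the t statistic and two-sided p-value.
#'   Degenerate zero-variance input follows the conventions p = 1 when the
#'   group means are equal and p = 0 when they differ (with a warning).
#' @export
t_test_unpaired <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    warning("zero pooled variance; degenerate p-value convention used")
    p <- if (diff == 0) 1 else 0
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(statistic = t, p_value = p, n = na + nb,
                 method = "two-tailed unpaired Student's t (pooled)"),
            class = "stat_result")
}

#' Label connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  label_components_cpp(m, connectivity == 8)
}

#' Count particles in an intensity image
#'
#' Reimplementation of the threshold-then-count workflow used with image
#' analysis software: binarize the image at `threshold`, label 8-connected
#' components, and count those with at least `min_size` pixels.
#'
#' @param image numeric matrix of intensities.
#' @param threshold intensity cutoff; pixels strictly above it are
#'   foreground.
#' @param min_size smallest component area (pixels) counted as a particle.
#' @return integer particle count.
#' @export
count_particles <- function(image, threshold, min_size = 10) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  lab <- label_components(image > threshold, connectivity = 8)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_size)
}

#' Rank correlation between cell counts and mean ODI after repopulation
#'
#' Restricts a repopulation table to treated animals at the three
#' post-withdrawal time points (days 1, 3 and 7) and returns Kendall's
#' tau-b between microglial counts and mean ODI, either across individual
#' animals (default) or across per-day group means.
#'
#' @param table a repopulation table as produced by
#'   [generate_repopulation_study()] (columns `group`, `day`,
#'   `microglia_count`, `mean_ODI`).
#' @param per_group if `TRUE`, correlate per-day group means instead of
#'   per-animal values.
#' @return a `stat_result` from [kendall_tau()].
#' @export
correlate_density_odi <- function(table, per_group = FALSE) {
  need <- c("group", "day", "microglia_count", "mean_ODI")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  sub <- table[table$group == "treated" & table$day %in% c(1, 3, 7), ]
  missing_days <- setdiff(c(1, 3, 7), unique(sub$day))
  if (length(missing_days) > 0)
    stop("table is missing treated animals for day(s) ",
         paste(missing_days, collapse = ", "))
  if (per_group) {
    counts <- tapply(sub$microglia_count, sub$day, mean)
    odis <- tapply(sub$mean_ODI, sub$day, mean)
    kendall_tau(as.numeric(counts), as.numeric(odis))
  } else {
    kendall_tau(sub$microglia_count, sub$mean_ODI)
  }
}
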
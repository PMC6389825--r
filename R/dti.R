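#' Fit the diffusion tensor and compute FA / MD
#'
#' Weighted linear least squares on `ln(S)`: an ordinary least-squares pass
#' followed by one reweighting with the squared predicted signals, the
#' standard WLLS scheme. By default only the low shell (b = 0 plus
#' `b <= max_b`) enters the design, limiting non-Gaussian bias from the
#' high-b shell; set `max_b = Inf` to use everything. Negative or zero
#' signals are clamped to a small positive floor before the log.
#'
#' @param signal numeric vector of signals, one per scheme row.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @param max_b largest b-value (s/mm^2) admitted to the tensor fit.
#' @param floor positive clamp applied to the signal before `log`.
#' @return object of class `tensor_fit`: list with the 3 x 3 tensor `D`
#'   (m^2/s), eigenvalues `lambda` (descending, clamped at 0 for the
#'   derived metrics), principal eigenvector `e1`, `fa`, `md` (m^2/s), and
#'   `s0`.
#' @export
fit_dti <- function(signal, scheme, max_b = 800, floor = 1e-6) {
  stopifnot(length(signal) == nrow(scheme))
  keep <- scheme$bval <= max_b
  b <- scheme$bval[keep] * 1e6                  # s/m^2
  g <- as.matrix(scheme[keep, c("gx", "gy", "gz")])
  if (sum(b > 0) < 6)
    stop("tensor fitting needs at least 6 diffusion-weighted directions ",
         "at b <= max_b")
  y <- log(pmax(signal[keep], floor))
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7) stop("rank-deficient design: directions are colinear")
  beta <- qr.coef(qrX, y)
  w <- exp(2 * as.numeric(X %*% beta))          # WLLS reweighting pass
  sw <- sqrt(w)
  beta <- qr.coef(qr(X * sw), y * sw)
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE)
  lam_raw <- ev$values                           # descending
  lam <- pmax(lam_raw, 0)                        # PSD safeguard for metrics
  md <- mean(lam)
  denom <- sqrt(sum(lam^2))
  fa <- if (denom < .Machine$double.eps) 0 else
    sqrt(1.5 * sum((lam - md)^2)) / denom
  structure(list(D = D, lambda = lam, lambda_raw = lam_raw,
                 e1 = ev$vectors[, 1], fa = fa, md = md,
                 s0 = exp(beta[1])),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("<tensor_fit> MD = %.4g m^2/s, FA = %.4f\n", x$md, x$fa))
  invisible(x)
}
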
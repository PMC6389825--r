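#' Orientation dispersion index from the Watson concentration
#'
#' `ODI = (2 / pi) * atan(1 / kappa)`: 1 at `kappa = 0` (isotropic
#' dispersion, by the usual limit convention) decreasing to 0 as
#' `kappa -> Inf` (perfectly coherent sticks).
#'
#' @param kappa Watson concentration (>= 0).
#' @return ODI in (0, 1].
#' @export
odi_from_kappa <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' @rdname odi_from_kappa
#' @param odi orientation dispersion index in (0, 1].
#' @export
kappa_from_odi <- function(odi) {
  stopifnot(all(odi > 0), all(odi <= 1))
  ifelse(odi == 1, 0, 1 / tan(pi * odi / 2))
}

#' NODDI parameter set
#'
#' Parameters of the three-compartment model: Watson-dispersed intra-neurite
#' sticks (fraction `v_ic` of the tissue, orientation `mu`, concentration
#' `kappa`), an extracellular axially symmetric Gaussian compartment whose
#' perpendicular diffusivity follows the tortuosity rule
#' `d_perp = d_par * (1 - v_ic)`, free water (fraction `v_iso`, diffusivity
#' `d_iso`), and an optional isotropically restricted, non-attenuating
#' fraction `v_dot` used for fixed (ex-vivo) tissue.
#'
#' @param v_ic intra-neurite volume fraction, in \[0, 1\].
#' @param kappa Watson concentration (>= 0).
#' @param v_iso free-water fraction, in \[0, 1\].
#' @param v_dot isotropically restricted fraction, in \[0, 1\] (0 for the
#'   standard in-vivo model).
#' @param mu unit 3-vector, mean neurite orientation.
#' @param d_par intrinsic parallel diffusivity, m^2/s (held fixed during
#'   fitting).
#' @param d_iso free-water diffusivity, m^2/s (held fixed).
#' @return object of class `noddi_params`; the derived `odi` is included.
#' @export
noddi_params <- function(v_ic, kappa, v_iso = 0, v_dot = 0,
                         mu = c(0, 0, 1), d_par = 0.6e-9, d_iso = 2e-9) {
  stopifnot(v_ic >= 0, v_ic <= 1, v_iso >= 0, v_iso <= 1,
            v_dot >= 0, v_dot <= 1, kappa >= 0,
            length(mu) == 3, d_par > 0, d_iso > 0)
  mu <- mu / sqrt(sum(mu^2))
  structure(list(v_ic = v_ic, kappa = kappa, v_iso = v_iso, v_dot = v_dot,
                 mu = as.numeric(mu), d_par = d_par, d_iso = d_iso,
                 odi = odi_from_kappa(kappa)),
            class = "noddi_params")
}

#' @export
print.noddi_params <- function(x, ...) {
  cat(sprintf(
    "<noddi_params> v_ic = %.3f, ODI = %.3f (kappa = %.2f), v_iso = %.3f, v_dot = %.3f\n",
    x$v_ic, x$odi, x$kappa, x$v_iso, x$v_dot))
  cat(sprintf("  mu = (%.3f, %.3f, %.3f), d_par = %g, d_iso = %g m^2/s\n",
              x$mu[1], x$mu[2], x$mu[3], x$d_par, x$d_iso))
  invisible(x)
}

#' Predict the normalized NODDI signal for an acquisition scheme
#'
#' Compartment signals: the intra-neurite signal is the Watson average of
#' the stick attenuation `exp(-b d_par (g.n)^2)`; the extracellular signal
#' is a Gaussian with the Watson-mean tensor of an axially symmetric
#' "zeppelin" obeying the tortuosity rule; free water attenuates as
#' `exp(-b d_iso)`; the dot compartment does not attenuate. They combine
#' as `S = (1 - v_iso) ((1 - v_dot)(v_ic S_ic + (1 - v_ic) S_ec) + v_dot)
#' + v_iso S_iso`, which reduces to the standard three-compartment mixture
#' when `v_dot = 0`. `S(b = 0) = 1` exactly.
#'
#' @param params a [noddi_params()] set.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @param nq quadrature order for the Watson spherical means.
#' @return numeric vector of normalized signals.
#' @export
predict_signal <- function(params, scheme, nq = 1001) {
  stopifnot(inherits(params, "noddi_params"))
  b <- scheme$bval * 1e6                       # s/m^2
  dirs <- as.matrix(scheme[, c("gx", "gy", "gz")])
  cosang <- as.numeric(dirs %*% params$mu)
  s_ic <- watson_stick_signal(params$kappa, b * params$d_par, cosang, nq)
  tau1 <- watson_tau1(params$kappa, nq)
  d_perp <- params$d_par * (1 - params$v_ic)
  # g' <D> g for the Watson-mean zeppelin
  gDg <- d_perp + (params$d_par - d_perp) *
    (tau1 * cosang^2 + (1 - tau1) * (1 - cosang^2) / 2)
  s_ec <- exp(-b * gDg)
  s_iso <- exp(-b * params$d_iso)
  (1 - params$v_iso) *
    ((1 - params$v_dot) *
       (params$v_ic * s_ic + (1 - params$v_ic) * s_ec) + params$v_dot) +
    params$v_iso * s_iso
}

#' Fit the NODDI model to a diffusion-weighted signal
#'
#' Two-stage deterministic fit: a coarse grid over `(v_ic, ODI, v_iso[,
#' v_dot])` with the neurite orientation initialized from the principal
#' eigenvector of a low-b tensor fit, followed by derivative-free
#' (Nelder-Mead) refinement of all free parameters (including `mu`) under
#' bound-enforcing transforms. Grid ties are broken by lowest residual then
#' lowest `v_iso`. The `ex_vivo` variant adds the isotropically restricted
#' `v_dot` compartment recommended for fixed tissue; `in_vivo` pins
#' `v_dot = 0`.
#'
#' @param signal numeric vector of (possibly noisy, unnormalized) signals,
#'   one per scheme row; normalized internally by the mean b = 0 signal.
#' @param scheme an [make_noddi_scheme()] acquisition scheme with at least
#'   one b = 0 measurement and two shells.
#' @param variant `"ex_vivo"` (default) or `"in_vivo"`.
#' @param d_par,d_iso fixed compartment diffusivities, m^2/s.
#' @param nq quadrature order for Watson spherical means.
#' @param maxit Nelder-Mead iteration cap (fixed for determinism).
#' @return a [noddi_params()] object with attributes `sse` (residual sum of
#'   squares) and `convergence` (optim code).
#' @export
fit_noddi <- function(signal, scheme, variant = c("ex_vivo", "in_vivo"),
                      d_par = 0.6e-9, d_iso = 2e-9, nq = 201,
                      maxit = 500) {
  variant <- match.arg(variant)
  stopifnot(length(signal) == nrow(scheme))
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  b0 <- scheme$bval == 0
  if (!any(b0)) stop("scheme has no b = 0 measurement")
  if (length(unique(scheme$bval[!b0])) < 2)
    stop("NODDI fitting needs at least two diffusion-weighted shells")
  s0 <- mean(signal[b0])
  if (!is.finite(s0) || s0 <= 0)
    stop("degenerate b = 0 signal; cannot normalize")
  y <- signal / s0
  if (all(y <= 0)) stop("all-zero or negative signal")

  # orientation seed from a low-b tensor fit
  mu0 <- c(0, 0, 1)
  tf <- try(fit_dti(signal, scheme), silent = TRUE)
  if (!inherits(tf, "try-error") && all(is.finite(tf$e1))) mu0 <- tf$e1

  b <- scheme$bval * 1e6
  dirs <- as.matrix(scheme[, c("gx", "gy", "gz")])
  cosang <- as.numeric(dirs %*% mu0)

  odi_u <- seq(0.04, 0.95, length.out = 10)
  kappa_u <- kappa_from_odi(odi_u)
  vic_u <- seq(0.05, 0.95, length.out = 10)
  viso_u <- seq(0, 0.4, length.out = 5)
  vdot_u <- if (variant == "ex_vivo") seq(0, 0.4, length.out = 5) else 0

  s_ic_mat <- vapply(kappa_u, function(k)
    watson_stick_signal(k, b * d_par, cosang, nq), numeric(length(b)))
  tau1_u <- watson_tau1(kappa_u, nq)
  s_iso <- exp(-b * d_iso)

  best <- list(sse = Inf)
  for (ki in seq_along(kappa_u)) {
    for (vi in seq_along(vic_u)) {
      v <- vic_u[vi]
      d_perp <- d_par * (1 - v)
      gDg <- d_perp + (d_par - d_perp) *
        (tau1_u[ki] * cosang^2 + (1 - tau1_u[ki]) * (1 - cosang^2) / 2)
      s_tissue <- v * s_ic_mat[, ki] + (1 - v) * exp(-b * gDg)
      for (vd in vdot_u) {
        inner <- (1 - vd) * s_tissue + vd
        for (vo in viso_u) {
          pred <- (1 - vo) * inner + vo * s_iso
          sse <- sum((y - pred)^2)
          if (sse < best$sse - 1e-12 ||
              (abs(sse - best$sse) <= 1e-12 && vo < best$viso)) {
            best <- list(sse = sse, vic = v, kappa = kappa_u[ki],
                         viso = vo, vdot = vd)
          }
        }
      }
    }
  }

  # refinement on transformed parameters (logit for fractions and ODI,
  # spherical angles for mu)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  clamp <- function(p, lo = 1e-4, hi = 1 - 1e-4) pmin(pmax(p, lo), hi)
  th0 <- acos(clamp(mu0[3], -1 + 1e-9, 1 - 1e-9))
  ph0 <- atan2(mu0[2], mu0[1])
  par0 <- c(logit(clamp(best$vic)), logit(clamp(odi_from_kappa(best$kappa))),
            logit(clamp(best$viso)), th0, ph0)
  fit_dot <- variant == "ex_vivo"
  if (fit_dot) par0 <- c(par0, logit(clamp(best$vdot)))
  obj <- function(p) {
    mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    prm <- noddi_params(v_ic = inv_logit(p[1]),
                        kappa = kappa_from_odi(inv_logit(p[2])),
                        v_iso = inv_logit(p[3]),
                        v_dot = if (fit_dot) inv_logit(p[6]) else 0,
                        mu = mu, d_par = d_par, d_iso = d_iso)
    sum((y - predict_signal(prm, scheme, nq))^2)
  }
  # restarted simplex: rebuilding the simplex at the incumbent escapes the
  # collapse that stalls a single Nelder-Mead run; stops when a restart no
  # longer improves the residual
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  for (r in 1:4) {
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
    improved <- opt$value - opt2$value > 1e-12 * (1 + opt$value)
    if (opt2$value <= opt$value) opt <- opt2
    if (!improved) break
  }
  p <- opt$par
  mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
  out <- noddi_params(v_ic = inv_logit(p[1]),
                      kappa = kappa_from_odi(inv_logit(p[2])),
                      v_iso = inv_logit(p[3]),
                      v_dot = if (fit_dot) inv_logit(p[6]) else 0,
                      mu = mu, d_par = d_par, d_iso = d_iso)
  attr(out, "sse") <- opt$value
  attr(out, "convergence") <- opt$convergence
  out
}
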
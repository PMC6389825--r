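# shared fixtures, built fresh in code

# reduced-direction two-shell scheme for fast fitting tests
quick_scheme <- function() {
  make_noddi_scheme(n_b0 = 3, shells = list(c(800, 9), c(2000, 15)))
}

empty_substrate <- function(d = 0.6e-9) {
  substrate_spec(40, diffusivity = d)
}

# independent pair-counting oracle for Kendall's tau-b
brute_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx * sy > 0) C <- C + 1
    if (sx * sy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# independent spherical average of exp(-b * d * (g.n)^2) weighted by the
# Watson density: 2-D product quadrature (Gauss-Legendre in cos(theta),
# trapezoid in phi), no Bessel reduction
quadrature_stick_oracle <- function(kappa, bd, g, mu, n_t = 400,
                                    n_phi = 200) {
  gl <- pracma::gaussLegendre(n_t, -1, 1)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  num <- 0; den <- 0
  for (k in seq_len(n_phi)) {
    n_vec <- cbind(st * cos(phi[k]), st * sin(phi[k]), ct)
    w_un <- exp(kappa * (as.numeric(n_vec %*% mu)^2 - 1))  # scaled Watson
    att <- exp(-bd * as.numeric(n_vec %*% g)^2)
    num <- num + sum(gl$w * w_un * att)
    den <- den + sum(gl$w * w_un)
  }
  num / den
}
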
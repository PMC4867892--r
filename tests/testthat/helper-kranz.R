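# Shared fixtures and independent oracles.

# Independent re-implementation of the net-assimilation balance from the
# printed formulas, used as an oracle against the package's solver. Kept
# deliberately naive (no shortcuts shared with the implementation).
oracle_A_of_cm <- function(Cm, p) {
  I2 <- p$irradiance * p$absorptance * (1 - p$F_spec) / 2
  J <- if (p$Jm == 0 || I2 == 0) 0 else if (p$theta == 0) min(I2, p$Jm) else
    Re(polyroot(c(I2 * p$Jm, -(I2 + p$Jm), p$theta)))[
      which.min(Re(polyroot(c(I2 * p$Jm, -(I2 + p$Jm), p$theta))))]
  Wc <- if (p$Vm_max > 0) Cm * p$Vm_max / (Cm + p$Kc * (1 + p$O / p$Ko)) else 0
  Wj <- if (Cm > 0) J * Cm / (4 * Cm + 8 * p$gamma_star) else 0
  Vm <- min(Wc, Wj)
  Vp <- if (p$Vp_max > 0) min(Cm * p$Vp_max / (Cm + p$Kp), p$Vpr) else 0
  Fm <- if (p$gamma_star > 0) Vm * p$gamma_star / Cm else 0
  Vm - p$rm_fraction * p$Rd - Fm + Vp - p$phi * (Vp + p$beta * Fm)
}

# Dense-scan + bisection oracle for the implicit Cm balance.
oracle_solve_cm <- function(Ci, p, gm) {
  h <- function(cm) cm - Ci + oracle_A_of_cm(cm, p) / gm
  lo <- 0; hi <- Ci + 50
  grid <- seq(lo, hi, length.out = 201)
  v <- vapply(grid, h, 0)
  i <- which(v[-1] * v[-201] <= 0)[1]
  a <- grid[i]; b <- grid[i + 1]
  for (k in 1:80) {
    m <- (a + b) / 2
    if (h(a) * h(m) <= 0) b <- m else a <- m
  }
  (a + b) / 2
}

# Random but physically plausible parameter draw.
random_params <- function() {
  c4_on <- runif(1) < 0.6
  species_params("F. floridana",
    Vm_max = runif(1, 10, 150),
    Vp_max = if (c4_on) runif(1, 5, 100) else 0,
    Vpr = runif(1, 2, 50),
    Kc = runif(1, 300, 700), Ko = runif(1, 2e5, 6e5),
    Kp = runif(1, 50, 120),
    Rd = runif(1, 0.2, 2),
    Jm = runif(1, 50, 400),
    phi = if (c4_on) runif(1, 0, 0.6) else 0,
    c_gm = runif(1, 0.3, 1))
}

noiseless_dataset <- function(species = "F. floridana", ...) {
  generate_dataset(species_params(species), noise_sd_A = 0, noise_sd_D = 0,
                   seed = 1, ...)
}
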
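#' Mesophyll conductance as a function of intercellular pCO2
#'
#' Empirical CO2 response of mesophyll conductance,
#' `gm = 1e-6 * Ci^2 - 0.0013 * Ci + c`, with the curvature shared across
#' species and only the scaling constant `c` species-specific (measured
#' 0.666 for F. pringlei; assigned by model fitting for the others). The
#' polynomial has its vertex at `Ci = 650` ubar; by default it is evaluated
#' as printed over the whole range but floored at 0.01 mol m-2 s-1 bar-1.
#' `clamp = "vertex"` instead holds gm at its vertex value beyond 650 ubar,
#' reflecting the observation that gm stabilises at high pCO2.
#'
#' @param Ci Intercellular pCO2, ubar. Vectorized.
#' @param c_gm Species scaling constant, mol m-2 s-1 bar-1.
#' @param clamp `"floor"` (default) or `"vertex"`.
#' @return gm, mol m-2 s-1 bar-1.
#' @examples
#' gm_polynomial(0, 0.666)    # 0.666
#' gm_polynomial(400, 0.666)  # 0.306
#' @export
gm_polynomial <- function(Ci, c_gm, clamp = c("floor", "vertex")) {
  clamp <- match.arg(clamp)
  stopifnot(all(Ci >= 0), c_gm > 0)
  x <- Ci
  if (clamp == "vertex") x <- pmin(x, 650)
  pmax(1e-6 * x^2 - 0.0013 * x + c_gm, 0.01)
}

#' Estimate mesophyll conductance of a C3 leaf from coupled gas-exchange and
#' isotope measurements
#'
#' For a C3 leaf (no C4 cycle, `As = 0`) measured at low O2, the
#' biochemical fractionation is `Delta_bio = b3 - e * Rd / A` (all
#' respiration treated as mesophyll respiration), and the
#' mesophyll-conductance term is the only unknown left in the
#' discrimination model, giving the closed form
#'
#' `gm = ((1+t)/(1-t)) * (a_l + b_s - Delta_bio) * (A/Ca) /
#'   (Delta_obs - a'/(1-t) * (1 - Ci/Ca) - ((1+t)/(1-t)) * Delta_bio * Ci/Ca)`
#'
#' Observations isotopically lighter than the infinite-gm prediction have no
#' physical gm and raise an error; an observation exactly on the
#' infinite-gm prediction returns `Inf`.
#'
#' @param gas A gas-exchange record: one-row data.frame (or list) with
#'   `A, Ca, Ci, Cl, E, g_ac`. Multi-row frames are processed row-wise.
#' @param iso Matching isotope record(s) with `Ce, Co, delta_e, delta_o`,
#'   or a numeric vector of observed discriminations (permil).
#' @param params A `c3c4_params` object for a C3 species (`Vp_max = 0`).
#' @return gm estimate(s), mol m-2 s-1 bar-1.
#' @export
estimate_gm_c3 <- function(gas, iso, params) {
  if (params$Vp_max != 0) {
    stop("gm estimation from discrimination is only valid for C3 leaves ",
         "(Vp_max = 0)", call. = FALSE)
  }
  Delta_obs <- if (is.numeric(iso)) iso else delta_from_tdl(iso)
  A <- gas$A
  if (any(A <= 0)) stop("gm estimation requires A > 0", call. = FALSE)
  ap <- combined_a_prime(gas$Ca, gas$Cl, gas$Ci, params)
  t <- ternary_t(ap, gas$E, gas$g_ac)
  Delta_bio <- params$b3 - params$e_resp * params$Rd / A
  ai <- params$a_l + params$b_s
  num <- (1 + t) / (1 - t) * (ai - Delta_bio) * (A / gas$Ca)
  den <- Delta_obs - ap / (1 - t) * (1 - gas$Ci / gas$Ca) -
    (1 + t) / (1 - t) * Delta_bio * gas$Ci / gas$Ca
  gm <- ifelse(abs(den) < 1e-12, Inf, num / den)
  if (any(gm[is.finite(gm)] <= 0)) {
    stop("inconsistent measurement: observed discrimination above the ",
         "infinite-gm prediction implies non-positive gm", call. = FALSE)
  }
  gm
}

#' Fit the gm(Ci) scaling constant
#'
#' Least-squares fit of the species scaling constant `c` with the quadratic
#' and linear coefficients pinned at their shared values (1e-6, -0.0013),
#' i.e. `c = mean(gm - (1e-6 * Ci^2 - 0.0013 * Ci))`.
#'
#' @param Ci Intercellular pCO2 values, ubar.
#' @param gm Matching gm estimates, mol m-2 s-1 bar-1. Alternatively `Ci`
#'   may be a data.frame with columns `Ci` and `gm`.
#' @return A list with `c_gm`, `fitted`, `residuals` and `rmse`.
#' @export
fit_gm_polynomial <- function(Ci, gm = NULL) {
  if (is.data.frame(Ci)) {
    gm <- Ci$gm
    Ci <- Ci$Ci
  }
  ok <- is.finite(Ci) & is.finite(gm)
  Ci <- Ci[ok]; gm <- gm[ok]
  if (length(Ci) < 3L) {
    stop("at least 3 finite (Ci, gm) points are required", call. = FALSE)
  }
  base <- 1e-6 * Ci^2 - 0.0013 * Ci
  c_gm <- mean(gm - base)
  fitted <- base + c_gm
  res <- gm - fitted
  list(c_gm = c_gm, fitted = fitted, residuals = res,
       rmse = sqrt(mean(res^2)))
}
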
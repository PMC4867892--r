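#' Electron transport rate from irradiance
#'
#' Non-rectangular hyperbola light response: `J` is the smaller root of
#' `theta*J^2 - (I2 + Jmax)*J + I2*Jmax = 0`, where the useful absorbed
#' irradiance is `I2 = irradiance * absorptance * (1 - F_spec) / 2` (the
#' factor 2 splits excitation between the photosystems and `F_spec` corrects
#' for spectral quality).
#'
#' @param irradiance Incident irradiance, umol quanta m-2 s-1.
#' @param Jmax Maximum electron transport capacity, umol e- m-2 s-1.
#' @param absorptance Leaf absorptance (0-1).
#' @param F_spec Spectral-quality correction (0-1).
#' @param theta Empirical curvature factor in `[0, 1)`; `theta = 0` gives
#'   the Blackman limit `min(I2, Jmax)`.
#' @return Realized electron transport `J <= min(I2, Jmax)`,
#'   umol e- m-2 s-1.
#' @export
electron_transport <- function(irradiance, Jmax, absorptance = 0.8,
                               F_spec = 0.15, theta = 0.1) {
  stopifnot(Jmax >= 0, irradiance >= 0, theta >= 0, theta < 1)
  I2 <- irradiance * absorptance * (1 - F_spec) / 2
  if (Jmax == 0 || I2 == 0) return(0)
  if (theta == 0) return(min(I2, Jmax))
  disc <- (I2 + Jmax)^2 - 4 * theta * I2 * Jmax
  if (disc < 0) {
    stop("negative discriminant in the light-response quadratic; check theta",
         call. = FALSE)
  }
  ((I2 + Jmax) - sqrt(disc)) / (2 * theta)
}

#' Rubisco-limited mesophyll carboxylation
#'
#' Michaelis-Menten rate with competitive O2 inhibition:
#' `Wc = Cm * Vm_max / (Cm + Kc * (1 + O/Ko))`.
#'
#' @param Cm Mesophyll pCO2, ubar.
#' @param params A `c3c4_params` object.
#' @return `Wc`, umol m-2 s-1. Vectorized over `Cm`.
#' @export
rubisco_limited_vm <- function(Cm, params) {
  stopifnot(all(Cm >= 0))
  if (params$Vm_max == 0) return(rep(0, length(Cm)))
  Cm * params$Vm_max / (Cm + params$Kc * (1 + params$O / params$Ko))
}

#' PEP carboxylation rate
#'
#' Michaelis-Menten PEPC rate capped by PEP regeneration:
#' `Vp = min(Cm * Vp_max / (Cm + Kp), Vpr)`; identically 0 when the C4
#' cycle is disabled (`Vp_max = 0`).
#'
#' @inheritParams rubisco_limited_vm
#' @return `Vp`, umol m-2 s-1. Vectorized over `Cm`.
#' @export
pepc_rate <- function(Cm, params) {
  stopifnot(all(Cm >= 0))
  if (params$Vp_max == 0) return(rep(0, length(Cm)))
  pmin(Cm * params$Vp_max / (Cm + params$Kp), params$Vpr)
}

#' Evaluate the two-compartment assimilation model at a known mesophyll pCO2
#'
#' The leaf is split into mesophyll and bundle sheath. PEPC fixes CO2 in the
#' mesophyll and delivers it to the bundle sheath at rate `Vp` (plus the
#' fraction `beta` of mesophyll photorespiration `Fm` released there); a
#' fraction `phi` (leakiness) leaks back, `L = phi * (Vp + beta * Fm)`.
#' Mesophyll Rubisco carboxylates at
#' `Vm = min(Wc, Wj)` where `Wj = J * Cm / (4 Cm + 8 gamma_star)` is the
#' electron-transport-limited rate using the mesophyll allocation `Jm`.
#' Net assimilation is
#' `A = Vm - Rm - Fm + Vp - L` with `Rm = rm_fraction * Rd`; the
#' bundle-sheath share is `As = Vp + beta*Fm - L` and the mesophyll share is
#' defined as `Am = A - As`, which enforces `A = As + Am` exactly.
#' Bundle-sheath photorespiration `Fs` is taken as 0 (the regime in which
#' the model is used keeps photorespiration negligible).
#'
#' @param Cm Mesophyll pCO2, ubar (scalar).
#' @param params A `c3c4_params` object.
#' @return A one-row data.frame (model state) with columns `Cm, J, Wc, Wj,
#'   Vm, Vp, Fm, Fs, L, As, Am, A, bs_share` (`bs_share = 100 * As / A`, NA
#'   when `A <= 0`).
#' @export
net_assimilation_given_cm <- function(Cm, params) {
  st <- .state_at_cm(Cm, params)
  as.data.frame(st)
}

# Scalar fast path shared by the implicit solver and the public state
# constructor; returns a plain named list.
.state_at_cm <- function(Cm, params, J = NULL) {
  stopifnot(length(Cm) == 1L, Cm >= 0)
  if (Cm == 0 && params$gamma_star > 0) {
    stop("photorespiration is singular at Cm = 0 (gamma_star > 0)",
         call. = FALSE)
  }
  if (is.null(J)) {
    J <- electron_transport(params$irradiance, params$Jm, params$absorptance,
                            params$F_spec, params$theta)
  }
  Wc <- if (params$Vm_max == 0) 0 else
    Cm * params$Vm_max / (Cm + params$Kc * (1 + params$O / params$Ko))
  Wj <- if (Cm > 0) J * Cm / (4 * Cm + 8 * params$gamma_star) else 0
  Vm <- min(Wc, Wj)
  Vp <- if (params$Vp_max == 0) 0 else
    min(Cm * params$Vp_max / (Cm + params$Kp), params$Vpr)
  Fm <- if (params$gamma_star > 0) Vm * params$gamma_star / Cm else 0
  Fs <- 0
  supply <- Vp + params$beta * Fm
  L <- params$phi * supply
  Rm <- params$rm_fraction * params$Rd
  A <- Vm - Rm - Fm + Vp - L
  As <- supply - L
  Am <- A - As
  list(Cm = Cm, J = J, Wc = Wc, Wj = Wj, Vm = Vm, Vp = Vp,
       Fm = Fm, Fs = Fs, L = L, As = As, Am = Am, A = A,
       bs_share = if (A > 0) 100 * As / A else NA_real_)
}

# Net assimilation only, for the root finder.
.A_at_cm <- function(Cm, params, J) {
  Wc <- if (params$Vm_max == 0) 0 else
    Cm * params$Vm_max / (Cm + params$Kc * (1 + params$O / params$Ko))
  Wj <- if (Cm > 0) J * Cm / (4 * Cm + 8 * params$gamma_star) else 0
  Vm <- min(Wc, Wj)
  Vp <- if (params$Vp_max == 0) 0 else
    min(Cm * params$Vp_max / (Cm + params$Kp), params$Vpr)
  Fm <- if (params$gamma_star > 0) Vm * params$gamma_star / Cm else 0
  supply <- Vp + params$beta * Fm
  Vm - params$rm_fraction * params$Rd - Fm + Vp - params$phi * supply
}

# Resolve a gm specification (scalar, Inf, function of Ci, or NULL meaning
# the species gm(Ci) polynomial) to a value at one Ci.
.gm_at <- function(gm, Ci, params) {
  if (is.null(gm)) return(gm_polynomial(Ci, params$c_gm))
  if (is.function(gm)) return(gm(Ci))
  stopifnot(is.numeric(gm), length(gm) == 1L)
  gm
}

#' Solve the coupled mesophyll CO2 / assimilation balance
#'
#' The mesophyll pCO2 is tied to assimilation through the diffusion
#' relation `Cm = Ci - A/gm`; since `A` depends on `Cm`, the model is
#' implicit. The root of `h(Cm) = Cm - Ci + A(Cm)/gm` is bracketed on
#' `[0, Ci + 50]` and solved by Brent's method to an absolute residual below
#' 1e-6 ubar (`h` is monotone for physical parameters; bracketing is robust
#' at the Vp/Vpr and Wc/Wj kinks).
#'
#' @param Ci Intercellular pCO2, ubar (scalar).
#' @param params A `c3c4_params` object.
#' @param gm Mesophyll conductance: a positive scalar (mol m-2 s-1 bar-1),
#'   `Inf` (then `Cm = Ci` exactly), a function of `Ci`, or `NULL` to use
#'   the species gm(Ci) polynomial [gm_polynomial()] with `params$c_gm`.
#' @return A one-row data.frame: the model state of
#'   [net_assimilation_given_cm()] with `Ci` and `gm` columns prepended.
#' @export
solve_assimilation <- function(Ci, params, gm = NULL) {
  stopifnot(length(Ci) == 1L, Ci >= 0)
  gm_val <- .gm_at(gm, Ci, params)
  if (!is.infinite(gm_val) && gm_val <= 0) {
    stop("gm must be positive (or Inf)", call. = FALSE)
  }
  J <- electron_transport(params$irradiance, params$Jm, params$absorptance,
                          params$F_spec, params$theta)
  if (is.infinite(gm_val)) {
    st <- .state_at_cm(Ci, params, J)
    return(as.data.frame(c(list(Ci = Ci, gm = Inf), st)))
  }
  h <- function(cm) cm - Ci + .A_at_cm(cm, params, J) / gm_val
  lo <- if (params$gamma_star > 0) 1e-9 else 0
  hi <- Ci + 50
  flo <- h(lo); fhi <- h(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop(sprintf(paste0("no root of the Cm balance in [%g, %g] ",
                        "(h = %g and %g at the ends)"), lo, hi, flo, fhi),
         call. = FALSE)
  }
  root <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
  st <- .state_at_cm(root, params, J)
  as.data.frame(c(list(Ci = Ci, gm = gm_val), st))
}

#' Assimilation response curve over a Ci grid
#'
#' Element-wise [solve_assimilation()] preserving grid order.
#'
#' @param Ci_grid Numeric vector of intercellular pCO2 values, ubar.
#' @inheritParams solve_assimilation
#' @return A data.frame with one row (model state) per grid point; empty
#'   grid gives a zero-row frame.
#' @export
assimilation_curve <- function(Ci_grid, params, gm = NULL) {
  if (length(Ci_grid) == 0L) {
    return(solve_assimilation(100, params, gm)[0, , drop = FALSE])
  }
  do.call(rbind, lapply(Ci_grid, solve_assimilation, params = params,
                        gm = gm))
}

#' CO2 compensation point
#'
#' The intercellular pCO2 at which net assimilation is zero. Given a
#' parameter set, the zero crossing of the modeled `A(Ci)` is bracketed on
#' `[0, 200]` ubar and solved to `|A| < 1e-6` umol m-2 s-1. Given a
#' data.frame of measured `(Ci, A)` pairs, the linear-interpolation zero
#' crossing is returned instead (see [gamma_from_aci()]).
#'
#' @param params A `c3c4_params` object, or a data.frame with `Ci` and `A`
#'   columns.
#' @inheritParams solve_assimilation
#' @param bracket Search interval for the model-based root, ubar.
#' @return Gamma, ubar.
#' @export
compensation_point <- function(params, gm = NULL, bracket = c(0, 200)) {
  if (is.data.frame(params)) return(gamma_from_aci(params))
  f <- function(ci) solve_assimilation(ci, params, gm)$A
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo == 0) return(bracket[1])
  if (flo * fhi > 0) {
    stop(sprintf(paste0("A(Ci) does not change sign on [%g, %g] ubar ",
                        "(A = %g and %g); widen the bracket"),
                 bracket[1], bracket[2], flo, fhi), call. = FALSE)
  }
  stats::uniroot(f, bracket, tol = 1e-9)$root
}
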
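#' Combined fractionation during diffusion through boundary layer and air
#'
#' Weighted mean of the boundary-layer (`a_b = 2.9` permil) and free-air
#' (`a = 4.4` permil) diffusional fractionations, weighted by the CO2 drops
#' across each path:
#' `a' = (a_b * (Ca - Cl) + a * (Cl - Ci)) / (Ca - Ci)`.
#'
#' @param Ca,Cl,Ci Ambient, leaf-surface and intercellular pCO2, ubar.
#' @param params A `c3c4_params` object supplying `a` and `a_b`.
#' @return `a'`, permil. Vectorized.
#' @export
combined_a_prime <- function(Ca, Cl, Ci, params = species_params("F. pringlei")) {
  if (any(Ca == Ci)) {
    stop("a' is undefined when Ca = Ci (zero total CO2 drop)", call. = FALSE)
  }
  (params$a_b * (Ca - Cl) + params$a * (Cl - Ci)) / (Ca - Ci)
}

#' Ternary correction factor
#'
#' The transpiration stream interacts with CO2 diffusion through the
#' stomata; the resulting ternary correction is
#' `t = (1 + a') * E / (2 * g_ac)` with `a'` in fractional (not permil)
#' units. For physical inputs `0 <= t << 1`.
#'
#' @param a_prime Combined diffusional fractionation, permil.
#' @param E Transpiration rate, mol m-2 s-1.
#' @param g_ac Total conductance to CO2 (boundary layer + stomata),
#'   mol m-2 s-1 bar-1.
#' @return `t`, dimensionless. Vectorized.
#' @export
ternary_t <- function(a_prime, E, g_ac) {
  if (any(g_ac <= 0)) stop("g_ac must be > 0", call. = FALSE)
  if (any(E < 0)) stop("E must be >= 0", call. = FALSE)
  (1 + a_prime / 1000) * E / (2 * g_ac)
}

#' Biochemical fractionation of net CO2 uptake (forward model)
#'
#' Net discrimination attributable to carboxylation, decarboxylation,
#' respiration and leakage biochemistry, for a model state with net
#' assimilation `A`, bundle-sheath assimilation `As`, PEPC rate `Vp` and
#' photorespiration rates `Fm`, `Fs`:
#'
#' `Delta_bio = (b3 - (f*Fm + e*Rm)/A)
#'   + (As/A) * ((b3 - s)*phi + (b4 - b3)*(Vp - f*beta*Fm)/(Vp + beta*Fm))
#'   - (f*Fs + e*Rs)/A * phi`
#'
#' where `b3` is the Rubisco fractionation, `b4` the combined C4-cycle
#' fractionation, `s` the leakage fractionation, `e` the apparent
#' respiratory offset and `f` the photorespiratory fractionation. With
#' photorespiration negligible (`Fm = Fs = 0`, the low-O2 regime) this
#' reduces exactly to
#' `Delta_bio = (b3 - e*Rm/A) + (As/A)*((b3 - s)*phi + (b4 - b3)) - e*Rs*phi/A`.
#'
#' @param state A model state (one-row data.frame from
#'   [solve_assimilation()] / [net_assimilation_given_cm()]), or any list
#'   with elements `A`, `As`, `Vp`, `Fm`, `Fs`.
#' @param params A `c3c4_params` object.
#' @return `Delta_bio`, permil.
#' @export
delta_bio_forward <- function(state, params) {
  A <- state$A; As <- state$As; Vp <- state$Vp
  Fm <- state$Fm; Fs <- state$Fs
  if (any(A <= 0)) {
    stop("Delta_bio is undefined for A <= 0", call. = FALSE)
  }
  Rm <- params$rm_fraction * params$Rd
  Rs <- params$Rd - Rm
  supply <- Vp + params$beta * Fm
  c4term <- ifelse(supply > 0,
                   (params$b4 - params$b3) *
                     (Vp - params$f_pr * params$beta * Fm) / supply,
                   0)
  if (any(supply == 0 & As != 0)) {
    stop("inconsistent state: As != 0 with no bundle-sheath CO2 supply",
         call. = FALSE)
  }
  (params$b3 - (params$f_pr * Fm + params$e_resp * Rm) / A) +
    (As / A) * ((params$b3 - params$s_leak) * params$phi + c4term) -
    (params$f_pr * Fs + params$e_resp * Rs) / A * params$phi
}

#' Observed-scale discrimination with mesophyll conductance and ternary
#' effects
#'
#' Maps the biochemical fractionation onto the discrimination measurable at
#' the leaf surface, accounting for diffusion in air and boundary layer
#' (`a'`), dissolution and liquid-phase diffusion (`a_l + b_s`) through a
#' finite mesophyll conductance, and the ternary transpiration correction:
#'
#' `Delta = a'/(1-t) + ((1+t)/(1-t)) * (a_l + b_s - Delta_bio) * A/(gm*Ca)
#'   + ((1+t)*Delta_bio - a') / (1-t) * Ci/Ca`
#'
#' @param Delta_bio Biochemical fractionation, permil.
#' @param A Net assimilation, umol m-2 s-1.
#' @param gm Mesophyll conductance, mol m-2 s-1 bar-1 (may be `Inf`).
#' @param Ca,Ci Ambient and intercellular pCO2, ubar.
#' @param a_prime Combined diffusional fractionation, permil.
#' @param t Ternary factor from [ternary_t()].
#' @param params A `c3c4_params` object supplying `a_l` and `b_s`.
#' @return `Delta`, permil. Vectorized.
#' @export
delta_model <- function(Delta_bio, A, gm, Ca, Ci, a_prime, t, params) {
  if (any(t >= 1)) stop("ternary factor t must be < 1", call. = FALSE)
  if (any(Ca <= 0)) stop("Ca must be > 0", call. = FALSE)
  ai <- params$a_l + params$b_s
  drawdown <- ifelse(is.infinite(gm), 0, A / (gm * Ca))
  a_prime / (1 - t) +
    (1 + t) / (1 - t) * (ai - Delta_bio) * drawdown +
    ((1 + t) * Delta_bio - a_prime) / (1 - t) * Ci / Ca
}

#' Invert the discrimination model for the biochemical fractionation
#'
#' Exact algebraic inverse of [delta_model()]: given an observed
#' discrimination and the gas-exchange state, recover
#'
#' `Delta_bio = (Delta - a'/(1-t) * (Ca-Ci)/Ca
#'              - ((1+t)/(1-t)) * (a_l + b_s) * A/(gm*Ca))
#'             / (((1+t)/(1-t)) * (Ci/Ca - A/(gm*Ca)))`
#'
#' The denominator is proportional to `Cm/Ca` and must be nonzero.
#'
#' @param Delta Observed discrimination, permil.
#' @inheritParams delta_model
#' @return `Delta_bio`, permil. Vectorized.
#' @export
delta_bio_invert <- function(Delta, A, gm, Ca, Ci, a_prime, t, params) {
  if (any(t >= 1)) stop("ternary factor t must be < 1", call. = FALSE)
  ai <- params$a_l + params$b_s
  drawdown <- ifelse(is.infinite(gm), 0, A / (gm * Ca))
  den <- (1 + t) / (1 - t) * (Ci / Ca - drawdown)
  if (any(abs(den) < 1e-14)) {
    stop("cannot invert: Ci/Ca - A/(gm*Ca) is zero (mesophyll pCO2 = 0)",
         call. = FALSE)
  }
  (Delta - a_prime / (1 - t) * (Ca - Ci) / Ca -
     (1 + t) / (1 - t) * ai * drawdown) / den
}

#' Observed discrimination from a two-point chamber measurement
#'
#' Standard open-chamber (TDL) formula: with `xi = Ce / (Ce - Co)`,
#' `Delta_obs = 1000 * xi * (delta_o - delta_e) /
#'   (1000 + delta_o - xi * (delta_o - delta_e))` permil,
#' where `Ce, Co` and `delta_e, delta_o` are the CO2 partial pressure and
#' delta13C of the air entering and leaving the chamber.
#'
#' @param Ce,Co Entering / outgoing pCO2, ubar. Alternatively `Ce` may be a
#'   data.frame with columns `Ce, Co, delta_e, delta_o`.
#' @param delta_e,delta_o Entering / outgoing delta13C, permil.
#' @return `Delta_obs`, permil. Vectorized.
#' @export
delta_from_tdl <- function(Ce, Co = NULL, delta_e = NULL, delta_o = NULL) {
  if (is.data.frame(Ce)) {
    d <- Ce
    Ce <- d$Ce; Co <- d$Co; delta_e <- d$delta_e; delta_o <- d$delta_o
  }
  if (any(Ce == Co)) {
    stop("Ce equals Co: no CO2 drawdown across the chamber, xi undefined",
         call. = FALSE)
  }
  xi <- Ce / (Ce - Co)
  num <- xi * (delta_o - delta_e)
  1000 * num / (1000 + delta_o - num)
}

#' Theoretical discrimination reference lines
#'
#' Simple-model endmember predictions of `Delta` as a function of `Ci/Ca`
#' (infinite mesophyll conductance, no ternary correction):
#' C3 leaves `Delta = 4.4 + x * (29 - 4.4)`; C4 leaves
#' `Delta = 4.4 + x * (-5.7 - 4.4 + phi * (29 - 1.8))` for leakiness `phi`.
#'
#' @param x `Ci/Ca` ratio(s) in `[0, 1]`.
#' @param phi Leakiness in `[0, 1]` (C4 line only).
#' @return `Delta`, permil. Vectorized.
#' @export
theoretical_c3_delta <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  4.4 + x * (29 - 4.4)
}

#' @rdname theoretical_c3_delta
#' @export
theoretical_c4_delta <- function(x, phi) {
  stopifnot(all(x >= 0 & x <= 1), all(phi >= 0 & phi <= 1))
  4.4 + x * (-5.7 - 4.4 + phi * (29 - 1.8))
}
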
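#' Species parameter sets for the two-compartment photosynthesis model
#'
#' A `c3c4_params` object collects every constant needed to evaluate the
#' coupled assimilation / discrimination model for one leaf: Michaelis-Menten
#' kinetics of Rubisco and PEPC, electron-transport capacity, respiration,
#' isotopic fractionation factors and the mesophyll-conductance scaling
#' constant. Partial pressures are in ubar, fluxes in umol m-2 s-1,
#' conductances in mol m-2 s-1 bar-1 and fractionations in permil, so that
#' `A/gm` is directly in ubar.
#'
#' `species_params()` returns one of the published presets for the four
#' Flaveria species (plus the two counterfactual columns used for hypothesis
#' testing: F. brownii refitted as a strict C4 plant and F. floridana as a
#' strict C3 plant), optionally with fields overridden.
#'
#' A disabled C4 cycle is encoded by `Vp_max = 0` (with `phi`, `b4` and
#' `s_leak` stored as 0 and unused), never by missing values, so a C3 leaf is
#' a strict special case of the same model.
#'
#' @param species Preset label; one of `"F. pringlei"`, `"F. bidentis"`,
#'   `"F. brownii"`, `"F. brownii (strict C4)"`, `"F. floridana"`,
#'   `"F. floridana (strict C3)"`. Matching is case-insensitive and ignores
#'   punctuation, so `"floridana"` works.
#' @param ... Named overrides for any field of the parameter set.
#' @return An object of class `c3c4_params`: a named list with fields
#'   `name`, `a`, `a_b`, `a_l`, `b_s`, `b3`, `b4`, `s_leak`, `e_resp`,
#'   `f_pr`, `beta`, `Vm_max`, `Vp_max`, `Vpr`, `Kc`, `Ko`, `Kp`, `Rd`,
#'   `rm_fraction`, `Jt`, `Jm`, `theta`, `absorptance`, `F_spec`, `phi`,
#'   `c_gm`, `O`, `irradiance`, `gamma_star`.
#' @examples
#' p <- species_params("F. floridana")
#' p$Vp_max  # 15 umol m-2 s-1
#' p$phi     # leakiness 0.40
#' @export
species_params <- function(species, ...) {
  key <- .canon_label(species)
  canon <- vapply(names(.table1), .canon_label, "")
  idx <- match(key, canon)
  if (is.na(idx)) {
    # unambiguous abbreviation; shortest label wins so "floridana" means the
    # base species column, not its strict-C3 counterfactual
    hits <- grep(key, canon, fixed = TRUE)
    if (length(hits) >= 1L && nzchar(key)) {
      idx <- hits[which.min(nchar(canon[hits]))]
    }
  }
  if (is.na(idx)) {
    stop("unknown species preset ", sQuote(species), "; valid labels are: ",
         paste(sQuote(names(.table1)), collapse = ", "), call. = FALSE)
  }
  p <- .table1[[idx]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
}

.canon_label <- function(x) {
  gsub("[^a-z0-9]+", "", tolower(x))
}

# Common constants shared by all presets: diffusional and biochemical
# fractionations, light-response shape, measurement conditions (19 mbar O2,
# 1500 umol quanta m-2 s-1, photorespiration negligible).
.preset <- function(name, Vm_max, Vp_max, Vpr, Kc, Ko, Kp, Rd, Jt, Jm,
                    phi, c_gm, e_resp, b4 = -5.7, s_leak = 1.8) {
  structure(list(
    name = name,
    a = 4.4, a_b = 2.9, a_l = 0.7, b_s = 1.1,
    b3 = 29, b4 = b4, s_leak = s_leak, e_resp = e_resp, f_pr = 11,
    beta = 1,
    Vm_max = Vm_max, Vp_max = Vp_max, Vpr = Vpr,
    Kc = Kc, Ko = Ko, Kp = Kp,
    Rd = Rd, rm_fraction = 0.5,
    Jt = Jt, Jm = Jm, theta = 0.1, absorptance = 0.8, F_spec = 0.15,
    phi = phi, c_gm = c_gm,
    O = 19000, irradiance = 1500, gamma_star = 0
  ), class = "c3c4_params")
}

.table1 <- list(
  "F. pringlei" = .preset("F. pringlei",
    Vm_max = 60, Vp_max = 0, Vpr = 0, Kc = 359, Ko = 528000, Kp = 0,
    Rd = 0.6, Jt = 120, Jm = 120, phi = 0, c_gm = 0.666, e_resp = 2.91,
    b4 = 0, s_leak = 0),
  "F. bidentis" = .preset("F. bidentis",
    Vm_max = 0, Vp_max = 90, Vpr = 36, Kc = 605, Ko = 507000, Kp = 80,
    Rd = 0.4, Jt = 400, Jm = 0, phi = 0.28, c_gm = 0.8, e_resp = 3.54),
  "F. brownii" = .preset("F. brownii",
    Vm_max = 15, Vp_max = 80, Vpr = 32, Kc = 383, Ko = 300000, Kp = 80,
    Rd = 1.3, Jt = 440, Jm = 40, phi = 0.21, c_gm = 0.666, e_resp = 3.51),
  "F. brownii (strict C4)" = .preset("F. brownii (strict C4)",
    Vm_max = 0, Vp_max = 80, Vpr = 50, Kc = 383, Ko = 300000, Kp = 80,
    Rd = 1.3, Jt = 700, Jm = 0, phi = 0.3, c_gm = 0.666, e_resp = 3.51),
  "F. floridana" = .preset("F. floridana",
    Vm_max = 90, Vp_max = 15, Vpr = 8, Kc = 395, Ko = 544000, Kp = 80,
    Rd = 1.7, Jt = 250, Jm = 200, phi = 0.40, c_gm = 0.78, e_resp = 3.72),
  "F. floridana (strict C3)" = .preset("F. floridana (strict C3)",
    Vm_max = 130, Vp_max = 0, Vpr = 0, Kc = 395, Ko = 544000, Kp = 0,
    Rd = 1.7, Jt = 0, Jm = 240, phi = 0, c_gm = 0.78, e_resp = 3.72,
    b4 = 0, s_leak = 0)
)

#' Validate a parameter set
#'
#' Checks physical constraints: non-negative rates, Michaelis constants and
#' conductance constants; `phi`, `beta` in `[0, 1]`; `theta` in `[0, 1)`;
#' `rm_fraction` in `(0, 1]`; a positive `Kp` whenever PEPC is active and
#' positive `Kc`, `Ko` whenever mesophyll Rubisco is active.
#'
#' @param p A `c3c4_params` object or a plain named list with the same
#'   fields.
#' @return The validated object, invisibly classed as `c3c4_params`.
#' @export
validate_params <- function(p) {
  need <- names(.table1[[1]])
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("parameter set is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- setdiff(need, "name")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("parameter ", sQuote(f), " must be a single finite number",
           call. = FALSE)
    }
  }
  nonneg <- c("Vm_max", "Vp_max", "Vpr", "Kc", "Ko", "Kp", "Rd", "Jt", "Jm",
              "c_gm", "O", "irradiance", "gamma_star", "absorptance")
  for (f in nonneg) {
    if (p[[f]] < 0) stop("parameter ", sQuote(f), " must be >= 0",
                         call. = FALSE)
  }
  if (p$phi < 0 || p$phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  if (p$beta < 0 || p$beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (p$theta < 0 || p$theta >= 1) stop("theta must lie in [0, 1)",
                                        call. = FALSE)
  if (p$rm_fraction <= 0 || p$rm_fraction > 1) {
    stop("rm_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (p$Vp_max > 0 && p$Kp <= 0) {
    stop("Kp must be > 0 when the C4 cycle is active (Vp_max > 0)",
         call. = FALSE)
  }
  if (p$Vm_max > 0 && (p$Kc <= 0 || p$Ko <= 0)) {
    stop("Kc and Ko must be > 0 when mesophyll Rubisco is active",
         call. = FALSE)
  }
  class(p) <- "c3c4_params"
  p
}

#' @export
print.c3c4_params <- function(x, ...) {
  cat("Leaf parameter set:", x$name, "\n")
  cat(sprintf("  Vm_max %g, Vp_max %g, Vpr %g umol m-2 s-1; Rd %g\n",
              x$Vm_max, x$Vp_max, x$Vpr, x$Rd))
  cat(sprintf("  Kc %g, Ko %g, Kp %g ubar; Jt %g, Jm %g; theta %g\n",
              x$Kc, x$Ko, x$Kp, x$Jt, x$Jm, x$theta))
  cat(sprintf("  phi %g, c_gm %g; b3 %g, b4 %g, s %g, e %g permil\n",
              x$phi, x$c_gm, x$b3, x$b4, x$s_leak, x$e_resp))
  cat(sprintf("  O %g ubar, irradiance %g, gamma_star %g ubar\n",
              x$O, x$irradiance, x$gamma_star))
  invisible(x)
}

#' Nonenzymatic CO2 hydration rate constant
#'
#' First-order rate constant of the uncatalysed CO2 hydration reaction as a
#' function of pH, `kc = 6.22e-11 / [H+] + 3.8e-2` with `[H+] = 10^-pH`,
#' used to express carbonic-anhydrase activity relative to the background
#' reaction. At the cytosolic pH of 7.4 this gives 0.0396 s-1; at the
#' chloroplast-stroma pH of 8.0, 0.0442 s-1.
#'
#' @param pH Scalar or vector pH, in (0, 14).
#' @return Rate constant(s) in s-1.
#' @examples
#' ca_rate_constant(7.4)
#' ca_rate_constant(8.0)
#' @export
ca_rate_constant <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14)) {
    stop("pH must be finite and strictly between 0 and 14", call. = FALSE)
  }
  6.22e-11 / 10^(-pH) + 3.8e-2
}

#' Apparent respiratory fractionation offset
#'
#' During online measurements the CO2 respired by the leaf derives from
#' carbohydrate fixed under growth conditions, while the chamber air comes
#' from a cylinder with a different isotopic composition. Assuming no
#' fractionation during mitochondrial respiration itself, the apparent
#' respiratory fractionation is the offset
#' `e = delta13C_cylinder - delta13C_atmosphere`.
#'
#' @param delta_cylinder delta13C of the measurement cylinder CO2, permil.
#' @param delta_atmosphere delta13C of the growth atmosphere, permil
#'   (default -8).
#' @return The offset `e`, permil.
#' @examples
#' respiration_offset(-4.12)  # 3.88
#' @export
respiration_offset <- function(delta_cylinder, delta_atmosphere = -8) {
  if (!all(is.finite(delta_cylinder)) || !all(is.finite(delta_atmosphere))) {
    stop("isotopic compositions must be finite", call. = FALSE)
  }
  delta_cylinder - delta_atmosphere
}
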
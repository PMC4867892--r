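#' Generate a coupled gas-exchange + isotope dataset
#'
#' Emulates one online measurement run: the chamber reference pCO2 is
#' stepped through `ca_grid` (default the nine-step sequence
#' 392, 980, 686, 490, 294, 196, 98, 49, 392 ubar used in the measurement
#' protocol), stomata are emulated by a fixed operating ratio
#' `Ci = ci_over_ca * Ca` (the fit never uses the stomatal rule, only the
#' resulting Ci, so this is the minimal sufficient emulation), the leaf
#' surface sits midway (`Cl = (Ca + Ci)/2`), and the forward model supplies
#' A and Delta at each step. Transpiration and conductances are derived
#' consistently from the modeled fluxes: `g_ac = A / (Ca - Ci)`,
#' `gs = gb = 2 g_ac`, and `E = 1.6 * gs * 0.01` (water/CO2 diffusivity
#' ratio 1.6 at a vapour-pressure deficit of 10 mbar bar-1).
#'
#' Independent homoscedastic Gaussian noise is added to A and Delta
#' (defaults 0.5 umol m-2 s-1 and 0.3 permil, resembling the
#' between-replicate scatter of online TDL systems). The TDL record is then
#' synthesised to be exactly consistent with the noisy discrimination:
#' `Ce = Ca`, the chamber drawdown is `Co = Ce - 2 * A` (2 ubar per
#' umol m-2 s-1, a typical chamber/flow combination), `delta_e` is the
#' cylinder composition, and `delta_o` is solved so that [delta_from_tdl()]
#' returns the noisy Delta exactly. Noiseless truth states are stored
#' alongside.
#'
#' @param params A `c3c4_params` object (the generating "species").
#' @param ca_grid Reference pCO2 sequence, ubar.
#' @param ci_over_ca Operating Ci/Ca ratio (default 0.7, C3-like; use about
#'   0.4 for C4-like leaves).
#' @param noise_sd_A,noise_sd_D Noise standard deviations for A
#'   (umol m-2 s-1) and Delta (permil); 0 for noiseless data.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @param delta_cylinder delta13C of the chamber supply cylinder, permil;
#'   default `params$e_resp - 8` so the respiratory offset is internally
#'   consistent with the parameter set.
#' @param gm gm specification as in [solve_assimilation()].
#' @return An object of class `c3c4_dataset`: list with `params, ca_grid,
#'   ci_over_ca, noise_sd_A, noise_sd_D, seed, gas, iso, truth`.
#' @export
generate_dataset <- function(params,
                             ca_grid = c(392, 980, 686, 490, 294, 196,
                                         98, 49, 392),
                             ci_over_ca = 0.7,
                             noise_sd_A = 0.5, noise_sd_D = 0.3,
                             seed = NULL,
                             delta_cylinder = params$e_resp - 8,
                             gm = NULL) {
  if (length(ca_grid) == 0L) stop("ca_grid must be non-empty", call. = FALSE)
  stopifnot(noise_sd_A >= 0, noise_sd_D >= 0, ci_over_ca > 0,
            ci_over_ca < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(ca_grid)
  Ca <- as.numeric(ca_grid)
  Ci <- ci_over_ca * Ca
  Cl <- (Ca + Ci) / 2

  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- tryCatch(solve_assimilation(Ci[i], params, gm),
                   error = function(e) {
                     stop("forward model failed at set-point ", i,
                          " (Ca = ", Ca[i], " ubar): ",
                          conditionMessage(e), call. = FALSE)
                   })
    st
  }))
  A <- truth$A
  if (any(A <= 0)) {
    stop("forward model gives A <= 0 at set-point(s) ",
         paste(which(A <= 0), collapse = ", "),
         "; the chamber emulation needs net uptake", call. = FALSE)
  }
  g_ac <- A / (Ca - Ci)
  gs <- 2 * g_ac
  gb <- 2 * g_ac
  E <- 1.6 * gs * 0.01
  ap <- combined_a_prime(Ca, Cl, Ci, params)
  t <- ternary_t(ap, E, g_ac)
  Delta_bio <- delta_bio_forward(truth, params)
  Delta <- delta_model(Delta_bio, A, truth$gm, Ca, Ci, ap, t, params)
  truth <- cbind(truth, a_prime = ap, t = t, Delta_bio = Delta_bio,
                 Delta = Delta)

  A_obs <- A + stats::rnorm(n, 0, noise_sd_A)
  D_obs <- Delta + stats::rnorm(n, 0, noise_sd_D)

  gas <- data.frame(set_point = seq_len(n), A = A_obs, Ca = Ca, Ci = Ci,
                    Cl = Cl, E = E, gs = gs, gb = gb, g_ac = g_ac,
                    pO2 = params$O, T_leaf = 25)
  Ce <- Ca
  Co <- Ce - 2 * A_obs
  small <- abs(Ce - Co) < 0.5
  Co[small] <- Ce[small] - 0.5
  xi <- Ce / (Ce - Co)
  delta_o <- (1000 * D_obs + xi * delta_cylinder * (1000 + D_obs)) /
    (xi * (1000 + D_obs) - D_obs)
  iso <- data.frame(set_point = seq_len(n), Ce = Ce, Co = Co,
                    delta_e = delta_cylinder, delta_o = delta_o,
                    xi = xi, Delta_obs = D_obs)

  structure(list(params = params, ca_grid = Ca, ci_over_ca = ci_over_ca,
                 noise_sd_A = noise_sd_A, noise_sd_D = noise_sd_D,
                 seed = seed, gas = gas, iso = iso, truth = truth),
            class = "c3c4_dataset")
}

#' @export
print.c3c4_dataset <- function(x, ...) {
  cat("Synthetic coupled dataset:", x$params$name, "\n")
  cat(sprintf("  %d set-points (Ca %g..%g ubar), Ci/Ca = %g\n",
              length(x$ca_grid), min(x$ca_grid), max(x$ca_grid),
              x$ci_over_ca))
  cat(sprintf("  noise sd: A %g, Delta %g; seed %s\n", x$noise_sd_A,
              x$noise_sd_D, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the two measurement CSVs in the schemas read by
#' [read_gas_exchange()] and [read_isotope()], a noiseless truth CSV, and a
#' JSON sidecar with the generating parameters and settings.
#'
#' @param dataset A `c3c4_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "c3c4_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(dataset$gas, file.path(dir, "gas_exchange.csv"))
  write_table_csv(dataset$iso, file.path(dir, "isotope.csv"))
  write_table_csv(dataset$truth, file.path(dir, "truth.csv"))
  side <- list(params = unclass(dataset$params),
               ca_grid = dataset$ca_grid,
               ci_over_ca = dataset$ci_over_ca,
               noise_sd_A = dataset$noise_sd_A,
               noise_sd_D = dataset$noise_sd_D,
               seed = dataset$seed)
  jsonlite::write_json(side, file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate A/Ci curves across an O2 series
#'
#' Produces one modeled A/Ci curve per O2 partial pressure, with the
#' photorespiratory compensation term scaled in proportion to O2
#' (`gamma_star = 0.000193 * pO2` with pO2 in ubar, the standard
#' Rubisco-specificity value at 25 C) so that the compensation point and
#' the O2 inhibition of assimilation respond to O2. Intended for exercising
#' [o2_response_normalization()] and [gamma_from_aci()]; the main fitting
#' pipeline keeps `gamma_star = 0` as appropriate for low-O2 measurements.
#'
#' @param params A `c3c4_params` object.
#' @param po2_mbar O2 partial pressures, mbar (default the measurement
#'   series 20, 50, 100, 200, 300).
#' @param ci_grid Ci values, ubar; the default follows the stepped
#'   reference-CO2 protocol at an operating Ci/Ca of 0.7, with a
#'   near-zero point added so the compensation point is always bracketed.
#' @param gamma_star_per_O Proportionality constant, ubar CO2 per ubar O2.
#' @param gm gm specification as in [solve_assimilation()].
#' @return Named list (names = pO2 in mbar) of data.frames of model states.
#' @export
generate_o2_series <- function(params, po2_mbar = c(20, 50, 100, 200, 300),
                               ci_grid = 0.7 * c(1, 24, 48, 73, 97, 145,
                                                 194, 291, 388, 485, 582,
                                                 776),
                               gamma_star_per_O = 0.000193, gm = NULL) {
  stopifnot(length(po2_mbar) > 0, all(po2_mbar > 0))
  out <- lapply(po2_mbar, function(po2) {
    p <- params
    p$O <- po2 * 1000
    p$gamma_star <- gamma_star_per_O * p$O
    p <- validate_params(p)
    assimilation_curve(ci_grid, p, gm)
  })
  names(out) <- as.character(po2_mbar)
  out
}
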
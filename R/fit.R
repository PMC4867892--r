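#' Assemble paired gas-exchange and isotope observations for fitting
#'
#' Joins a gas-exchange table and an isotope table (matched by row order,
#' one row per CO2 set-point) into the single observation frame consumed by
#' [fit_c3c4()]: `set_point, Ci, Ca, Cl, E, g_ac, A_obs, Delta_obs`.
#'
#' @param gas Gas-exchange data.frame (see [read_gas_exchange()]).
#' @param iso Isotope data.frame (see [read_isotope()]), or a numeric
#'   vector of observed discriminations, permil.
#' @return A data.frame of paired observations.
#' @export
c3c4_data <- function(gas, iso = NULL) {
  Delta_obs <- if (is.null(iso)) rep(NA_real_, nrow(gas))
               else if (is.numeric(iso)) iso
               else delta_from_tdl(iso)
  if (length(Delta_obs) != nrow(gas)) {
    stop("gas-exchange and isotope tables must have one row per common ",
         "set-point (got ", nrow(gas), " and ", length(Delta_obs), ")",
         call. = FALSE)
  }
  data.frame(
    set_point = if ("set_point" %in% names(gas)) gas$set_point
                else seq_len(nrow(gas)),
    Ci = gas$Ci, Ca = gas$Ca, Cl = gas$Cl, E = gas$E, g_ac = gas$g_ac,
    A_obs = gas$A, Delta_obs = Delta_obs
  )
}

#' Predict paired A and Delta responses for a parameter set
#'
#' Solves the coupled assimilation model at each observed `Ci` and maps the
#' resulting biochemical fractionation through the
#' mesophyll-conductance / ternary discrimination model using the measured
#' diffusion state (`Ca, Cl, E, g_ac`) of each record.
#'
#' @param params A `c3c4_params` object.
#' @param data Observation frame from [c3c4_data()] (columns `Ci, Ca, Cl,
#'   E, g_ac`; `A_obs`/`Delta_obs` are ignored here).
#' @param gm Mesophyll conductance specification as in
#'   [solve_assimilation()]; default the gm(Ci) polynomial with
#'   `params$c_gm`.
#' @return A data.frame with one model state per row plus `a_prime, t,
#'   Delta_bio, Delta`.
#' @export
predict_c3c4 <- function(params, data, gm = NULL) {
  states <- assimilation_curve(data$Ci, params, gm)
  ap <- combined_a_prime(data$Ca, data$Cl, data$Ci, params)
  t <- ternary_t(ap, data$E, data$g_ac)
  Delta_bio <- delta_bio_forward(states, params)
  Delta <- delta_model(Delta_bio, states$A, states$gm, data$Ca, data$Ci,
                       ap, t, params)
  cbind(states, a_prime = ap, t = t, Delta_bio = Delta_bio, Delta = Delta)
}

.default_bounds <- list(
  phi = c(0, 1), c_gm = c(0.05, 2), Vpr = c(0, 100),
  Vm_max = c(0, 250), Vp_max = c(0, 250), Jm = c(0, 600), Jt = c(0, 1200)
)

#' Joint least-squares objective over the A and Delta blocks
#'
#' `w_A * sum((A_obs - A_mod)^2) + w_D * sum((Delta_obs - Delta_mod)^2)`.
#' With `weighting = "scaled"` (default) each block weight is
#' `1 / rms(observed block)^2`, making the objective unit-free so the
#' numerically larger A block cannot dominate the permil-scale Delta block;
#' `"raw"` uses unit weights. Model-evaluation failures return `Inf`.
#'
#' @param free_values Numeric vector of trial values.
#' @param free_names Matching parameter names (subset of `phi, c_gm, Vpr,
#'   Vm_max, Vp_max, Jm, Jt`).
#' @param base_params A `c3c4_params` object holding all fixed values.
#' @param data Observation frame from [c3c4_data()].
#' @param weighting `"scaled"` or `"raw"`.
#' @param gm gm specification (default: polynomial driven by the trial
#'   `c_gm`).
#' @param weights Optional explicit block weights, named `c(A = , D = )`,
#'   overriding `weighting` (e.g. `c(A = 1, D = 0)` reduces to an A-only
#'   least squares).
#' @return Scalar objective.
#' @export
joint_objective <- function(free_values, free_names, base_params, data,
                            weighting = c("scaled", "raw"), gm = NULL,
                            weights = NULL) {
  weighting <- match.arg(weighting)
  w <- if (is.null(weights)) .block_weights(data, weighting)
       else c(A = unname(weights["A"]), D = unname(weights["D"]))
  p <- base_params
  p[free_names] <- as.list(free_values)
  res <- tryCatch(.block_ssr(p, data, gm), error = function(e) NULL)
  if (is.null(res)) return(Inf)
  unname(w["A"] * res["A"] + w["D"] * res["D"])
}

.block_weights <- function(data, weighting) {
  # Delta block dropped entirely for A-only data.
  wD_on <- any(is.finite(data$Delta_obs))
  if (weighting == "raw") return(c(A = 1, D = as.numeric(wD_on)))
  c(A = 1 / mean(data$A_obs^2),
    D = if (wD_on) 1 / mean(data$Delta_obs^2, na.rm = TRUE) else 0)
}

.block_ssr <- function(p, data, gm) {
  pred <- .predict_fast(p, data, gm)
  dD <- data$Delta_obs - pred$Delta
  c(A = sum((data$A_obs - pred$A)^2),
    D = sum(dD[is.finite(dD)]^2))
}

# Objective-path prediction without data.frame overhead.
.predict_fast <- function(params, data, gm) {
  n <- length(data$Ci)
  J <- electron_transport(params$irradiance, params$Jm, params$absorptance,
                          params$F_spec, params$theta)
  A <- As <- Vp <- Fm <- gm_v <- numeric(n)
  for (i in seq_len(n)) {
    Ci <- data$Ci[i]
    g <- .gm_at(gm, Ci, params)
    if (is.infinite(g)) {
      cm <- Ci
    } else {
      h <- function(cm) cm - Ci + .A_at_cm(cm, params, J) / g
      lo <- if (params$gamma_star > 0) 1e-9 else 0
      hi <- Ci + 50
      if (h(lo) * h(hi) > 0) stop("no root of the Cm balance")
      cm <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
    }
    st <- .state_at_cm(cm, params, J)
    A[i] <- st$A; As[i] <- st$As; Vp[i] <- st$Vp; Fm[i] <- st$Fm
    gm_v[i] <- g
  }
  state <- list(A = A, As = As, Vp = Vp, Fm = Fm, Fs = numeric(n))
  Delta_bio <- delta_bio_forward(state, params)
  ap <- combined_a_prime(data$Ca, data$Cl, data$Ci, params)
  t <- ternary_t(ap, data$E, data$g_ac)
  Delta <- delta_model(Delta_bio, A, gm_v, data$Ca, data$Ci, ap, t, params)
  list(A = A, Delta = Delta)
}

#' Concurrently fit the A/Ci and Delta/Ci models
#'
#' Fits the two-compartment assimilation model and the
#' mesophyll-conductance-aware discrimination model simultaneously to
#' paired A/Ci and Delta/Ci observations, minimising [joint_objective()]
#' over a chosen set of free parameters with the rest fixed at their preset
#' values. Fitting both blocks with one parameter set is what makes weak
#' C4-cycle activity identifiable: parameter combinations acceptable for A
#' alone are rejected by Delta and vice versa.
#'
#' The objective can be kinked at the Wc/Wj and Vp/Vpr crossovers, so a
#' bounded derivative-free search is used: golden-section refinement of a
#' coarse deterministic scan for one free parameter, Nelder-Mead on a
#' logit-transformed (bounded) scale from a deterministic 3-point-per-
#' parameter start grid for several.
#'
#' @param data Observation frame from [c3c4_data()], or a
#'   `c3c4_dataset` from [generate_dataset()].
#' @param params Base `c3c4_params` object (fixed values and defaults for
#'   the free parameters).
#' @param free Character vector of free parameter names, subset of
#'   `phi, c_gm, Vpr, Vm_max, Vp_max, Jm, Jt`.
#' @param lower,upper Optional named bounds; defaults are physical
#'   (`phi` in `[0,1]`, rates non-negative).
#' @param weighting Objective weighting, see [joint_objective()].
#' @param gm gm specification; default the gm(Ci) polynomial driven by
#'   `c_gm` (fitted when `c_gm` is free).
#' @param hypothesis Label stored on the result (e.g. `"C4-active"`).
#' @return An object of class `c3c4_fit`; see [print.c3c4_fit()],
#'   [coef.c3c4_fit()], [predict.c3c4_fit()], [residuals.c3c4_fit()],
#'   [plot.c3c4_fit()], [simulate.c3c4_fit()].
#' @examples
#' \donttest{
#' d <- generate_dataset(species_params("F. floridana"), noise_sd_A = 0,
#'                       noise_sd_D = 0, seed = 1)
#' f <- fit_c3c4(d, species_params("F. floridana", phi = 0.2), free = "phi")
#' coef(f)  # recovers phi = 0.40
#' }
#' @export
fit_c3c4 <- function(data, params, free = c("phi", "c_gm"),
                     lower = NULL, upper = NULL,
                     weighting = c("scaled", "raw"), gm = NULL,
                     hypothesis = params$name) {
  weighting <- match.arg(weighting)
  if (inherits(data, "c3c4_dataset")) data <- c3c4_data(data$gas, data$iso)
  bad <- setdiff(free, names(.default_bounds))
  if (length(bad)) {
    stop("cannot free parameter(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(names(.default_bounds), collapse = ", "),
         call. = FALSE)
  }
  lo <- vapply(free, function(f) {
    if (!is.null(lower) && f %in% names(lower)) lower[[f]]
    else .default_bounds[[f]][1]
  }, 0)
  hi <- vapply(free, function(f) {
    if (!is.null(upper) && f %in% names(upper)) upper[[f]]
    else .default_bounds[[f]][2]
  }, 0)
  if (any(hi <= lo)) stop("upper bounds must exceed lower bounds",
                          call. = FALSE)
  obj <- function(x) joint_objective(x, free, params, data, weighting, gm)

  if (length(free) == 1L) {
    opt <- .fit_1d(obj, lo, hi)
  } else {
    opt <- .fit_nm(obj, lo, hi)
  }
  est <- stats::setNames(opt$par, free)
  ident <- .identifiability(obj, est, lo, hi, opt$value)
  p_hat <- params
  p_hat[free] <- as.list(est)
  p_hat <- validate_params(p_hat)
  pred <- predict_c3c4(p_hat, data, gm)
  ssr <- .block_ssr(p_hat, data, gm)
  w <- .block_weights(data, weighting)
  structure(list(
    hypothesis = hypothesis,
    free = est,
    params = p_hat,
    fixed_params = params,
    bounds = list(lower = stats::setNames(lo, free),
                  upper = stats::setNames(hi, free)),
    ssr_A = unname(ssr["A"]), ssr_D = unname(ssr["D"]),
    weights = w,
    objective = opt$value,
    n = nrow(data),
    converged = opt$converged,
    identifiability = ident,
    predicted = pred,
    data = data,
    weighting = weighting,
    gm = gm,
    call = match.call()
  ), class = "c3c4_fit")
}

# Curvature probe at the optimum: a finite-difference Hessian of the
# objective on the normalized (0-1) parameter scale. A near-zero smallest
# eigenvalue relative to the largest marks a ridge along which the data do
# not constrain the parameters (e.g. leakiness and Vp_max from A-only data
# in the Vpr-capped region); the corresponding direction is reported.
.identifiability <- function(obj, est, lo, hi, fmin, step = 0.02,
                             ratio_tol = 1e-6) {
  k <- length(est)
  u <- (est - lo) / (hi - lo)
  f_u <- function(uu) obj(lo + (hi - lo) * pmin(pmax(uu, 0), 1))
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, step)
    H[i, i] <- (f_u(u + ei) - 2 * fmin + f_u(u - ei)) / step^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, step)
      H[i, j] <- H[j, i] <-
        (f_u(u + ei + ej) - f_u(u + ei - ej) -
           f_u(u - ei + ej) + f_u(u - ei - ej)) / (4 * step^2)
    }
  }
  if (any(!is.finite(H))) {
    return(list(eigenvalues = rep(NA_real_, k), poorly_identified = NA,
                flat_direction = NULL))
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- ev$values
  flat <- lam[k] < ratio_tol * max(abs(lam[1]), .Machine$double.eps)
  list(eigenvalues = lam,
       poorly_identified = isTRUE(flat),
       flat_direction = if (isTRUE(flat)) {
         stats::setNames(ev$vectors[, k], names(est))
       } else NULL)
}

# Deterministic 1-D minimisation: coarse scan, then stats::optimize on the
# bracketing subinterval around the best scan point.
.fit_1d <- function(obj, lo, hi, n_scan = 25) {
  grid <- seq(lo, hi, length.out = n_scan)
  vals <- vapply(grid, obj, 0)
  if (all(!is.finite(vals))) {
    stop("objective is non-finite over the whole search interval",
         call. = FALSE)
  }
  i <- which.min(vals)
  a <- grid[max(1, i - 1)]
  b <- grid[min(n_scan, i + 1)]
  o <- stats::optimize(obj, c(a, b), tol = 1e-9)
  if (vals[i] < o$objective) {
    list(par = grid[i], value = vals[i], converged = TRUE)
  } else {
    list(par = o$minimum, value = o$objective, converged = TRUE)
  }
}

# Bounded Nelder-Mead via logit transform from a deterministic start grid
# (3 quantiles per parameter).
.fit_nm <- function(obj, lo, hi) {
  k <- length(lo)
  to_z <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                              1e-6), 1 - 1e-6))
  to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
  fz <- function(z) obj(to_x(z))
  qs <- c(0.25, 0.5, 0.75)
  starts <- matrix(rep(qs, each = k), ncol = k, byrow = TRUE)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    x0 <- lo + (hi - lo) * starts[s, ]
    fit <- tryCatch(
      stats::optim(to_z(x0), fz, method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    conv <- fit$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && fit$counts[1] < best$counts[1])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed to produce a finite objective",
         call. = FALSE)
  }
  list(par = to_x(best$par), value = best$value, converged = any_conv)
}
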
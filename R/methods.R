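#' Methods for fitted concurrent A/Delta models
#'
#' Standard accessors for `c3c4_fit` objects returned by [fit_c3c4()].
#'
#' @param x,object A `c3c4_fit` object.
#' @param ... Passed on or ignored.
#' @name c3c4_fit-methods
NULL

#' @rdname c3c4_fit-methods
#' @export
print.c3c4_fit <- function(x, ...) {
  cat("Concurrent A/Ci + Delta/Ci fit  [", x$hypothesis, "]\n", sep = "")
  cat("  free parameters:\n")
  for (nm in names(x$free)) {
    cat(sprintf("    %-8s %.4g\n", nm, x$free[[nm]]))
  }
  cat(sprintf("  objective %.6g (%s weights); SSR_A %.4g, SSR_Delta %.4g\n",
              x$objective, x$weighting, x$ssr_A, x$ssr_D))
  cat(sprintf("  n = %d set-points; converged: %s\n", x$n, x$converged))
  if (isTRUE(x$identifiability$poorly_identified)) {
    dir <- x$identifiability$flat_direction
    cat("  warning: near-flat objective direction (",
        paste(sprintf("%s %.2f", names(dir), dir), collapse = ", "),
        "); parameters poorly identified by these data\n", sep = "")
  }
  invisible(x)
}

#' @rdname c3c4_fit-methods
#' @export
coef.c3c4_fit <- function(object, ...) object$free

#' @rdname c3c4_fit-methods
#' @export
summary.c3c4_fit <- function(object, ...) {
  out <- list(
    hypothesis = object$hypothesis,
    free = object$free,
    objective = object$objective,
    rmse_A = sqrt(object$ssr_A / object$n),
    rmse_D = sqrt(object$ssr_D / object$n),
    n = object$n,
    converged = object$converged,
    params = object$params
  )
  class(out) <- "summary.c3c4_fit"
  out
}

#' @export
print.summary.c3c4_fit <- function(x, ...) {
  cat("Concurrent fit summary  [", x$hypothesis, "]\n", sep = "")
  for (nm in names(x$free)) {
    cat(sprintf("  %-8s %.4g\n", nm, x$free[[nm]]))
  }
  cat(sprintf("  RMSE(A) %.3g umol m-2 s-1; RMSE(Delta) %.3g permil; n = %d\n",
              x$rmse_A, x$rmse_D, x$n))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @rdname c3c4_fit-methods
#' @param newdata Optional observation frame (as [c3c4_data()]) or numeric
#'   vector of Ci values at which to predict; default the fitting data.
#'   For a bare Ci vector, only the assimilation block is predicted.
#' @export
predict.c3c4_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted)
  if (is.numeric(newdata)) {
    return(assimilation_curve(newdata, object$params, object$gm))
  }
  predict_c3c4(object$params, newdata, object$gm)
}

#' @rdname c3c4_fit-methods
#' @export
fitted.c3c4_fit <- function(object, ...) {
  data.frame(Ci = object$data$Ci, A = object$predicted$A,
             Delta = object$predicted$Delta)
}

#' @rdname c3c4_fit-methods
#' @param block `"both"`, `"A"` or `"Delta"`.
#' @export
residuals.c3c4_fit <- function(object, block = c("both", "A", "Delta"),
                               ...) {
  block <- match.arg(block)
  rA <- object$data$A_obs - object$predicted$A
  rD <- object$data$Delta_obs - object$predicted$Delta
  switch(block,
         A = rA,
         Delta = rD,
         both = data.frame(Ci = object$data$Ci, A = rA, Delta = rD))
}

#' @rdname c3c4_fit-methods
#' @export
plot.c3c4_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  o <- order(x$data$Ci)
  graphics::plot(x$data$Ci, x$data$A_obs, xlab = "Ci (ubar)",
                 ylab = "A (umol m-2 s-1)", main = x$hypothesis, ...)
  graphics::lines(x$data$Ci[o], x$predicted$A[o])
  graphics::plot(x$data$Ci, x$data$Delta_obs, xlab = "Ci (ubar)",
                 ylab = "Delta (permil)", main = "discrimination", ...)
  graphics::lines(x$data$Ci[o], x$predicted$Delta[o])
  invisible(x)
}

#' @rdname c3c4_fit-methods
#' @param nsim Number of synthetic datasets.
#' @param seed RNG seed for the generator.
#' @export
simulate.c3c4_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    out[[i]] <- generate_dataset(object$params,
                                 ca_grid = sort(unique(object$data$Ca)),
                                 seed = s, ...)
  }
  if (nsim == 1) out[[1]] else out
}
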
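#' Read a gas-exchange measurement table
#'
#' Reads per-set-point chamber measurements from CSV. Mandatory columns are
#' `set_point, A, Ca, Ci, Cl, E`; the total conductance to CO2 `g_ac`
#' (boundary layer plus stomata in series) may either be supplied directly
#' or be derived from `gs` and `gb` as `1 / (1/gs + 1/gb)`. Optional columns
#' `gs, gb, pO2, T_leaf` are carried through when present. Units: partial
#' pressures in ubar, fluxes in umol m-2 s-1 (E in mol m-2 s-1),
#' conductances in mol m-2 s-1 bar-1.
#'
#' @param path CSV file with a header row, `.` decimal separator.
#' @return A data.frame of validated records in file order.
#' @export
read_gas_exchange <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("set_point", "A", "Ca", "Ci", "Cl", "E")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop("gas-exchange file ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("g_ac" %in% names(d))) {
    if (all(c("gs", "gb") %in% names(d))) {
      d$g_ac <- 1 / (1 / d$gs + 1 / d$gb)
    } else {
      stop("gas-exchange file must contain either g_ac or both gs and gb",
           call. = FALSE)
    }
  } else if (all(c("gs", "gb") %in% names(d))) {
    fill <- is.na(d$g_ac)
    d$g_ac[fill] <- 1 / (1 / d$gs[fill] + 1 / d$gb[fill])
  }
  numcols <- setdiff(names(d), "set_point")
  for (cc in numcols) {
    if (!is.numeric(d[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1]
      stop("non-numeric value in column ", sQuote(cc), " at data row ",
           bad, " of ", path, call. = FALSE)
    }
  }
  .check_rows(d, path, function(r) {
    if (!is.finite(r$Ca) || r$Ca <= 0) return("Ca must be > 0")
    if (!is.finite(r$g_ac) || r$g_ac <= 0) return("g_ac must be > 0")
    if (is.finite(r$E) && r$E < 0) return("E must be >= 0")
    NULL
  })
  d
}

#' Read a two-point isotope (TDL) measurement table
#'
#' Reads tunable-diode-laser chamber measurements from CSV with columns
#' `set_point, Ce, Co, delta_e, delta_o` (CO2 partial pressure and delta13C
#' of air entering and leaving the chamber). The derived columns
#' `xi = Ce / (Ce - Co)` and the observed discrimination `Delta_obs` (see
#' [delta_from_tdl()]) are appended.
#'
#' @param path CSV file with a header row.
#' @return A data.frame of validated records in file order with `xi` and
#'   `Delta_obs` columns added.
#' @export
read_isotope <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("set_point", "Ce", "Co", "delta_e", "delta_o")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop("isotope file ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cc in c("Ce", "Co", "delta_e", "delta_o")) {
    if (!is.numeric(d[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1]
      stop("non-numeric value in column ", sQuote(cc), " at data row ",
           bad, " of ", path, call. = FALSE)
    }
  }
  .check_rows(d, path, function(r) {
    if (r$Ce == r$Co) {
      return("Ce equals Co (no CO2 drawdown across the chamber)")
    }
    NULL
  })
  d$xi <- d$Ce / (d$Ce - d$Co)
  d$Delta_obs <- delta_from_tdl(d$Ce, d$Co, d$delta_e, d$delta_o)
  d
}

.check_rows <- function(d, path, fun) {
  for (i in seq_len(nrow(d))) {
    msg <- fun(d[i, , drop = FALSE])
    if (!is.null(msg)) {
      stop("invalid record at data row ", i, " of ", path, ": ", msg,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# %.15g round-trips through read.csv at the precision we print, so
# write -> read -> write is byte-stable.
.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a measurement or result table as lossless CSV
#'
#' Numeric columns are printed with 15 significant digits so that a
#' write/read/write cycle is byte-identical.
#'
#' @param d data.frame to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(d, path) {
  out <- d
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- .fmt_num(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a parameter set as JSON or YAML
#'
#' Files use keys named exactly as the fields of [species_params()] output.
#' Format is chosen from the file extension (`.json`, `.yml`/`.yaml`).
#'
#' @param path File path.
#' @return `read_params()` returns a validated `c3c4_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  p <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML parameter files",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_params(p)
}

#' @rdname read_params
#' @param p A `c3c4_params` object (or compatible named list).
#' @export
write_params <- function(p, path) {
  p <- validate_params(p)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to write YAML parameter files",
           call. = FALSE)
    }
    yaml::write_yaml(unclass(p), path)
  } else {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a fit result to disk
#'
#' Emits a JSON file with the free-parameter estimates, objective breakdown
#' and convergence metadata, plus a CSV of the predicted model states
#' alongside it (same stem, `_curves.csv` suffix).
#'
#' @param fit A `c3c4_fit` object from [fit_c3c4()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "c3c4_fit"))
  rep <- list(
    hypothesis = fit$hypothesis,
    free_params = as.list(fit$free),
    fixed_params = unclass(fit$params),
    ssr_A = fit$ssr_A, ssr_D = fit$ssr_D,
    weights = as.list(fit$weights),
    objective = fit$objective,
    n_points = fit$n,
    converged = fit$converged
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  curves <- sub("\\.json$", "", path)
  write_table_csv(fit$predicted, paste0(curves, "_curves.csv"))
  invisible(path)
}
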
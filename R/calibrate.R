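#' Two-point analytical parameter fit
#'
#' Because the GRRO/GPRO current density -- and hence any shielding derived
#' from it -- is exactly linear in its defining parameter, a parameter
#' reproducing a reference shielding is obtained from two probe
#' evaluations by straight-line solve, with no iteration:
#' slope = (s2 - s1)/(p2 - p1), parameter = p1 + (target - s1)/slope.
#'
#' @param p1,p2 probe parameter values (distinct)
#' @param s1,s2 isotropic shieldings at the probes (ppm)
#' @param target reference isotropic shielding (ppm)
#' @return list with `parameter`, `slope` (ppm per parameter unit) and
#'   `intercept` (shielding at parameter 0, ppm)
#' @export
two_point_fit <- function(p1, s1, p2, s2, target) {
  if (p1 == p2) stop("probe parameters must differ")
  if (abs(s2 - s1) < 1e-12) {
    stop("degenerate slope: shielding is insensitive to the parameter (|",
         format(s2 - s1, digits = 3), "| ppm between probes)")
  }
  slope <- (s2 - s1) / (p2 - p1)
  intercept <- s1 - slope * p1
  list(parameter = p1 + (target - s1) / slope, slope = slope,
       intercept = intercept)
}

#' Calibrate per-nucleus scheme parameters against reference shieldings
#'
#' For each referenced nucleus, fits the GRRO alpha (or GPRO beta) that
#' makes the Biot-Savart isotropic shielding match the reference exactly,
#' using the two-point analytical formula on uniform-parameter probe
#' integrations (one grid pass; all nuclei are read out simultaneously
#' and, by linearity, fitted independently).
#'
#' @param state a `ctocd_state`
#' @param references named numeric vector of reference shieldings (ppm);
#'   names are nucleus indices (unnamed vectors must cover every nucleus)
#' @param scheme "GRRO" or "GPRO"
#' @param probes two probe parameter values; defaults c(0, -0.01) for
#'   GRRO and c(0, -0.05) for GPRO
#' @param grid optional `ctocd_grid` (built with `...` otherwise)
#' @param ... grid construction arguments
#' @return object of class `ctocd_calibration` (a data.frame with one row
#'   per referenced nucleus: slope, intercept, fitted parameter,
#'   reference, residual, environment key)
#' @export
calibrate_molecule <- function(state, references,
                               scheme = c("GRRO", "GPRO"), probes = NULL,
                               grid = NULL, ...) {
  scheme <- match.arg(scheme)
  if (is.null(probes)) {
    probes <- if (scheme == "GRRO") c(0, -0.01) else c(0, -0.05)
  }
  stopifnot(length(probes) == 2, probes[1] != probes[2])
  mol <- st_molecule(state)
  nat <- n_atoms(mol)
  if (is.null(names(references))) {
    if (length(references) != nat) {
      stop("unnamed references must provide one value per nucleus")
    }
    names(references) <- seq_len(nat)
  }
  idx <- as.integer(names(references))
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nat)) {
    stop("reference names must be nucleus indices in 1..", nat)
  }
  if (length(references) == 0) stop("empty reference set")
  if (is.null(grid)) grid <- molecular_grid(mol, ...)
  dec <- .shielding_decomposition(state, grid, scheme = scheme)
  iso <- function(p) {
    ## uniform-parameter isotropic shieldings from the linear decomposition
    vapply(seq_len(nat), function(n) {
      tn <- apply(dec$base[n, , , , drop = FALSE], c(2, 3), sum) +
        p * apply(dec$kern[n, , , , drop = FALSE], c(2, 3), sum)
      sum(diag(tn)) / 3
    }, 0)
  }
  s1 <- iso(probes[1]); s2 <- iso(probes[2])
  keys <- classify_molecule(mol)
  rows <- lapply(seq_along(idx), function(i) {
    n <- idx[i]
    fit <- tryCatch(two_point_fit(probes[1], s1[n], probes[2], s2[n],
                                  references[i]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("nucleus ", n, " (", mol$symbols[n], "): ",
              conditionMessage(fit))
      return(data.frame(nucleus = n, element = mol$symbols[n],
                        key = keys[n], scheme = scheme, slope = NA_real_,
                        intercept = NA_real_, parameter = NA_real_,
                        reference = unname(references[i]),
                        residual = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    resid <- (fit$intercept + fit$slope * fit$parameter) - references[i]
    data.frame(nucleus = n, element = mol$symbols[n], key = keys[n],
               scheme = scheme, slope = fit$slope,
               intercept = fit$intercept, parameter = fit$parameter,
               reference = unname(references[i]), residual = unname(resid),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "probes") <- probes
  attr(out, "provenance") <- list(
    basis = if (!is.null(state$basis_name)) state$basis_name else "analytic",
    method = if (!is.null(state$method)) state$method else "analytic",
    scheme = scheme,
    grid = list(radial_n = grid$radial_n, n_theta = grid$n_theta,
                n_phi = grid$n_phi))
  class(out) <- c("ctocd_calibration", "data.frame")
  out
}

#' @export
print.ctocd_calibration <- function(x, ...) {
  cat(sprintf("CTOCD %s calibration (%d nuclei, probes %s)\n",
              x$scheme[1], nrow(x),
              paste(attr(x, "probes"), collapse = ", ")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Aggregate calibrated parameters into a parameter table
#'
#' Arithmetic mean and sample (n-1) standard deviation of the fitted
#' parameters within element groups or chemical-environment groups.
#'
#' @param records a `ctocd_calibration` (or rbind of several)
#' @param grouping "element" or "environment"
#' @return object of class `ctocd_parameter_table`: data.frame with key,
#'   mean, sd, n, plus scheme/grouping/provenance attributes
#' @export
aggregate_parameters <- function(records,
                                 grouping = c("element", "environment")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(records) > 0)
  ok <- !records$flagged & is.finite(records$parameter)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0) stop("no usable calibration records")
  g <- if (grouping == "element") records$element else records$key
  sp <- split(records$parameter, g)
  out <- data.frame(
    key = names(sp),
    mean = vapply(sp, mean, 0),
    sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0, 0),
    n = vapply(sp, length, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scheme") <- records$scheme[1]
  attr(out, "grouping") <- grouping
  attr(out, "provenance") <- attr(records, "provenance")
  class(out) <- c("ctocd_parameter_table", "data.frame")
  out
}

#' @export
print.ctocd_parameter_table <- function(x, ...) {
  cat(sprintf("CTOCD %s parameter table (grouping: %s)\n",
              attr(x, "scheme"), attr(x, "grouping")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Convert a parameter table to a per-atom parameter specification
#'
#' @param table a `ctocd_parameter_table`
#' @param rho_cut density floor for the resulting spec
#' @return a [param_spec()]
#' @export
param_table_as_spec <- function(table, rho_cut = 1e-10) {
  vals <- stats::setNames(table$mean, table$key)
  if (attr(table, "grouping") == "element") {
    param_spec(attr(table, "scheme"), element = vals, rho_cut = rho_cut)
  } else {
    param_spec(attr(table, "scheme"), environment = vals, rho_cut = rho_cut)
  }
}

#' Predicted shielding error from parameter dispersion
#'
#' The isotropic shielding is linear in the scheme parameter, so the
#' shielding uncertainty implied by using a group-mean parameter with
#' dispersion `std` is |slope| * std (ppm).
#'
#' @param slope shielding-vs-parameter slope (ppm per parameter unit)
#' @param std parameter standard deviation (parameter units)
#' @return predicted error (ppm)
#' @export
#' @examples
#' propagate_error(11, 0.05)       # hydrogen, GRRO
#' propagate_error(23750, 0.00016) # carbon, GRRO
propagate_error <- function(slope, std) {
  stopifnot(is.finite(slope), is.finite(std))
  abs(slope) * std
}
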
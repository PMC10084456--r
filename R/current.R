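#' Scheme parameter for current-density construction
#'
#' The CTOCD shift function is d(r) = r - f(rho) grad ln rho.  GRRO takes
#' f = alpha (a constant length-squared scale, bohr^2 in strict dimensional
#' terms, conventionally quoted in a0); GPRO takes f = beta rho^(-2/3) with
#' beta dimensionless, the exponent fixed by requiring f grad ln rho to
#' carry the dimension of a length.  With beta equal to the Thomas-Fermi
#' (Harris-Cina) value -0.0174 the GPRO diamagnetic term coincides with the
#' local-density current approximation.  Both parameters should be
#' negative to keep the tropicity of the diamagnetic vortex close to the
#' nuclei.
#'
#' @param scheme one of "CO", "DZ1", "GRRO", "GPRO"
#' @param alpha GRRO parameter (bohr units as quoted in parameter tables)
#' @param beta GPRO parameter (dimensionless); default NULL.  Use
#'   `beta_harris_cina()` for the Thomas-Fermi value.
#' @param rho_cut density floor (bohr^-3) below which the grad-ln-rho shift
#'   is suppressed (the GPRO power diverges in density tails)
#' @return object of class `ctocd_scheme_parameter`
#' @export
scheme_parameter <- function(scheme = c("GRRO", "GPRO", "CO", "DZ1"),
                             alpha = NULL, beta = NULL, rho_cut = 1e-10) {
  scheme <- match.arg(scheme)
  if (scheme == "GRRO") {
    if (is.null(alpha)) stop("GRRO requires alpha")
    if (alpha > 0) warning("alpha should be negative (alpha = ", alpha,
                           ") to keep the tropicity of the diamagnetic vortex")
  } else if (scheme == "GPRO") {
    if (is.null(beta)) stop("GPRO requires beta")
    if (beta > 0) warning("beta should be negative (beta = ", beta,
                          ") to keep the tropicity of the diamagnetic vortex")
  }
  structure(list(scheme = scheme, alpha = alpha, beta = beta,
                 rho_cut = rho_cut),
            class = "ctocd_scheme_parameter")
}

#' Thomas-Fermi (Harris-Cina) GPRO beta value
#' @return -(3 pi^2)^(1/3) / (18 pi^2) = -0.0174
#' @export
beta_harris_cina <- function() .ctocd_const$beta_harris_cina

.param_value <- function(param) {
  switch(param$scheme,
         GRRO = param$alpha, GPRO = param$beta,
         stop("scheme ", param$scheme, " carries no free parameter"))
}

## Levi-Civita tensor
.eps3 <- local({
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[2, 1, 3] <- e[1, 3, 2] <- -1
  e
})

.new_field <- function(points, tensor, scheme, param, component, eval_fun,
                       extra = list()) {
  structure(c(list(points = points, tensor = tensor, scheme = scheme,
                   param = param, component = component, eval = eval_fun),
              extra),
            class = "ctocd_current_field")
}

#' @export
print.ctocd_current_field <- function(x, ...) {
  pv <- if (is.null(x$param)) "" else
    sprintf(", param %s", format(x$param, digits = 6))
  cat(sprintf("<current field: %s/%s%s, %d points, max |J| = %.3e a.u.>\n",
              x$scheme, x$component, pv, nrow(x$points),
              max(sqrt(rowSums(matrix(x$tensor^2, nrow(x$points)))))))
  invisible(x)
}

## ---- tensor builders (internal; tensors are N x 3 x 3 arrays with
##      tensor[n, delta, beta] = dJ_delta/dB_beta in a.u.) ----

## diamagnetic CO term: -(1/2c) rho eps_{delta beta nu} (r - r0')_nu
.tensor_co_dia <- function(rho, rel) {
  N <- length(rho)
  tn <- array(0, c(N, 3, 3))
  hc <- 1 / (2 * .ctocd_const$speed_of_light)
  for (d in 1:3) for (b in 1:3) for (v in 1:3) {
    if (.eps3[d, b, v] != 0) {
      tn[, d, b] <- tn[, d, b] - hc * .eps3[d, b, v] * rho * rel[, v]
    }
  }
  tn
}

## paramagnetic term from L kernels shifted to origin r0p:
## (1/2c) [ CL_beta - eps_{beta mu nu} s_mu CP_nu ]_delta,  s = r0p - r0
.tensor_co_para <- function(sf, s) {
  N <- length(sf$rho)
  tn <- array(0, c(N, 3, 3))
  hc <- 1 / (2 * .ctocd_const$speed_of_light)
  for (b in 1:3) {
    ker <- sf$CL[[b]]
    for (m in 1:3) for (v in 1:3) {
      if (.eps3[b, m, v] != 0 && s[m] != 0) {
        ker <- ker - .eps3[b, m, v] * s[m] * sf$CP[[v]]
      }
    }
    tn[, , b] <- hc * ker
  }
  tn
}

## DZ1 delta-paramagnetic replacement of the diamagnetic term:
## -(1/2c) eps_{mu beta nu} (r - r0)_nu CP_mu
.tensor_dz1_delta <- function(sf, rel) {
  N <- length(sf$rho)
  tn <- array(0, c(N, 3, 3))
  hc <- 1 / (2 * .ctocd_const$speed_of_light)
  for (b in 1:3) for (m in 1:3) for (v in 1:3) {
    if (.eps3[m, b, v] != 0) {
      tn[, , b] <- tn[, , b] - hc * .eps3[m, b, v] * rel[, v] * sf$CP[[m]]
    }
  }
  tn
}

## unit-parameter kernel K (per unit alpha for GRRO, per unit beta for
## GPRO): K = (1/2c)[ eps_{mu beta nu} (grad ln rho)_nu CP_mu
##               - eps_{delta beta nu} (grad rho)_nu ] * (rho^(-2/3) GPRO),
## suppressed where rho < rho_cut
.tensor_kernel <- function(sf, scheme, rho_cut) {
  N <- length(sf$rho)
  tn <- array(0, c(N, 3, 3))
  hc <- 1 / (2 * .ctocd_const$speed_of_light)
  live <- sf$rho >= rho_cut
  gln <- sf$grad / pmax(sf$rho, rho_cut)
  gln[!live, ] <- 0
  grho <- sf$grad
  grho[!live, ] <- 0
  for (b in 1:3) {
    acc <- matrix(0, N, 3)
    for (m in 1:3) for (v in 1:3) {
      if (.eps3[m, b, v] != 0) {
        acc <- acc + .eps3[m, b, v] * gln[, v] * sf$CP[[m]]
      }
    }
    for (d in 1:3) for (v in 1:3) {
      if (.eps3[d, b, v] != 0) {
        acc[, d] <- acc[, d] - .eps3[d, b, v] * grho[, v]
      }
    }
    tn[, , b] <- hc * acc
  }
  if (scheme == "GPRO") {
    w <- ifelse(live, pmax(sf$rho, rho_cut)^(-2 / 3), 0)
    tn <- tn * as.vector(w)
  }
  tn
}

## ---- public operations ----

#' Common-origin current-density tensor
#'
#' Conventional split into a paramagnetic response term and the Larmor
#' diamagnetic term -(1/2c) rho B x (r - r0'); both depend on the chosen
#' vector-potential origin in a finite basis (only their exact-limit sum
#' does not), which is the defect the CTOCD schemes remove.
#'
#' @param state a `ctocd_state`
#' @param points N x 3 matrix (bohr)
#' @param origin vector-potential origin r0' (default: the state's common
#'   origin)
#' @return a `ctocd_current_field` with components `tensor` (total),
#'   `diamagnetic`, `paramagnetic`
#' @export
co_current <- function(state, points, origin = NULL) {
  points <- matrix(points, ncol = 3)
  r0p <- if (is.null(origin)) st_origin(state) else as.numeric(origin)
  eval_fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    sf <- .state_fields(state, pts)
    rel <- pts - matrix(r0p, nrow(pts), 3, byrow = TRUE)
    .tensor_co_dia(sf$rho, rel) + .tensor_co_para(sf, r0p - st_origin(state))
  }
  sf <- .state_fields(state, points)
  rel <- points - matrix(r0p, nrow(points), 3, byrow = TRUE)
  dia <- .tensor_co_dia(sf$rho, rel)
  para <- .tensor_co_para(sf, r0p - st_origin(state))
  .new_field(points, dia + para, "CO", NULL, "total", eval_fun,
             extra = list(diamagnetic = dia, paramagnetic = para,
                          origin = r0p))
}

#' Ipsocentric (CTOCD-DZ1) current-density tensor
#'
#' The d(r) = r limit: the diamagnetic contribution vanishes identically
#' and is replaced by a linear-momentum response term.  This is the
#' alpha = beta = 0 limit of both GRRO and GPRO, and is origin-independent
#' in any basis.
#'
#' @inheritParams co_current
#' @return a `ctocd_current_field`
#' @export
dz1_current <- function(state, points) {
  points <- matrix(points, ncol = 3)
  r0 <- st_origin(state)
  eval_fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    sf <- .state_fields(state, pts)
    rel <- pts - matrix(r0, nrow(pts), 3, byrow = TRUE)
    .tensor_co_para(sf, c(0, 0, 0)) + .tensor_dz1_delta(sf, rel)
  }
  .new_field(points, eval_fun(points), "DZ1", NULL, "total", eval_fun)
}

#' Divergenceless CTOCD diamagnetic term
#'
#' The merged diamagnetic contribution of the GRRO/GPRO schemes,
#' J_d = -(f(rho)/2c) B x grad rho, which is divergenceless for any f(rho)
#' since div(grad rho x B) = 0.  Proportional to alpha (GRRO) or beta
#' (GPRO).
#'
#' @inheritParams co_current
#' @param param a `ctocd_scheme_parameter` with scheme GRRO or GPRO
#' @return a `ctocd_current_field` (component "diamagnetic")
#' @export
ctocd_diamagnetic <- function(state, points, param) {
  .ctocd_component(state, points, param, dia = TRUE, delta = FALSE,
                   component = "diamagnetic")
}

#' CTOCD additional paramagnetic (Delta) term
#'
#' The linear-momentum response contribution generated by the
#' -f(rho) grad ln rho part of the shift function, contracted pointwise
#' with (d(r) - r) x B; strictly proportional to the scheme parameter.
#'
#' @inheritParams ctocd_diamagnetic
#' @return a `ctocd_current_field` (component "delta")
#' @export
ctocd_delta_paramagnetic <- function(state, points, param) {
  .ctocd_component(state, points, param, dia = FALSE, delta = TRUE,
                   component = "delta")
}

.ctocd_component <- function(state, points, param, dia, delta, component) {
  if (!inherits(param, "ctocd_scheme_parameter") ||
      !param$scheme %in% c("GRRO", "GPRO")) {
    stop("param must be a GRRO or GPRO scheme_parameter")
  }
  points <- matrix(points, ncol = 3)
  pv <- .param_value(param)
  eval_fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    sf <- .state_fields(state, pts)
    K <- .tensor_kernel(sf, param$scheme, param$rho_cut)
    if (dia && !delta) {
      ## keep only the -(1/2c) f eps grad-rho part
      Kd <- .tensor_kernel_part(sf, param$scheme, param$rho_cut, "dia")
      pv * Kd
    } else if (delta && !dia) {
      Kd <- .tensor_kernel_part(sf, param$scheme, param$rho_cut, "delta")
      pv * Kd
    } else pv * K
  }
  .new_field(points, eval_fun(points), param$scheme, pv, component, eval_fun)
}

## kernel restricted to its diamagnetic or delta-paramagnetic part
.tensor_kernel_part <- function(sf, scheme, rho_cut, part) {
  N <- length(sf$rho)
  tn <- array(0, c(N, 3, 3))
  hc <- 1 / (2 * .ctocd_const$speed_of_light)
  live <- sf$rho >= rho_cut
  if (part == "dia") {
    grho <- sf$grad
    grho[!live, ] <- 0
    for (d in 1:3) for (b in 1:3) for (v in 1:3) {
      if (.eps3[d, b, v] != 0) {
        tn[, d, b] <- tn[, d, b] - hc * .eps3[d, b, v] * grho[, v]
      }
    }
  } else {
    gln <- sf$grad / pmax(sf$rho, rho_cut)
    gln[!live, ] <- 0
    for (b in 1:3) for (m in 1:3) for (v in 1:3) {
      if (.eps3[m, b, v] != 0) {
        tn[, , b] <- tn[, , b] + hc * .eps3[m, b, v] * gln[, v] * sf$CP[[m]]
      }
    }
  }
  if (scheme == "GPRO") {
    w <- ifelse(live, pmax(sf$rho, rho_cut)^(-2 / 3), 0)
    tn <- tn * as.vector(w)
  }
  tn
}

#' Unit-parameter current kernel
#'
#' The field K with total(param) = total(0) + param * K exactly, for any
#' parameter value; computed once and reusable for per-atom parameter
#' switching during single-pass shielding integration.
#'
#' @inheritParams co_current
#' @param scheme "GRRO" or "GPRO"
#' @param rho_cut density floor for the shift suppression
#' @return a `ctocd_current_field` (component "kernel")
#' @export
unit_parameter_kernel <- function(state, points, scheme = c("GRRO", "GPRO"),
                                  rho_cut = 1e-10) {
  scheme <- match.arg(scheme)
  points <- matrix(points, ncol = 3)
  eval_fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    sf <- .state_fields(state, pts)
    .tensor_kernel(sf, scheme, rho_cut)
  }
  .new_field(points, eval_fun(points), scheme, NULL, "kernel", eval_fun)
}

#' Total CTOCD (or CO) current-density tensor
#'
#' For GRRO/GPRO this equals the DZ1 field plus the scheme parameter times
#' the unit-parameter kernel; for param scheme "DZ1" it is the ipsocentric
#' field, for "CO" the common-origin field at the state's origin.
#'
#' @inheritParams ctocd_diamagnetic
#' @param param a `ctocd_scheme_parameter`
#' @return a `ctocd_current_field`
#' @export
total_current <- function(state, points, param) {
  stopifnot(inherits(param, "ctocd_scheme_parameter"))
  points <- matrix(points, ncol = 3)
  if (param$scheme == "CO") return(co_current(state, points))
  if (param$scheme == "DZ1") return(dz1_current(state, points))
  pv <- .param_value(param)
  r0 <- st_origin(state)
  eval_fun <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    sf <- .state_fields(state, pts)
    rel <- pts - matrix(r0, nrow(pts), 3, byrow = TRUE)
    .tensor_co_para(sf, c(0, 0, 0)) + .tensor_dz1_delta(sf, rel) +
      pv * .tensor_kernel(sf, param$scheme, param$rho_cut)
  }
  .new_field(points, eval_fun(points), param$scheme, pv, "total", eval_fun)
}

#' Numerical divergence of a current field
#'
#' Central-difference divergence of each column (magnetic-field component)
#' of the current-density tensor; for the exact field and for the CTOCD
#' diamagnetic term this vanishes identically (charge-current
#' conservation).
#'
#' @param field a `ctocd_current_field`
#' @param h central-difference step (bohr)
#' @param points optional alternative evaluation points (default: the
#'   field's own points)
#' @return N x 3 matrix: divergence (a.u./bohr) per field component beta
#' @export
divergence_map <- function(field, h = 1e-3, points = NULL) {
  if (!is.numeric(h) || h <= 0) stop("h must be a positive step length")
  pts <- if (is.null(points)) field$points else matrix(points, ncol = 3)
  N <- nrow(pts)
  div <- matrix(0, N, 3)
  for (d in 1:3) {
    dp <- pts; dp[, d] <- dp[, d] + h
    dm <- pts; dm[, d] <- dm[, d] - h
    tp <- field$eval(dp); tm <- field$eval(dm)
    div <- div + (matrix(tp[, d, ], N, 3) - matrix(tm[, d, ], N, 3)) / (2 * h)
  }
  div
}
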
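#' Build a converged ground state with magnetic and momentum response
#'
#' Runs a restricted closed-shell self-consistent-field calculation and
#' solves the coupled-perturbed equations for the six imaginary one-electron
#' perturbations the CTOCD construction needs: the three Cartesian
#' components of the total angular momentum about a common origin r0, and
#' the three components of the total linear momentum.  The resulting state
#' can evaluate the ground-state density, its gradient, and the six
#' response current kernels on arbitrary point sets.
#'
#' The common origin r0 defaults to the centre of nuclear charge; CTOCD
#' fields built from the state are invariant under its choice (this is the
#' whole point of the construction and is exercised by the test suite), so
#' it is internal scaffolding only.
#'
#' @param mol a `ctocd_molecule` (closed shell)
#' @param basis basis-set name ("STO-3G") or a custom named list mapping
#'   element symbols to shell lists (see [even_tempered_shells()])
#' @param method electronic-structure method; only "HF" (restricted
#'   Hartree-Fock) is available
#' @param scf_tol SCF energy convergence threshold (hartree)
#' @param response_tol residual threshold for the coupled-perturbed solve
#' @param origin optional common origin r0 (bohr, length-3)
#' @return an object of classes `ctocd_response_state`, `ctocd_state`
#' @export
build_response_state <- function(mol, basis = "STO-3G", method = "HF",
                                 scf_tol = 1e-10, response_tol = 1e-8,
                                 origin = NULL) {
  if (!toupper(method) %in% c("HF", "RHF")) {
    stop("unsupported method '", method,
         "'; the built-in engine provides restricted Hartree-Fock (\"HF\")")
  }
  bs <- build_basis(mol, basis)
  scf <- rhf_scf(bs, mol, tol = scf_tol)
  r0 <- if (is.null(origin)) center_of_nuclear_charge(mol) else as.numeric(origin)
  stopifnot(length(r0) == 3)
  Lw <- angmom_matrices(bs, r0)
  Pw <- derivative_matrices(bs)
  P_L <- cphf_imaginary(scf, Lw, tol = response_tol)
  P_P <- cphf_imaginary(scf, Pw, tol = response_tol)
  structure(
    list(molecule = mol, basis = bs,
         basis_name = if (is.character(basis)) basis else "custom",
         method = toupper(method),
         nelec = n_electrons(mol), scf = scf, scf_energy = scf$energy,
         origin = r0, P_L = P_L, P_P = P_P,
         scf_tol = scf_tol, response_tol = response_tol),
    class = c("ctocd_response_state", "ctocd_state"))
}

#' @export
print.ctocd_response_state <- function(x, ...) {
  cat(sprintf(
    "<response state: %d atoms, %s/%s, %d electrons, E = %.8f Eh>\n",
    n_atoms(x$molecule), x$method, x$basis_name, x$nelec, x$scf_energy))
  invisible(x)
}

st_molecule <- function(state) state$molecule
st_origin <- function(state) state$origin
st_nelec <- function(state) state$nelec

#' Evaluate the ground-state density and gradient
#'
#' @param state a `ctocd_state`
#' @param points N x 3 matrix of positions (bohr)
#' @return list with `rho` (length N, bohr^-3) and `grad` (N x 3, bohr^-4)
#' @export
evaluate_density <- function(state, points) {
  points <- matrix(points, ncol = 3)
  stopifnot(all(is.finite(points)))
  if (inherits(state, "ctocd_analytic_state")) {
    return(state$density_fun(points))
  }
  ao <- ao_eval(state$basis, points)
  .density_from_ao(state, ao)
}

.density_from_ao <- function(state, ao) {
  VD <- ao$val %*% state$scf$D
  rho <- rowSums(VD * ao$val)
  grad <- cbind(2 * rowSums(VD * ao$dx),
                2 * rowSums(VD * ao$dy),
                2 * rowSums(VD * ao$dz))
  list(rho = pmax(rho, 0), grad = grad)
}

## All per-point fields the current-density construction needs:
## rho, grad (N x 3), and the response current kernels
##   CL[[beta]], CP[[mu]]: N x 3 matrices with
##   C(r; P)_delta = sum_{mu nu} P_{mu nu} chi_mu(r) d_delta chi_nu(r),
## the first-order probability-current contribution per unit (imaginary)
## perturbation coefficient.
.state_fields <- function(state, pts) {
  pts <- matrix(pts, ncol = 3)
  N <- nrow(pts)
  zero3 <- function() matrix(0, N, 3)
  if (inherits(state, "ctocd_analytic_state")) {
    d <- state$density_fun(pts)
    return(list(rho = d$rho, grad = d$grad,
                CL = list(zero3(), zero3(), zero3()),
                CP = list(zero3(), zero3(), zero3())))
  }
  ao <- ao_eval(state$basis, pts)
  dens <- .density_from_ao(state, ao)
  ckern <- function(P) {
    VP <- ao$val %*% P
    cbind(rowSums(VP * ao$dx), rowSums(VP * ao$dy), rowSums(VP * ao$dz))
  }
  list(rho = dens$rho, grad = dens$grad,
       CL = lapply(state$P_L, ckern),
       CP = lapply(state$P_P, ckern))
}
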
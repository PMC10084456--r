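## Gaussian basis machinery: contracted Cartesian s/p shells.
##
## STO-3G parameters are the standard published exponents/contraction
## coefficients (Hehre, Stewart, Pople scheme) for the elements that occur
## in the fixtures.  An even-tempered generator is provided for
## convergence studies (e.g. momentum-response completeness for the DZ1
## limit of closed-shell atoms).

.sto3g_1s_coefs  <- c(0.1543289673, 0.5353281423, 0.4446345422)
.sto3g_2s_coefs  <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.sto3g_2p_coefs  <- c(0.1559162750, 0.6076837186, 0.3919573931)

.sto3g_data <- list(
  H  = list(list(l = 0L, exps = c(3.425250914, 0.6239137298, 0.1688554040),
                 coefs = .sto3g_1s_coefs)),
  He = list(list(l = 0L, exps = c(6.362421394, 1.158922999, 0.3136497915),
                 coefs = .sto3g_1s_coefs)),
  C  = list(list(l = 0L, exps = c(71.61683735, 13.04509632, 3.530512160),
                 coefs = .sto3g_1s_coefs),
            list(l = 0L, exps = c(2.941249355, 0.6834830964, 0.2222899159),
                 coefs = .sto3g_2s_coefs),
            list(l = 1L, exps = c(2.941249355, 0.6834830964, 0.2222899159),
                 coefs = .sto3g_2p_coefs)),
  N  = list(list(l = 0L, exps = c(99.10616896, 18.05231239, 4.885660238),
                 coefs = .sto3g_1s_coefs),
            list(l = 0L, exps = c(3.780455879, 0.8784966449, 0.2857143744),
                 coefs = .sto3g_2s_coefs),
            list(l = 1L, exps = c(3.780455879, 0.8784966449, 0.2857143744),
                 coefs = .sto3g_2p_coefs)),
  O  = list(list(l = 0L, exps = c(130.7093214, 23.80886605, 6.443608313),
                 coefs = .sto3g_1s_coefs),
            list(l = 0L, exps = c(5.033151319, 1.169596125, 0.3803889600),
                 coefs = .sto3g_2s_coefs),
            list(l = 1L, exps = c(5.033151319, 1.169596125, 0.3803889600),
                 coefs = .sto3g_2p_coefs))
)

#' Even-tempered shell specification for one element
#'
#' Geometric series of uncontracted s (and optionally p) exponents,
#' `alpha0 * ratio^(0:(n-1))`.
#'
#' @param n_s,alpha0_s,ratio_s s-shell count, smallest exponent, ratio
#' @param n_p,alpha0_p,ratio_p p-shell count, smallest exponent, ratio
#' @return a shell list usable as a custom basis entry in
#'   [build_response_state()]'s `basis` argument
#' @export
even_tempered_shells <- function(n_s, alpha0_s, ratio_s,
                                 n_p = 0, alpha0_p = 1, ratio_p = ratio_s) {
  sh <- lapply(alpha0_s * ratio_s^(seq_len(n_s) - 1),
               function(a) list(l = 0L, exps = a, coefs = 1))
  if (n_p > 0) {
    sh <- c(sh, lapply(alpha0_p * ratio_p^(seq_len(n_p) - 1),
                       function(a) list(l = 1L, exps = a, coefs = 1)))
  }
  sh
}

## primitive normalization for Cartesian gaussians, l <= 1
.prim_norm <- function(a, l) {
  if (l == 0L) (2 * a / pi)^0.75 else (2 * a / pi)^0.75 * 2 * sqrt(a)
}

## Build the flat shell table for a molecule.
## basis: "STO-3G", or a named list element -> shell list (each shell a
## list(l, exps, coefs)).
build_basis <- function(mol, basis = "STO-3G") {
  tab <- if (is.character(basis)) {
    if (toupper(basis) != "STO-3G") {
      stop("unknown basis set name '", basis, "'; built-in: STO-3G ",
           "(or pass a custom shell list)")
    }
    .sto3g_data
  } else basis
  shells <- list()
  ao_atom <- integer(0)
  ao_labels <- character(0)
  nao <- 0L
  for (ia in seq_len(n_atoms(mol))) {
    el <- mol$symbols[ia]
    esh <- tab[[el]]
    if (is.null(esh)) stop("no basis functions for element ", el)
    for (sh in esh) {
      l <- sh$l
      if (!l %in% c(0L, 1L)) stop("only s and p shells supported")
      ## contraction coefficients refer to normalized primitives; the
      ## same-center overlap of two normalized primitives is
      ## (2 sqrt(ab)/(a+b))^(l + 3/2), which renormalizes the contraction
      ## exactly.  Working coefficients below multiply *unnormalized*
      ## primitives.
      u <- outer(sh$exps, sh$exps,
                 function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
      s_self <- sum(outer(sh$coefs, sh$coefs) * u)
      c_n <- sh$coefs * vapply(sh$exps, .prim_norm, 0, l = l) / sqrt(s_self)
      ncomp <- if (l == 0L) 1L else 3L
      shells[[length(shells) + 1L]] <-
        list(l = l, exps = sh$exps, coefs = c_n,
             center = mol$coords[ia, ], atom = ia, ao_offset = nao)
      ao_atom <- c(ao_atom, rep(ia, ncomp))
      ao_labels <- c(ao_labels,
                     if (l == 0L) sprintf("%s%d s", el, ia)
                     else sprintf("%s%d p%s", el, ia, c("x", "y", "z")))
      nao <- nao + ncomp
    }
  }
  structure(list(shells = shells, n_ao = nao, ao_atom = ao_atom,
                 ao_labels = ao_labels, molecule = mol),
            class = "ctocd_basis")
}
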
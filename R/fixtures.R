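#' Built-in small-molecule test geometries
#'
#' Deterministic textbook geometries (no conformer search, no randomness),
#' used by tests and examples.  Bond lengths/angles: H2 0.7414 A; H2O
#' r(OH) = 0.9572 A, HOH 104.52 deg; NH3 r(NH) = 1.0116 A, HNH 106.7 deg;
#' CH4 r(CH) = 1.087 A tetrahedral; HCN r(CH) = 1.0655, r(CN) = 1.1532 A;
#' CO 1.1283 A; N2 1.0977 A.  Glycine and alanine are neutral
#' (non-zwitterionic) sp2/sp3 constructions with standard bond lengths,
#' intended for connectivity and environment-typing work.
#'
#' @param name one of "H2", "He", "H2O", "NH3", "CH4", "HCN", "CO", "N2",
#'   "glycine", "alanine"
#' @return a `ctocd_molecule` (bonds not perceived)
#' @export
#' @examples
#' make_fixture("H2O")
make_fixture <- function(name) {
  A <- .ctocd_const$bohr_per_angstrom
  geo <- switch(
    name,
    He = list(sym = "He", xyz = c(0, 0, 0)),
    H2 = list(sym = c("H", "H"),
              xyz = c(0, 0, 0,  0, 0, 0.7414)),
    H2O = {
      th <- (104.52 / 2) * pi / 180
      list(sym = c("O", "H", "H"),
           xyz = c(0, 0, 0,
                   0.9572 * sin(th), 0,  0.9572 * cos(th),
                  -0.9572 * sin(th), 0,  0.9572 * cos(th)))
    },
    NH3 = {
      hnh <- 106.7 * pi / 180
      ct <- sqrt((cos(hnh) + 0.5) / 1.5)   # polar angle from C3 axis
      st <- sqrt(1 - ct^2)
      r <- 1.0116
      xyz <- c(0, 0, 0)
      for (ph in c(0, 2 * pi / 3, 4 * pi / 3)) {
        xyz <- c(xyz, r * st * cos(ph), r * st * sin(ph), r * ct)
      }
      list(sym = c("N", "H", "H", "H"), xyz = xyz)
    },
    CH4 = {
      d <- 1.087 / sqrt(3)
      list(sym = c("C", "H", "H", "H", "H"),
           xyz = c(0, 0, 0,   d, d, d,   d, -d, -d,  -d, d, -d,  -d, -d, d))
    },
    HCN = list(sym = c("H", "C", "N"),
               xyz = c(-1.0655, 0, 0,  0, 0, 0,  1.1532, 0, 0)),
    CO = list(sym = c("C", "O"),
              xyz = c(0, 0, 0,  1.1283, 0, 0)),
    N2 = list(sym = c("N", "N"),
              xyz = c(0, 0, 0,  1.0977, 0, 0)),
    glycine = list(
      sym = c("C", "O", "O", "C", "H", "N", "H", "H", "H", "H"),
      xyz = c(0.000000,  0.000000,  0.000000,
              1.215000,  0.000000,  0.000000,
             -0.680000,  1.177795,  0.000000,
             -0.760000, -1.316359,  0.000000,
             -0.006181,  1.875554,  0.000000,
             -1.002485, -1.736356, -1.371797,
             -0.170904, -2.075990,  0.513835,
             -1.712408, -1.186002,  0.513835,
             -0.554956, -2.634145, -1.489239,
             -2.003758, -1.797679, -1.489239)),
    alanine = list(
      sym = c("C", "O", "O", "C", "H", "N", "H", "H", "H", "C",
              "H", "H", "H"),
      xyz = c(0.000000,  0.000000,  0.000000,
              1.215000,  0.000000,  0.000000,
             -0.680000,  1.177795,  0.000000,
             -0.760000, -1.316359,  0.000000,
             -0.006181,  1.875554,  0.000000,
             -1.002485, -1.736356, -1.371797,
             -0.170904, -2.075990,  0.513835,
             -0.554956, -2.634145, -1.489239,
             -2.003758, -1.797679, -1.489239,
             -2.096866, -1.133380,  0.721254,
             -2.911652, -1.210894,  0.001383,
             -2.208561, -1.906818,  1.481135,
             -2.122735, -0.152080,  1.195049)),
    stop("unknown fixture '", name, "'; available: ",
         paste(ctocd_fixtures(), collapse = ", "))
  )
  molecule(geo$sym, matrix(geo$xyz, ncol = 3, byrow = TRUE) * A)
}

#' Names of the built-in fixtures
#' @return character vector
#' @export
ctocd_fixtures <- function() {
  c("H2", "He", "H2O", "NH3", "CH4", "HCN", "CO", "N2", "glycine", "alanine")
}

#' Closed-form one-electron model states
#'
#' Builds an analytic state usable wherever a converged response state is
#' accepted: a single electron in a normalized s-type gaussian
#' (rho = (2a/pi)^(3/2) exp(-2a r^2)) or hydrogenic 1s
#' (rho = (Z^3/pi) exp(-2 Z r)) orbital centred at the origin.  The state
#' is spherical, so all angular-momentum and linear-momentum response
#' kernels vanish identically and the common-origin current is the pure
#' Larmor (diamagnetic) term; the Lamb formula then gives the shielding in
#' closed form, which pins the package's sign and prefactor conventions.
#'
#' @param kind "gaussian" or "hydrogenic"
#' @param exponent gaussian exponent a (bohr^-2) or nuclear charge Z
#' @return an object of classes `ctocd_analytic_state`, `ctocd_state`
#' @export
make_analytic_state <- function(kind = c("gaussian", "hydrogenic"),
                                exponent = 1) {
  kind <- match.arg(kind)
  stopifnot(exponent > 0)
  a <- exponent
  if (kind == "gaussian") {
    dens <- function(pts) {
      r2 <- rowSums(pts^2)
      rho <- (2 * a / pi)^1.5 * exp(-2 * a * r2)
      list(rho = rho, grad = pts * (-4 * a * rho))
    }
    inv_r <- 2 * sqrt(2 * a / pi)          # <1/r> = 2 sqrt(2a/pi)
  } else {
    dens <- function(pts) {
      r <- sqrt(rowSums(pts^2))
      rho <- (a^3 / pi) * exp(-2 * a * r)
      g <- -2 * a * rho / pmax(r, 1e-300)
      list(rho = rho, grad = pts * g)
    }
    inv_r <- a                              # <1/r> = Z
  }
  mol <- molecule(if (kind == "hydrogenic" && a <= 2) "H" else "He",
                  matrix(0, 1, 3))
  structure(
    list(kind = kind, exponent = a, molecule = mol, nelec = 1,
         origin = c(0, 0, 0), density_fun = dens, inv_r = inv_r),
    class = c("ctocd_analytic_state", "ctocd_state"))
}

#' @export
print.ctocd_analytic_state <- function(x, ...) {
  cat(sprintf("<analytic %s state, exponent %g, 1 electron>\n",
              x$kind, x$exponent))
  invisible(x)
}
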
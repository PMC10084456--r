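#' Physical constants and unit conversions (atomic units internally)
#'
#' All lengths inside the package are bohr, energies hartree, densities
#' bohr^-3.  XYZ files follow the de-facto convention and are Angstrom.
#' @name ctocd-constants
#' @keywords internal
NULL

## CODATA-style values; c in a.u. pins the Biot-Savart prefactor
.ctocd_const <- list(
  bohr_per_angstrom = 1.8897259886,
  angstrom_per_bohr = 1 / 1.8897259886,
  speed_of_light    = 137.035999,     # a.u.
  # Thomas-Fermi (Harris-Cina) value of the GPRO beta parameter:
  # beta_HC = -(3 pi^2)^(1/3) / (18 pi^2) = -0.0174
  beta_harris_cina  = -(3 * pi^2)^(1 / 3) / (18 * pi^2)
)

#' Lamb-formula isotropic shielding of a spherical density
#'
#' For a spherical closed-shell atom the diamagnetic (Larmor) current alone
#' determines the shielding, sigma = (1/3c^2) <1/r>, reported in ppm.
#'
#' @param inv_r expectation value of 1/r over the electron density (a.u.)
#' @return isotropic shielding in ppm
#' @export
#' @examples
#' lamb_shielding(1)   # hydrogenic 1s, Z = 1: 17.750 ppm
lamb_shielding <- function(inv_r) {
  1e6 * inv_r / (3 * .ctocd_const$speed_of_light^2)
}
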
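Package: ctocd
Title: Origin-Independent Induced Current Densities and NMR Shieldings via
    CTOCD-GRRO and CTOCD-GPRO
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes magnetically induced first-order current densities and
    isotropic nuclear magnetic shieldings with the continuous transformation
    of the origin of the current density (CTOCD) family of schemes, in the
    GRRO (gradient of rho) and GPRO (gradient of a power of rho) variants
    whose shift function d(r) = r - f(rho) grad ln rho yields a divergenceless
    diamagnetic component.  Both schemes depend linearly on a single scheme
    parameter (alpha for GRRO, beta for GPRO), which the package exploits for
    two-point analytical calibration of per-nucleus, per-element or
    per-chemical-environment parameters against reference shieldings.
    Shieldings for all nuclei of a molecule are obtained in a single
    Biot-Savart integration pass over a Becke multicenter quadrature with a
    per-atom parameter switch.  A compact restricted Hartree-Fock and
    coupled-perturbed response backend (s/p Gaussian bases) supplies the
    perturbed densities; closed-form one-electron model states are provided
    for validation against the Lamb formula.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
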
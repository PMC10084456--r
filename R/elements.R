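## Static element data: atomic numbers, covalent radii (Cordero 2008, in
## Angstrom) and Bragg-Slater radii (Slater 1964, in Angstrom; hydrogen set
## to 0.35 A as is customary for Becke cell size adjustment, noble gases
## filled in from neighbouring values).  Covers the elements that occur in
## amino acids and the small-molecule fixtures, plus the first two rows.

.element_table <- data.frame(
  symbol = c("H", "He",
             "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z = 1:18,
  r_cov = c(0.31, 0.28,
            1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06),
  r_slater = c(0.35, 0.30,
               1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.55,
               1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 1.05),
  stringsAsFactors = FALSE
)

#' Element data lookup
#'
#' Returns the static per-element data the package ships: atomic number,
#' covalent radius and Bragg-Slater radius (both Angstrom).
#'
#' @param symbols character vector of element symbols
#' @return data.frame with one row per requested symbol
#' @export
element_data <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  .element_table[idx, , drop = FALSE]
}

atomic_number <- function(symbols) element_data(symbols)$Z

covalent_radius_bohr <- function(symbols) {
  element_data(symbols)$r_cov * .ctocd_const$bohr_per_angstrom
}

slater_radius_bohr <- function(symbols) {
  element_data(symbols)$r_slater * .ctocd_const$bohr_per_angstrom
}
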
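#' Chemical-environment atom typing
#'
#' Assigns each atom a canonical chemical-environment key used to select
#' differentiated scheme parameters.  Heavy atoms are identified by their
#' element plus the sorted multiset of nearest-neighbour elements; hydrogens
#' additionally carry the sorted multiset of second-shell elements (the
#' neighbours of the attached atom, excluding the hydrogen itself), which
#' makes proton parameters transferable between molecules.  Keys are pure
#' connectivity: no aromaticity or hybridisation perception.
#'
#' The canonical tag reads `El[shell1]` for heavy atoms and
#' `H[shell1][shell2]` for hydrogens, with shells as comma-separated sorted
#' element symbols; it is invariant under atom reordering and isometries.
#'
#' @param mol a `ctocd_molecule` with perceived bonds
#' @param idx atom index
#' @return character scalar, the environment key
#' @seealso [classify_molecule()]
#' @export
classify_atom <- function(mol, idx) {
  n <- n_atoms(mol)
  if (!(is.numeric(idx) && length(idx) == 1 && idx >= 1 && idx <= n)) {
    stop("atom index out of range: ", idx)
  }
  idx <- as.integer(idx)
  adj <- bond_adjacency(mol)
  shell1 <- sort(mol$symbols[adj[[idx]]])
  el <- mol$symbols[idx]
  if (el == "H") {
    shell2 <- character(0)
    for (j in adj[[idx]]) {
      shell2 <- c(shell2, mol$symbols[setdiff(adj[[j]], idx)])
    }
    sprintf("H[%s][%s]", paste(shell1, collapse = ","),
            paste(sort(shell2), collapse = ","))
  } else {
    sprintf("%s[%s]", el, paste(shell1, collapse = ","))
  }
}

#' Classify every atom of a molecule
#'
#' @param mol a `ctocd_molecule`; bonds are perceived on the fly if absent
#' @return character vector of environment keys, one per atom (named by
#'   element symbol), with attribute `n_distinct`
#' @export
classify_molecule <- function(mol) {
  if (is.null(mol$bonds)) mol <- perceive_bonds(mol)
  keys <- vapply(seq_len(n_atoms(mol)), function(i) classify_atom(mol, i), "")
  names(keys) <- mol$symbols
  attr(keys, "n_distinct") <- length(unique(keys))
  keys
}

#' Export an atom -> environment-key map as JSON
#'
#' @param mol a `ctocd_molecule`
#' @param path output path; if NULL the JSON string is returned
#' @return the JSON string, invisibly when written to file
#' @export
envtype_json <- function(mol, path = NULL) {
  if (is.null(mol$bonds)) mol <- perceive_bonds(mol)
  keys <- classify_molecule(mol)
  obj <- list(atoms = data.frame(index = seq_along(keys),
                                 element = mol$symbols,
                                 key = as.character(keys),
                                 stringsAsFactors = FALSE),
              n_distinct = attr(keys, "n_distinct"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
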
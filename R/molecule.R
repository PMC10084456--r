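#' Molecular geometry container
#'
#' Constructs a molecule object holding element symbols, Cartesian
#' coordinates in bohr, total charge, spin multiplicity and (optionally
#' perceived) bonds.  Internal unit of length is bohr everywhere.
#'
#' @param symbols character vector of element symbols
#' @param coords numeric n x 3 matrix of positions in bohr
#' @param charge integer total charge (default 0)
#' @param multiplicity integer spin multiplicity (default 1)
#' @param bonds integer 2-column matrix of atom index pairs, or NULL
#' @return an object of class `ctocd_molecule`
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                     bonds = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords)) {
    stop("length(symbols) must equal nrow(coords)")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  Z <- atomic_number(symbols)
  n <- length(symbols)
  if (n > 1) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    if (min(d) < 0.5) {
      stop("two atoms closer than 0.5 bohr (min distance ",
           format(min(d), digits = 4), ")")
    }
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    stopifnot(all(bonds >= 1), all(bonds <= n), all(bonds[, 1] != bonds[, 2]))
  }
  structure(
    list(symbols = as.character(symbols), Z = Z, coords = coords,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity),
         bonds = bonds),
    class = "ctocd_molecule")
}

#' @export
print.ctocd_molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms [%s], charge %d, mult %d, %s>\n",
              length(x$symbols),
              paste(unique(x$symbols), collapse = ","),
              x$charge, x$multiplicity,
              if (is.null(x$bonds)) "bonds not perceived"
              else sprintf("%d bonds", nrow(x$bonds))))
  invisible(x)
}

n_atoms <- function(mol) length(mol$symbols)

n_electrons <- function(mol) sum(mol$Z) - mol$charge

#' Read a molecule from an XYZ document
#'
#' Standard XYZ dialect: first line atom count, second line comment, then
#' one `symbol x y z` row per atom with coordinates in Angstrom (converted
#' to bohr internally).  The comment line may carry `charge=<int>` and
#' `mult=<int>` tokens.
#'
#' @param path_or_text path to an XYZ file, or a character vector holding
#'   the document itself (with embedded newlines or one element per line)
#' @return a `ctocd_molecule` (bonds not perceived)
#' @export
read_xyz <- function(path_or_text) {
  if (length(path_or_text) == 1 && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    lines <- readLines(path_or_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  if (length(lines) < 2) stop("XYZ parse error: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("XYZ parse error at line 1: atom count must be a positive integer, got '",
         trimws(lines[1]), "'")
  }
  if (length(lines) < n + 2) {
    stop("XYZ parse error: expected ", n, " atom rows, found ",
         max(0L, length(lines) - 2L))
  }
  comment <- lines[2]
  charge <- 0L; mult <- 1L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2) charge <- as.integer(m[2])
  m <- regmatches(comment, regexec("mult=([0-9]+)", comment))[[1]]
  if (length(m) == 2) mult <- as.integer(m[2])

  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 2])
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error at line ", i + 2, ": expected 'symbol x y z', got '",
           ln, "'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", i + 2, ": non-numeric coordinate in '",
           ln, "'")
    }
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  molecule(symbols, coords * .ctocd_const$bohr_per_angstrom,
           charge = charge, multiplicity = mult)
}

#' Write a molecule to XYZ (Angstrom)
#'
#' @param mol a `ctocd_molecule`
#' @param path output path; if NULL the document is returned as a character
#'   vector of lines
#' @param comment comment line content; charge/multiplicity tokens are
#'   appended when non-default
#' @return invisibly, the lines written
#' @export
write_xyz <- function(mol, path = NULL, comment = "") {
  if (mol$charge != 0L || mol$multiplicity != 1L) {
    comment <- trimws(paste(comment,
                            sprintf("charge=%d mult=%d",
                                    mol$charge, mol$multiplicity)))
  }
  ang <- mol$coords * .ctocd_const$angstrom_per_bohr
  rows <- sprintf("%-3s %20.12f %20.12f %20.12f",
                  mol$symbols, ang[, 1], ang[, 2], ang[, 3])
  lines <- c(as.character(n_atoms(mol)), comment, rows)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Perceive covalent bonds from interatomic distances
#'
#' A bond is assigned between atoms i and j when their distance does not
#' exceed `scale` times the sum of their covalent radii.  Isolated atoms are
#' allowed; self-bonds never occur and the perceived set is symmetric by
#' construction.
#'
#' @param mol a `ctocd_molecule`
#' @param scale dimensionless tolerance factor (default 1.2)
#' @return the molecule with `$bonds` set (2-column matrix, i < j)
#' @export
perceive_bonds <- function(mol, scale = 1.2) {
  n <- n_atoms(mol)
  if (n < 2) {
    mol$bonds <- matrix(integer(0), ncol = 2)
    return(mol)
  }
  rc <- covalent_radius_bohr(mol$symbols)
  d <- as.matrix(stats::dist(mol$coords))
  thr <- outer(rc, rc, "+") * scale
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- matrix(as.integer(hit), ncol = 2,
                      dimnames = NULL)[order(hit[, 1], hit[, 2]), , drop = FALSE]
  mol
}

## adjacency list (list of integer vectors) from the bond matrix
bond_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(integer(0)), n)
  if (is.null(mol$bonds)) stop("bonds not perceived; call perceive_bonds()")
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

## center of nuclear charge, the default common origin of the backend
center_of_nuclear_charge <- function(mol) {
  colSums(mol$coords * mol$Z) / sum(mol$Z)
}
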
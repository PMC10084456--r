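## Reports, parameter-table serialization and Gaussian cube export.

#' Write a shielding report
#'
#' CSV columns / JSON fields: nucleus index, element, environment key,
#' scheme, per-atom parameter, isotropic shielding (ppm) and the full
#' 3 x 3 tensor (row-major).  JSON output carries a provenance header.
#'
#' @param result a `ctocd_shielding_result`
#' @param path output path ending in .csv or .json
#' @param provenance optional named list merged into the JSON provenance
#' @return invisibly, the report data.frame
#' @export
write_shielding_report <- function(result, path, provenance = list()) {
  mol <- result$molecule
  keys <- tryCatch(as.character(classify_molecule(mol)),
                   error = function(e) rep(NA_character_, n_atoms(mol)))
  df <- as.data.frame(result)
  df$key <- keys
  tens <- t(vapply(seq_len(dim(result$tensors)[1]),
                   function(n) as.vector(t(result$tensors[n, , ])),
                   numeric(9)))
  colnames(tens) <- paste0("sigma_",
                           as.vector(t(outer(c("x", "y", "z"),
                                             c("x", "y", "z"), paste0))))
  df <- cbind(df, tens)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(provenance = c(list(scheme = result$scheme,
                                    grid = result$grid), provenance),
                nuclei = df)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}

#' Serialize a parameter table to JSON (with provenance header)
#'
#' @param table a `ctocd_parameter_table`
#' @param path output path
#' @return invisibly, the JSON string
#' @export
write_parameter_table <- function(table, path) {
  obj <- list(scheme = attr(table, "scheme"),
              grouping = attr(table, "grouping"),
              provenance = attr(table, "provenance"),
              entries = as.data.frame(table))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(js, path)
  invisible(js)
}

#' Read a parameter table written by [write_parameter_table()]
#'
#' @param path JSON path
#' @return a `ctocd_parameter_table`
#' @export
read_parameter_table <- function(path) {
  obj <- jsonlite::fromJSON(path)
  out <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  attr(out, "scheme") <- obj$scheme
  attr(out, "grouping") <- obj$grouping
  attr(out, "provenance") <- obj$provenance
  class(out) <- c("ctocd_parameter_table", "data.frame")
  out
}

#' Read reference shieldings (nucleus index -> sigma in ppm)
#'
#' Accepts JSON (object index -> value, or records with nucleus/sigma
#' fields) or CSV with columns `nucleus`, `sigma`.
#'
#' @param path input path
#' @return named numeric vector
#' @export
read_references <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.data.frame(obj)) {
      return(stats::setNames(as.numeric(obj$sigma),
                             as.character(obj$nucleus)))
    }
    v <- unlist(obj)
    if (length(v) == 0) stop("empty reference file: ", path)
    return(stats::setNames(as.numeric(v), names(v)))
  }
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty reference file: ", path)
  stats::setNames(as.numeric(df$sigma), as.character(df$nucleus))
}

## ---- Gaussian cube ---------------------------------------------------

#' Write a volumetric field as a Gaussian cube file
#'
#' Standard cube layout (lengths in bohr, negative N convention not used,
#' so units are bohr); the two comment lines carry the supplied
#' provenance.  Values must be ordered with z fastest, then y, then x.
#'
#' @param path output path
#' @param mol a `ctocd_molecule`
#' @param origin grid origin (bohr)
#' @param step length-3 spacing along the three axes (bohr, axes are
#'   Cartesian)
#' @param n length-3 point counts
#' @param values numeric vector of length prod(n), z fastest
#' @param comment up to two comment lines (provenance)
#' @return invisibly, the path
#' @export
write_cube <- function(path, mol, origin, step, n, values,
                       comment = c("ctocd volumetric field", "")) {
  n <- as.integer(n)
  stopifnot(length(n) == 3, length(values) == prod(n))
  con <- file(path, "w")
  on.exit(close(con))
  cm <- c(comment, "", "")[1:2]
  writeLines(cm, con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f",
                     n_atoms(mol), origin[1], origin[2], origin[3]), con)
  ax <- diag(step, 3)
  for (d in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f",
                       n[d], ax[d, 1], ax[d, 2], ax[d, 3]), con)
  }
  for (a in seq_len(n_atoms(mol))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       mol$Z[a], as.numeric(mol$Z[a]),
                       mol$coords[a, 1], mol$coords[a, 2],
                       mol$coords[a, 3]), con)
  }
  ## z fastest; 6 values per line
  for (ix in seq_len(n[1])) for (iy in seq_len(n[2])) {
    col <- values[((ix - 1) * n[2] + (iy - 1)) * n[3] + seq_len(n[3])]
    for (s in seq(1, n[3], by = 6)) {
      e <- min(s + 5, n[3])
      writeLines(paste(sprintf("%13.5E", col[s:e]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path cube path
#' @return list with `comment`, `origin`, `step`, `n`, `coords`, `Z`,
#'   `values` (z fastest)
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  comment <- lines[1:2]
  hd <- function(ln) as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
  h <- hd(lines[3]); nat <- as.integer(h[1]); origin <- h[2:4]
  n <- integer(3); step <- numeric(3)
  for (d in 1:3) {
    v <- hd(lines[3 + d]); n[d] <- as.integer(v[1]); step[d] <- v[d + 1]
  }
  Z <- integer(nat); coords <- matrix(0, nat, 3)
  for (a in seq_len(nat)) {
    v <- hd(lines[6 + a]); Z[a] <- as.integer(v[1]); coords[a, ] <- v[3:5]
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + nat))]),
                                     "[[:space:]]+")))
  list(comment = comment, origin = origin, step = step, n = n,
       coords = coords, Z = Z, values = vals)
}

#' Export a current-field quantity on a regular grid as a cube file
#'
#' @param field a `ctocd_current_field` (its closure is re-evaluated on
#'   the regular grid)
#' @param mol the molecule (for the cube atom block)
#' @param path output path
#' @param origin,step,n regular-grid specification (bohr)
#' @param quantity "jmod" (Frobenius norm of the tensor) or "column"
#'   (tensor column `beta`, component `delta`)
#' @param delta,beta tensor indices used when `quantity = "column"`
#' @return invisibly, the path
#' @export
field_cube <- function(field, mol, path, origin, step, n,
                       quantity = c("jmod", "column"), delta = 1, beta = 3) {
  quantity <- match.arg(quantity)
  n <- as.integer(n)
  gx <- origin[1] + step[1] * (seq_len(n[1]) - 1)
  gy <- origin[2] + step[2] * (seq_len(n[2]) - 1)
  gz <- origin[3] + step[3] * (seq_len(n[3]) - 1)
  ## z fastest ordering
  pts <- cbind(rep(gx, each = n[2] * n[3]),
               rep(rep(gy, each = n[3]), times = n[1]),
               rep(gz, times = n[1] * n[2]))
  tn <- field$eval(pts)
  vals <- if (quantity == "jmod") {
    sqrt(rowSums(matrix(tn, nrow(pts))^2))
  } else {
    tn[, delta, beta]
  }
  write_cube(path, mol, origin, step, n, vals,
             comment = c(sprintf("ctocd current field: %s/%s quantity=%s",
                                 field$scheme, field$component, quantity),
                         sprintf("param=%s delta=%d beta=%d",
                                 format(field$param), delta, beta)))
}
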
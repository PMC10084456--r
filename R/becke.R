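#' Becke multicenter partition weights
#'
#' Smooth relative weight functions w_A(r) with sum_A w_A(r) = 1
#' everywhere, w_A = 1 near its own nucleus and vanishing near any other,
#' built from the k-fold iterated cutoff polynomial p(x) = (3x - x^3)/2 on
#' the confocal elliptical coordinate of each atom pair.  With
#' `radii_mode = "bragg-slater"` the cell boundaries are shifted according
#' to the ratio of Bragg-Slater atomic radii (hydrogen 0.35 Angstrom),
#' with the standard |a| <= 1/2 clip on the shift parameter.
#'
#' @param mol a `ctocd_molecule`
#' @param points N x 3 matrix (bohr)
#' @param k smoothing iteration count (default 3)
#' @param radii_mode "bragg-slater" (size-adjusted cells) or "uniform"
#' @return N x n_atoms matrix of weights (rows sum to 1)
#' @export
becke_weights <- function(mol, points, k = 3,
                          radii_mode = c("bragg-slater", "uniform")) {
  radii_mode <- match.arg(radii_mode)
  stopifnot(k >= 1)
  points <- matrix(points, ncol = 3)
  nat <- n_atoms(mol)
  N <- nrow(points)
  if (nat == 1) return(matrix(1, N, 1))
  ## distances point -> atom
  dist_pa <- vapply(seq_len(nat), function(a) {
    sqrt(rowSums((points - matrix(mol$coords[a, ], N, 3, byrow = TRUE))^2))
  }, numeric(N))
  dist_pa <- matrix(dist_pa, N, nat)
  R <- as.matrix(stats::dist(mol$coords))
  radii <- slater_radius_bohr(mol$symbols)
  smooth <- function(mu) {
    for (i in seq_len(k)) mu <- 0.5 * mu * (3 - mu^2)
    mu
  }
  P <- matrix(1, N, nat)
  for (a in seq_len(nat)) for (b in seq_len(nat)) {
    if (a == b) next
    mu <- (dist_pa[, a] - dist_pa[, b]) / R[a, b]
    if (radii_mode == "bragg-slater") {
      chi <- radii[a] / radii[b]
      u <- (chi - 1) / (chi + 1)
      aab <- u / (u^2 - 1)
      aab <- max(min(aab, 0.5), -0.5)
      mu <- mu + aab * (1 - mu^2)
    }
    P[, a] <- P[, a] * 0.5 * (1 - smooth(mu))
  }
  P / rowSums(P)
}

#' Atom-centred molecular quadrature grid
#'
#' Product grids per atom: a Gauss-Legendre radial rule mapped to
#' (0, infinity) by r = R_m (1+x)/(1-x) with R_m the atom's Bragg-Slater
#' radius, and a Gauss-Legendre (cos theta) x uniform (phi) angular rule.
#' Point weights combine the quadrature weight with the atom's Becke
#' partition weight, so plain weighted sums integrate molecular functions.
#'
#' @param mol a `ctocd_molecule`
#' @param radial_n radial points per atom (default 70)
#' @param n_theta,n_phi angular orders (default 24 x 48)
#' @param k Becke smoothing iterations
#' @param radii_mode passed to [becke_weights()]
#' @return object of class `ctocd_grid`: list with `points` (N x 3),
#'   `weights` (quadrature x partition), `atom` (cell index per point) and
#'   the generating parameters
#' @export
molecular_grid <- function(mol, radial_n = 70, n_theta = 24, n_phi = 48,
                           k = 3, radii_mode = c("bragg-slater", "uniform")) {
  radii_mode <- match.arg(radii_mode)
  if (radial_n < 2 || n_theta < 2 || n_phi < 4) {
    stop("unsupported grid orders (radial_n >= 2, n_theta >= 2, n_phi >= 4)")
  }
  gl_r <- pracma::gaussLegendre(radial_n, -1, 1)
  gl_t <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  w_phi <- 2 * pi / n_phi
  ## unit sphere directions and angular weights
  ct <- gl_t$x; st <- sqrt(1 - ct^2)
  dirs <- matrix(0, n_theta * n_phi, 3)
  w_ang <- numeric(n_theta * n_phi)
  idx <- 1L
  for (it in seq_len(n_theta)) for (ip in seq_len(n_phi)) {
    dirs[idx, ] <- c(st[it] * cos(phi[ip]), st[it] * sin(phi[ip]), ct[it])
    w_ang[idx] <- gl_t$w[it] * w_phi
    idx <- idx + 1L
  }
  radii <- slater_radius_bohr(mol$symbols)
  nat <- n_atoms(mol)
  pts_list <- list(); w_list <- list(); atom_list <- list()
  for (a in seq_len(nat)) {
    Rm <- radii[a]
    r <- Rm * (1 + gl_r$x) / (1 - gl_r$x)
    drdx <- 2 * Rm / (1 - gl_r$x)^2
    w_rad <- gl_r$w * drdx * r^2
    ## all radial x angular combinations
    pa <- kronecker(r, dirs)                    # radial-major, angular fast
    wa <- rep(w_rad, each = nrow(dirs)) * rep(w_ang, times = radial_n)
    pa <- pa + matrix(mol$coords[a, ], nrow(pa), 3, byrow = TRUE)
    pts_list[[a]] <- pa
    w_list[[a]] <- wa
    atom_list[[a]] <- rep(a, length(wa))
  }
  points <- do.call(rbind, pts_list)
  w_quad <- unlist(w_list)
  atom <- unlist(atom_list)
  wB <- becke_weights(mol, points, k = k, radii_mode = radii_mode)
  w_part <- wB[cbind(seq_len(nrow(points)), atom)]
  structure(list(points = points, weights = w_quad * w_part,
                 w_quad = w_quad, w_partition = w_part, atom = atom,
                 radial_n = radial_n, n_theta = n_theta, n_phi = n_phi,
                 k = k, radii_mode = radii_mode, molecule = mol),
            class = "ctocd_grid")
}

#' @export
print.ctocd_grid <- function(x, ...) {
  cat(sprintf(
    "<molecular grid: %d atoms x (%d radial x %d x %d angular) = %d points, Becke k = %d, %s radii>\n",
    n_atoms(x$molecule), x$radial_n, x$n_theta, x$n_phi,
    nrow(x$points), x$k, x$radii_mode))
  invisible(x)
}

#' Integrate a per-point function over a molecular grid
#'
#' @param grid a `ctocd_grid`
#' @param values numeric vector (length = number of grid points) or a
#'   function of an N x 3 point matrix returning such a vector
#' @return the integral (weighted sum)
#' @export
grid_integrate <- function(grid, values) {
  if (is.function(values)) values <- values(grid$points)
  sum(grid$weights * values)
}
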
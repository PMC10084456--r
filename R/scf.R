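## Restricted closed-shell Hartree-Fock and the coupled-perturbed equations
## for purely imaginary one-electron perturbations (magnetic field /
## angular momentum, linear momentum).  Sizes here are small (tens of
## basis functions), so Fock builds use the stored ERI tensor and the
## response equations are solved directly as a dense linear system.

nuclear_repulsion <- function(mol) {
  n <- n_atoms(mol)
  if (n < 2) return(0)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    e <- e + mol$Z[i] * mol$Z[j] /
      sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
  }
  e
}

## G[D] = J - K/2 for a symmetric density matrix (RHF convention, D
## contains the factor 2 over occupied orbitals)
.fock_2e <- function(Gm, D) {
  n <- dim(Gm)[1]
  Gmat <- matrix(aperm(Gm, c(1, 2, 3, 4)), n * n, n * n)
  J <- matrix(Gmat %*% as.vector(D), n, n)
  Km <- matrix(aperm(Gm, c(1, 3, 2, 4)), n * n, n * n)
  K <- matrix(Km %*% as.vector(D), n, n)
  J - 0.5 * K
}

rhf_scf <- function(basis, mol = basis$molecule, tol = 1e-10,
                    max_iter = 200) {
  nel <- n_electrons(mol)
  if (mol$multiplicity != 1L || nel %% 2 != 0) {
    stop("only closed-shell (even electron count, multiplicity 1) systems ",
         "are supported")
  }
  nocc <- nel %/% 2
  S <- overlap_matrix(basis)
  Tm <- kinetic_matrix(basis)
  V <- nuclear_attraction_matrix(basis, mol)
  H <- Tm + V
  Gm <- eri_tensor(basis)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    stop("near-linear dependence in basis (min overlap eigenvalue ",
         format(min(es$values), digits = 3), ")")
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  diagonalize <- function(Fm) {
    Fp <- t(X) %*% Fm %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    list(C = X %*% ev$vectors[, ord, drop = FALSE], eps = ev$values[ord])
  }
  density_of <- function(C) {
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    2 * Cocc %*% t(Cocc)
  }
  ## core guess
  sol <- diagonalize(H)
  C <- sol$C; eps <- sol$eps
  D <- density_of(C)
  energy_old <- Inf
  err_list <- list(); fock_list <- list()
  conv <- FALSE
  d_e <- Inf
  for (it in seq_len(max_iter)) {
    Fm <- H + .fock_2e(Gm, D)
    energy <- 0.5 * sum(D * (H + Fm)) + nuclear_repulsion(mol)
    ## DIIS on the orthonormalized gradient FDS - SDF
    err <- X %*% (Fm %*% D %*% S - S %*% D %*% Fm) %*% X
    d_e <- abs(energy - energy_old)
    d_g <- max(abs(err))
    energy_old <- energy
    if (d_e < tol && d_g < sqrt(tol)) { conv <- TRUE; break }
    err_list <- c(err_list, list(err)); fock_list <- c(fock_list, list(Fm))
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m) {
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      }
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cw <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cw) && all(is.finite(cw))) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, cw))
      }
    }
    sol <- diagonalize(Fm)
    C <- sol$C; eps <- sol$eps
    D <- density_of(C)
  }
  energy <- energy_old
  if (!conv) {
    stop("SCF did not converge in ", max_iter,
         " iterations (last dE = ", format(d_e, digits = 3), ")")
  }
  list(C = C, eps = eps, D = D, energy = energy, n_occ = nocc,
       S = S, H = H, eri = Gm, X = X, n_iter = it)
}

## Coupled-perturbed HF for an imaginary Hermitian perturbation O = -i W
## with W a real antisymmetric AO matrix.  Returns the real antisymmetric
## first-order density matrix P (the full perturbed density is D1 = i P)
## satisfying (eps_a - eps_i) u_ai + K_ai[P(u)] = W_ai, with only the
## exchange part of the two-electron response surviving (the Coulomb
## contraction of a symmetric ERI with an antisymmetric density vanishes).
cphf_imaginary <- function(scf, W_list, tol = 1e-8) {
  C <- scf$C; eps <- scf$eps; nocc <- scf$n_occ
  n <- ncol(C)
  nv <- n - nocc
  if (nv == 0) {
    return(lapply(W_list, function(W) matrix(0, n, n)))
  }
  occ <- seq_len(nocc); vir <- nocc + seq_len(nv)
  Co <- C[, occ, drop = FALSE]; Cv <- C[, vir, drop = FALSE]
  Gm <- scf$eri
  nK <- matrix(aperm(Gm, c(1, 3, 2, 4)), n * n, n * n)
  Kop <- function(P) {
    ## exchange response: K[P]_{mu nu} = -1/2 sum (mu la | nu si) P_{la si}
    -0.5 * matrix(nK %*% as.vector(P), n, n)
  }
  pmat <- function(u) {
    ## P = 2 sum_ai u_ai (C_a C_i^T - C_i C_a^T)
    U <- matrix(u, nv, nocc)
    M <- Cv %*% U %*% t(Co)
    2 * (M - t(M))
  }
  de <- outer(eps[vir], eps[occ], "-")   # nv x nocc
  nov <- nv * nocc
  ## build the response operator column by column (sizes are tiny)
  A <- matrix(0, nov, nov)
  for (k in seq_len(nov)) {
    u <- numeric(nov); u[k] <- 1
    P <- pmat(u)
    Kai <- t(Cv) %*% Kop(P) %*% Co
    A[, k] <- as.vector(de * matrix(u, nv, nocc) + Kai)
  }
  lapply(W_list, function(W) {
    Wai <- t(Cv) %*% W %*% Co
    u <- solve(A, as.vector(Wai))
    resid <- max(abs(A %*% u - as.vector(Wai)))
    if (!is.finite(resid) || resid > tol * max(1, max(abs(Wai)))) {
      stop("coupled-perturbed equations failed to reach tolerance")
    }
    pmat(u)
  })
}
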
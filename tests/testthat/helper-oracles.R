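## Independent oracles used across the suite.

## ---- s-only restricted Hartree-Fock (closed-form s-Gaussian integrals,
##      plain fixed-point SCF).  Entirely separate from the package's
##      McMurchie-Davidson engine; used to pin SCF energies for He/H2.
oracle_s_only_rhf <- function(centers, exps_list, coefs_list, Z, nocc,
                              tol = 1e-12) {
  F0 <- function(t) ifelse(t < 1e-13, 1 - t / 3,
                           0.5 * sqrt(pi / pmax(t, 1e-300)) *
                             pracma::erf(sqrt(pmax(t, 0))))
  nb <- length(exps_list)
  norm_c <- Map(function(e, c) c * (2 * e / pi)^0.75, exps_list, coefs_list)
  S <- matrix(0, nb, nb); TT <- matrix(0, nb, nb); V <- matrix(0, nb, nb)
  for (i in 1:nb) for (j in 1:nb) {
    RA <- centers[[i]]; RB <- centers[[j]]
    R2 <- sum((RA - RB)^2)
    for (ka in seq_along(exps_list[[i]])) for (kb in seq_along(exps_list[[j]])) {
      a <- exps_list[[i]][ka]; b <- exps_list[[j]][kb]
      cc <- norm_c[[i]][ka] * norm_c[[j]][kb]
      p <- a + b
      s0 <- (pi / p)^1.5 * exp(-a * b / p * R2)
      S[i, j] <- S[i, j] + cc * s0
      TT[i, j] <- TT[i, j] + cc * a * b / p * (3 - 2 * a * b / p * R2) * s0
      P <- (a * RA + b * RB) / p
      for (ic in seq_along(Z)) {
        PC2 <- sum((P - centers[[ic]])^2)
        V[i, j] <- V[i, j] - cc * Z[ic] * 2 * pi / p *
          exp(-a * b / p * R2) * F0(p * PC2)
      }
    }
  }
  G <- array(0, c(nb, nb, nb, nb))
  for (i in 1:nb) for (j in 1:nb) for (k in 1:nb) for (l in 1:nb) {
    for (ka in seq_along(exps_list[[i]])) for (kb in seq_along(exps_list[[j]])) {
      a <- exps_list[[i]][ka]; b <- exps_list[[j]][kb]
      p <- a + b
      P <- (a * centers[[i]] + b * centers[[j]]) / p
      kab <- exp(-a * b / p * sum((centers[[i]] - centers[[j]])^2))
      for (kc in seq_along(exps_list[[k]])) for (kd in seq_along(exps_list[[l]])) {
        cpc <- exps_list[[k]][kc]; d <- exps_list[[l]][kd]
        q <- cpc + d
        Q <- (cpc * centers[[k]] + d * centers[[l]]) / q
        kcd <- exp(-cpc * d / q * sum((centers[[k]] - centers[[l]])^2))
        tt <- p * q / (p + q) * sum((P - Q)^2)
        G[i, j, k, l] <- G[i, j, k, l] +
          norm_c[[i]][ka] * norm_c[[j]][kb] * norm_c[[k]][kc] *
          norm_c[[l]][kd] *
          2 * pi^2.5 / (p * q * sqrt(p + q)) * kab * kcd * F0(tt)
      }
    }
  }
  H <- TT + V
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nb) %*% t(es$vectors)
  D <- matrix(0, nb, nb)
  for (it in 1:300) {
    J <- matrix(matrix(G, nb^2, nb^2) %*% as.vector(D), nb, nb)
    K <- matrix(matrix(aperm(G, c(1, 3, 2, 4)), nb^2, nb^2) %*% as.vector(D),
                nb, nb)
    Fm <- H + J - 0.5 * K
    Fp <- t(X) %*% Fm %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    C <- X %*% ev$vectors[, order(ev$values), drop = FALSE]
    Dn <- 2 * C[, 1:nocc, drop = FALSE] %*% t(C[, 1:nocc, drop = FALSE])
    if (max(abs(Dn - D)) < tol) { D <- Dn; break }
    D <- Dn
  }
  J <- matrix(matrix(G, nb^2, nb^2) %*% as.vector(D), nb, nb)
  K <- matrix(matrix(aperm(G, c(1, 3, 2, 4)), nb^2, nb^2) %*% as.vector(D),
              nb, nb)
  E <- 0.5 * sum(D * (2 * H + J - 0.5 * K))
  Enuc <- 0
  nc <- length(Z)
  if (nc > 1) for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
    Enuc <- Enuc + Z[i] * Z[j] / sqrt(sum((centers[[i]] - centers[[j]])^2))
  }
  E + Enuc
}

## ---- finite-field complex SCF: independent check of the analytic
##      coupled-perturbed solution for an imaginary perturbation -i*W.
oracle_finite_field_density <- function(state, W, lambda = 1e-5,
                                        tol = 1e-12) {
  scf <- state$scf
  S <- scf$S; H <- scf$H; G <- scf$eri
  n <- ncol(S); nocc <- scf$n_occ
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  Hp <- H + lambda * (-1i) * W
  D <- scf$D + 0i
  nJ <- matrix(G, n * n, n * n)
  nK <- matrix(aperm(G, c(1, 3, 2, 4)), n * n, n * n)
  for (it in 1:500) {
    Jm <- matrix(nJ %*% as.vector(t(Conj(D))), n, n)
    Km <- matrix(nK %*% as.vector(t(Conj(D))), n, n)
    Fm <- Hp + Jm - 0.5 * Km
    Fp <- Conj(t(X)) %*% Fm %*% X
    ev <- eigen((Fp + Conj(t(Fp))) / 2)
    C <- X %*% ev$vectors[, order(Re(ev$values)), drop = FALSE]
    Co <- C[, 1:nocc, drop = FALSE]
    Dn <- 2 * Co %*% Conj(t(Co))
    if (max(Mod(Dn - D)) < tol) { D <- Dn; break }
    D <- Dn
  }
  Im(D) / lambda    # approximates the antisymmetric response matrix P
}

## ---- shared cached fixtures (built once per test run) ----------------
.cache <- new.env()

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

state_h2o <- function() cached("state_h2o", function() {
  build_response_state(make_fixture("H2O"))
})

state_he <- function() cached("state_he", function() {
  build_response_state(make_fixture("He"))
})

state_h2 <- function() cached("state_h2", function() {
  build_response_state(make_fixture("H2"))
})

## even-tempered He basis with enough p completeness for a meaningful
## ipsocentric (DZ1) limit
he_et_basis <- function() {
  list(He = even_tempered_shells(n_s = 8, alpha0_s = 0.15, ratio_s = 3,
                                 n_p = 6, alpha0_p = 0.15, ratio_p = 3))
}

state_he_et <- function() cached("state_he_et", function() {
  build_response_state(make_fixture("He"), basis = he_et_basis())
})

grid_h2o <- function() cached("grid_h2o", function() {
  molecular_grid(make_fixture("H2O"))
})

grid_he <- function() cached("grid_he", function() {
  molecular_grid(make_fixture("He"), radial_n = 80, n_theta = 16, n_phi = 32)
})

state_ch4 <- function() cached("state_ch4", function() {
  build_response_state(make_fixture("CH4"))
})

grid_ch4 <- function() cached("grid_ch4", function() {
  molecular_grid(make_fixture("CH4"))
})

## memoized uniform-parameter shieldings (all nuclei) on the default grids
fixture_sigma <- function(which, scheme, p) {
  key <- paste0("sig_", which, "_", scheme, "_", format(p, digits = 12))
  cached(key, function() {
    st <- switch(which, h2o = state_h2o(), he_et = state_he_et(),
                 ch4 = state_ch4())
    grid <- switch(which, h2o = grid_h2o(), he_et = grid_he(),
                   ch4 = grid_ch4())
    par <- switch(scheme,
                  GRRO = scheme_parameter("GRRO", alpha = p),
                  GPRO = scheme_parameter("GPRO", beta = p),
                  scheme_parameter(scheme))
    integrate_shielding_all_nuclei(st, par, grid)$sigma_av
  })
}

ch4_grro_slopes <- function() cached("ch4_grro_slopes", function() {
  (fixture_sigma("ch4", "GRRO", -0.01) - fixture_sigma("ch4", "GRRO", 0)) /
    (-0.01)
})
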
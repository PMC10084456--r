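## McMurchie-Davidson molecular integrals over contracted Cartesian s/p
## Gaussian shells, vectorized over primitive pairs/quartets.
##
## Conventions: unnormalized primitive g = (x-Ax)^i (y-Ay)^j (z-Az)^k
## exp(-a|r-A|^2); working contraction coefficients (basis.R) absorb all
## normalization.  The Boys function is evaluated through the regularized
## incomplete gamma, F_m(T) = Gamma(m+1/2) P(m+1/2, T) / (2 T^(m+1/2)).

boys_f <- function(m, T) {
  T <- pmax(T, 0)
  out <- numeric(length(T))
  tiny <- T < 1e-13
  if (any(tiny)) out[tiny] <- 1 / (2 * m + 1) - T[tiny] / (2 * m + 3)
  if (any(!tiny)) {
    Tt <- T[!tiny]
    s <- m + 0.5
    out[!tiny] <- gamma(s) * stats::pgamma(Tt, s) / (2 * Tt^s)
  }
  out
}

## Hermite expansion coefficient E_t^{ij} for one Cartesian direction,
## vectorized over primitive pairs.  Qx = Ax - Bx (scalar), a, b vectors.
e_coef <- function(i, j, t, Qx, a, b) {
  p <- a + b
  q <- a * b / p
  if (t < 0 || t > i + j) return(numeric(length(a)))
  if (i == 0 && j == 0 && t == 0) return(exp(-q * Qx * Qx))
  if (j == 0) {
    ## decrement i
    e_coef(i - 1, j, t - 1, Qx, a, b) / (2 * p) -
      (q * Qx / a) * e_coef(i - 1, j, t, Qx, a, b) +
      (t + 1) * e_coef(i - 1, j, t + 1, Qx, a, b)
  } else {
    ## decrement j
    e_coef(i, j - 1, t - 1, Qx, a, b) / (2 * p) +
      (q * Qx / b) * e_coef(i, j - 1, t, Qx, a, b) +
      (t + 1) * e_coef(i, j - 1, t + 1, Qx, a, b)
  }
}

## Hermite Coulomb integrals R_{tuv}(p, PC) for all t+u+v <= L,
## vectorized over rows of PC (and the vector p).  Returns an array of
## dimension (nq, L+1, L+1, L+1).
hermite_coulomb <- function(L, p, PC) {
  nq <- length(p)
  T <- p * rowSums(PC * PC)
  Fm <- vapply(0:L, function(m) boys_f(m, T), numeric(nq))
  Fm <- matrix(Fm, nrow = nq)
  nxt <- NULL
  dims <- c(nq, L + 1, L + 1, L + 1)
  get3 <- function(arr, t, u, v) {
    if (t < 0 || u < 0 || v < 0) return(numeric(nq))
    arr[, t + 1, u + 1, v + 1]
  }
  for (m in L:0) {
    cur <- array(0, dims)
    cur[, 1, 1, 1] <- (-2 * p)^m * Fm[, m + 1]
    if (m < L) {
      for (tot in 1:(L - m)) {
        for (t in 0:tot) for (u in 0:(tot - t)) {
          v <- tot - t - u
          val <- if (t > 0) {
            (t - 1) * get3(nxt, t - 2, u, v) + PC[, 1] * get3(nxt, t - 1, u, v)
          } else if (u > 0) {
            (u - 1) * get3(nxt, t, u - 2, v) + PC[, 2] * get3(nxt, t, u - 1, v)
          } else {
            (v - 1) * get3(nxt, t, u, v - 2) + PC[, 3] * get3(nxt, t, u, v - 1)
          }
          cur[, t + 1, u + 1, v + 1] <- val
        }
      }
    }
    nxt <- cur
  }
  nxt
}

## component exponent table: for l=0 one component (0,0,0); for l=1 the
## three Cartesian p components
.shell_comps <- function(l) {
  if (l == 0L) matrix(0L, 1, 3) else diag(3L)
}

## Precompute shell-pair primitive data
.shell_pair <- function(sa, sb) {
  na <- length(sa$exps); nb <- length(sb$exps)
  av <- rep(sa$exps, times = nb)
  bv <- rep(sb$exps, each = na)
  cc <- rep(sa$coefs, times = nb) * rep(sb$coefs, each = na)
  p <- av + bv
  AB <- sa$center - sb$center
  P <- (outer(av, sa$center) + outer(bv, sb$center)) / p
  list(sa = sa, sb = sb, av = av, bv = bv, cc = cc, p = p, AB = AB, P = P)
}

## 1D overlap integral <i|j> for direction d of a shell pair (vector over
## primitive pairs); negative indices give 0
.s1 <- function(sp, i, j, d) {
  if (i < 0 || j < 0) return(numeric(length(sp$av)))
  e_coef(i, j, 0, sp$AB[d], sp$av, sp$bv) * sqrt(pi / sp$p)
}

## Generic one-electron assembly: fun1d(sp, i, j, d) must return the
## integral factor for direction d; the product over the three directions,
## contracted over primitives, is placed in the AO matrix.
.one_electron_matrix <- function(basis, fun1d) {
  n <- basis$n_ao
  M <- matrix(0, n, n)
  shells <- basis$shells
  for (isa in seq_along(shells)) for (isb in seq_along(shells)) {
    sa <- shells[[isa]]; sb <- shells[[isb]]
    sp <- .shell_pair(sa, sb)
    ca <- .shell_comps(sa$l); cb <- .shell_comps(sb$l)
    for (ia in seq_len(nrow(ca))) for (ib in seq_len(nrow(cb))) {
      val <- sp$cc
      for (d in 1:3) val <- val * fun1d(sp, ca[ia, d], cb[ib, d], d)
      M[sa$ao_offset + ia, sb$ao_offset + ib] <- sum(val)
    }
  }
  M
}

overlap_matrix <- function(basis) {
  .one_electron_matrix(basis, function(sp, i, j, d) .s1(sp, i, j, d))
}

kinetic_matrix <- function(basis) {
  n <- basis$n_ao
  M <- matrix(0, n, n)
  shells <- basis$shells
  for (isa in seq_along(shells)) for (isb in seq_along(shells)) {
    sa <- shells[[isa]]; sb <- shells[[isb]]
    sp <- .shell_pair(sa, sb)
    ca <- .shell_comps(sa$l); cb <- .shell_comps(sb$l)
    s1 <- function(i, j, d) .s1(sp, i, j, d)
    k1 <- function(i, j, d) {
      -0.5 * (j * (j - 1) * s1(i, j - 2, d) -
                2 * sp$bv * (2 * j + 1) * s1(i, j, d) +
                4 * sp$bv^2 * s1(i, j + 2, d))
    }
    for (ia in seq_len(nrow(ca))) for (ib in seq_len(nrow(cb))) {
      iv <- ca[ia, ]; jv <- cb[ib, ]
      tot <- 0
      for (d in 1:3) {
        term <- k1(iv[d], jv[d], d)
        for (dd in setdiff(1:3, d)) term <- term * s1(iv[dd], jv[dd], dd)
        tot <- tot + term
      }
      M[sa$ao_offset + ia, sb$ao_offset + ib] <- sum(sp$cc * tot)
    }
  }
  M
}

## Hermite expansion coefficients E_{tuv} for all components of a shell
## pair: list with E = array (np, ncompA*ncompB, (L+1)^3) and L
.pair_hermite <- function(sp) {
  sa <- sp$sa; sb <- sp$sb
  L <- sa$l + sb$l
  ca <- .shell_comps(sa$l); cb <- .shell_comps(sb$l)
  np <- length(sp$av)
  nherm <- (L + 1)^3
  ncomp <- nrow(ca) * nrow(cb)
  E <- array(0, c(np, ncomp, nherm))
  Ed <- vector("list", 3)   # per-direction coefficient stacks
  for (ia in seq_len(nrow(ca))) for (ib in seq_len(nrow(cb))) {
    ic <- (ia - 1) * nrow(cb) + ib
    Ex <- lapply(1:3, function(d) {
      matrix(vapply(0:L, function(t) e_coef(ca[ia, d], cb[ib, d], t,
                                            sp$AB[d], sp$av, sp$bv),
                    numeric(np)), nrow = np)
    })
    for (t in 0:L) for (u in 0:L) for (v in 0:L) {
      if (t + u + v > L) next
      h <- t + u * (L + 1) + v * (L + 1)^2 + 1
      E[, ic, h] <- sp$cc * Ex[[1]][, t + 1] * Ex[[2]][, u + 1] *
        Ex[[3]][, v + 1]
    }
  }
  list(E = E, L = L, np = np, ncomp = ncomp)
}

nuclear_attraction_matrix <- function(basis, mol = basis$molecule) {
  n <- basis$n_ao
  M <- matrix(0, n, n)
  shells <- basis$shells
  for (isa in seq_along(shells)) for (isb in seq_along(shells)) {
    sa <- shells[[isa]]; sb <- shells[[isb]]
    sp <- .shell_pair(sa, sb)
    ph <- .pair_hermite(sp)
    L <- ph$L
    acc <- matrix(0, ph$np, ph$ncomp)
    for (ic in seq_len(n_atoms(mol))) {
      PC <- sp$P - matrix(mol$coords[ic, ], ph$np, 3, byrow = TRUE)
      Rb <- hermite_coulomb(L, sp$p, PC)
      Z <- mol$Z[ic]
      for (t in 0:L) for (u in 0:L) for (v in 0:L) {
        if (t + u + v > L) next
        h <- t + u * (L + 1) + v * (L + 1)^2 + 1
        acc <- acc - Z * ph$E[, , h, drop = FALSE][, , 1] *
          Rb[, t + 1, u + 1, v + 1]
      }
    }
    vals <- colSums(acc * (2 * pi / sp$p))
    for (ic2 in seq_len(ph$ncomp)) {
      ia <- (ic2 - 1) %/% (if (sb$l == 0L) 1 else 3) + 1
      ib <- (ic2 - 1) %% (if (sb$l == 0L) 1 else 3) + 1
      M[sa$ao_offset + ia, sb$ao_offset + ib] <- vals[ic2]
    }
  }
  M
}

## Derivative matrix D^d_{mu nu} = <mu | d/dx_d | nu> (real antisymmetric)
derivative_matrices <- function(basis) {
  lapply(1:3, function(dd) {
    .one_electron_matrix(basis, function(sp, i, j, d) {
      if (d == dd) {
        j * .s1(sp, i, j - 1, d) - 2 * sp$bv * .s1(sp, i, j + 1, d)
      } else .s1(sp, i, j, d)
    })
  })
}

## Angular-momentum matrices about origin r0:
## L^beta_{mu nu} = <mu | ((r - r0) x grad)_beta | nu>  (real antisymmetric;
## the physical operator is -i times this)
angmom_matrices <- function(basis, r0) {
  ## mixed moment x derivative: <mu | (r_u - r0_u) d_v | nu>, u != v
  mixed <- function(u, v) {
    .one_electron_matrix(basis, function(sp, i, j, d) {
      if (d == u) {
        .s1(sp, i, j + 1, d) + (sp$sb$center[d] - r0[d]) * .s1(sp, i, j, d)
      } else if (d == v) {
        j * .s1(sp, i, j - 1, d) - 2 * sp$bv * .s1(sp, i, j + 1, d)
      } else .s1(sp, i, j, d)
    })
  }
  list(mixed(2, 3) - mixed(3, 2),   # L_x = y dz - z dy
       mixed(3, 1) - mixed(1, 3),   # L_y
       mixed(1, 2) - mixed(2, 1))   # L_z
}

## Full ERI tensor (mu nu | la si) in chemists' notation, n^4 array.
eri_tensor <- function(basis) {
  shells <- basis$shells
  n <- basis$n_ao
  ns <- length(shells)
  G <- array(0, c(n, n, n, n))
  ## precompute pair data + Hermite coefficients for ordered pairs
  pairs <- list()
  pidx <- matrix(0L, ns, ns)
  k <- 0L
  for (i in seq_len(ns)) for (j in i:ns) {
    k <- k + 1L
    sp <- .shell_pair(shells[[i]], shells[[j]])
    ph <- .pair_hermite(sp)
    pairs[[k]] <- list(i = i, j = j, sp = sp, ph = ph)
    pidx[i, j] <- k
  }
  np_tot <- k
  sign_cache <- new.env()
  for (kb in seq_len(np_tot)) for (kk in kb:np_tot) {
    br <- pairs[[kb]]; ke <- pairs[[kk]]
    Lb <- br$ph$L; Lk <- ke$ph$L; Lt <- Lb + Lk
    nb <- br$ph$np; nk <- ke$ph$np
    ## index map (hermite_bra, hermite_ket) -> box index, with ket parity
    key <- paste0(Lb, "_", Lk)
    if (is.null(sign_cache[[key]])) {
      hb <- (Lb + 1)^3; hk <- (Lk + 1)^3
      map <- matrix(1L, hb, hk); sgn <- matrix(0, hb, hk)  # sign 0 masks unused cells
      for (t1 in 0:Lb) for (u1 in 0:Lb) for (v1 in 0:Lb) {
        if (t1 + u1 + v1 > Lb) next
        h1 <- t1 + u1 * (Lb + 1) + v1 * (Lb + 1)^2 + 1
        for (t2 in 0:Lk) for (u2 in 0:Lk) for (v2 in 0:Lk) {
          if (t2 + u2 + v2 > Lk) next
          h2 <- t2 + u2 * (Lk + 1) + v2 * (Lk + 1)^2 + 1
          map[h1, h2] <- (t1 + t2) + (u1 + u2) * (Lt + 1) +
            (v1 + v2) * (Lt + 1)^2 + 1L
          sgn[h1, h2] <- (-1)^(t2 + u2 + v2)
        }
      }
      sign_cache[[key]] <- list(map = map, sgn = sgn)
    }
    ms <- sign_cache[[key]]
    ## loop over primitive quartets: vectorized Hermite box per ket pair
    res <- matrix(0, br$ph$ncomp, ke$ph$ncomp)
    for (ibp in seq_len(nb)) {
      pb <- br$sp$p[ibp]
      PQ <- matrix(br$sp$P[ibp, ], nk, 3, byrow = TRUE) - ke$sp$P
      omega <- pb * ke$sp$p / (pb + ke$sp$p)
      ## R box vectorized over ket primitives
      Rb <- hermite_coulomb(Lt, omega, PQ * sqrt(1))  # arg: alpha, PQ
      pref <- 2 * pi^2.5 / (pb * ke$sp$p * sqrt(pb + ke$sp$p))
      Eb <- matrix(br$ph$E[ibp, , ], nrow = br$ph$ncomp)  # ncompb x hb
      for (ikp in seq_len(nk)) {
        Rflat <- as.vector(Rb[ikp, , , ])
        Rmat <- matrix(Rflat[ms$map], nrow = nrow(ms$map)) * ms$sgn
        Ek <- matrix(ke$ph$E[ikp, , ], nrow = ke$ph$ncomp)  # ncompk x hk
        res <- res + pref[ikp] * (Eb %*% Rmat %*% t(Ek))
      }
    }
    ## scatter with full 8-fold symmetry
    ai <- shells[[br$i]]$ao_offset + seq_len(if (shells[[br$i]]$l == 0L) 1 else 3)
    aj <- shells[[br$j]]$ao_offset + seq_len(if (shells[[br$j]]$l == 0L) 1 else 3)
    ak <- shells[[ke$i]]$ao_offset + seq_len(if (shells[[ke$i]]$l == 0L) 1 else 3)
    al <- shells[[ke$j]]$ao_offset + seq_len(if (shells[[ke$j]]$l == 0L) 1 else 3)
    nj <- length(aj); nl <- length(al)
    for (ia in seq_along(ai)) for (ja in seq_along(aj)) {
      rowc <- (ia - 1) * nj + ja
      for (ka in seq_along(ak)) for (la in seq_along(al)) {
        colc <- (ka - 1) * nl + la
        v <- res[rowc, colc]
        G[ai[ia], aj[ja], ak[ka], al[la]] <- v
        G[aj[ja], ai[ia], ak[ka], al[la]] <- v
        G[ai[ia], aj[ja], al[la], ak[ka]] <- v
        G[aj[ja], ai[ia], al[la], ak[ka]] <- v
        G[ak[ka], al[la], ai[ia], aj[ja]] <- v
        G[al[la], ak[ka], ai[ia], aj[ja]] <- v
        G[ak[ka], al[la], aj[ja], ai[ia]] <- v
        G[al[la], ak[ka], aj[ja], ai[ia]] <- v
      }
    }
  }
  G
}

## AO values and gradients on arbitrary points: list(val, dx, dy, dz),
## each N x n_ao
ao_eval <- function(basis, pts) {
  pts <- matrix(pts, ncol = 3)
  N <- nrow(pts)
  n <- basis$n_ao
  val <- matrix(0, N, n); dx <- matrix(0, N, n)
  dy <- matrix(0, N, n); dz <- matrix(0, N, n)
  for (sh in basis$shells) {
    rel <- pts - matrix(sh$center, N, 3, byrow = TRUE)
    r2 <- rowSums(rel * rel)
    g <- numeric(N); gp <- numeric(N)
    for (kp in seq_along(sh$exps)) {
      e <- sh$coefs[kp] * exp(-sh$exps[kp] * r2)
      g <- g + e
      gp <- gp - sh$exps[kp] * e
    }
    if (sh$l == 0L) {
      j <- sh$ao_offset + 1L
      val[, j] <- g
      dx[, j] <- 2 * rel[, 1] * gp
      dy[, j] <- 2 * rel[, 2] * gp
      dz[, j] <- 2 * rel[, 3] * gp
    } else {
      for (u in 1:3) {
        j <- sh$ao_offset + u
        val[, j] <- rel[, u] * g
        dx[, j] <- (u == 1) * g + rel[, u] * 2 * rel[, 1] * gp
        dy[, j] <- (u == 2) * g + rel[, u] * 2 * rel[, 2] * gp
        dz[, j] <- (u == 3) * g + rel[, u] * 2 * rel[, 3] * gp
      }
    }
  }
  list(val = val, dx = dx, dy = dy, dz = dz)
}
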
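test_that("the Biot-Savart pipeline reproduces the Lamb formula for model atoms", {
  ## hydrogenic 1s, Z = 1: sigma = 1e6/(3 c^2) = 17.750 ppm
  st <- make_analytic_state("hydrogenic", 1)
  grid <- molecular_grid(st$molecule, radial_n = 70, n_theta = 16,
                         n_phi = 32)
  res <- integrate_shielding_all_nuclei(st, scheme_parameter("CO"), grid)
  expect_equal(res$sigma_av, 17.750, tolerance = 0.05 / 17.75)
  expect_equal(res$sigma_av, lamb_shielding(1), tolerance = 1e-6)
  ## gaussian orbital: <1/r> = 2 sqrt(2a/pi)
  stg <- make_analytic_state("gaussian", 0.8)
  gg <- molecular_grid(stg$molecule, radial_n = 70, n_theta = 16, n_phi = 32)
  expect_equal(grid_integrate(gg, function(p) stg$density_fun(p)$rho), 1,
               tolerance = 1e-8)
  resg <- integrate_shielding_all_nuclei(stg, scheme_parameter("CO"), gg)
  expect_equal(resg$sigma_av, lamb_shielding(2 * sqrt(2 * 0.8 / pi)),
               tolerance = 1e-6)
  ## the shielding tensor of a spherical state is isotropic
  expect_equal(resg$tensors[1, , ], diag(resg$sigma_av, 3),
               tolerance = 1e-6)
})

test_that("helium SCF state satisfies the internal Lamb identity", {
  st <- state_he()
  grid <- grid_he()
  res <- integrate_shielding_all_nuclei(st, scheme_parameter("CO"), grid)
  inv_r <- grid_integrate(grid, function(p) {
    d <- evaluate_density(st, p)
    d$rho / pmax(sqrt(rowSums(p^2)), 1e-12)
  })
  expect_equal(res$sigma_av, lamb_shielding(inv_r), tolerance = 0.1 / 60)
})

test_that("shielding density has the correct null, sign and decay behaviour", {
  st <- make_analytic_state("gaussian", 1)
  set.seed(53)
  pts <- matrix(rnorm(60, sd = 1.5), ncol = 3)
  fld <- co_current(st, pts)
  ## zero tensor gives zero density
  zfld <- fld; zfld$tensor[] <- 0
  expect_true(all(shielding_density(zfld, c(0, 0, 0)) == 0))
  ## long-range decay: |Sigma| ~ |J| / |r - R_N|^2 (log-log slope -2 after
  ## factoring the current magnitude)
  rs <- c(2, 4, 8)
  vals <- vapply(rs, function(r) {
    p <- matrix(c(r, 0, 0), 1)
    f <- co_current(st, p)
    jmag <- max(abs(f$tensor))
    abs(shielding_density(f, c(0, 0, 0))) / jmag
  }, 0)
  slopes <- diff(log(vals)) / diff(log(rs))
  expect_equal(slopes, c(-2, -2), tolerance = 1e-6)
  ## a grid point sitting on the nucleus is excluded with a message
  p0 <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  f0 <- co_current(st, p0)
  expect_message(sd0 <- shielding_density(f0, c(0, 0, 0)), "excluded")
  expect_identical(sd0[1], 0)
})

test_that("isotropic shieldings vary exactly linearly in alpha and beta", {
  st <- state_h2o()
  grid <- grid_h2o()
  for (scheme in c("GRRO", "GPRO")) {
    ps <- if (scheme == "GRRO") c(0, -0.005, -0.01) else c(0, -0.025, -0.05)
    par <- function(p) if (scheme == "GRRO") {
      scheme_parameter("GRRO", alpha = p)
    } else scheme_parameter("GPRO", beta = p)
    sig <- vapply(ps, function(p) {
      integrate_shielding_all_nuclei(st, par(p), grid)$sigma_av
    }, numeric(3))
    expect_lt(max(abs(sig[, 2] - (sig[, 1] + sig[, 3]) / 2)), 1e-8)
  }
})

test_that("helium GRRO sweep: the midpoint shielding is the mean of the ends", {
  st <- state_he_et()
  grid <- grid_he()
  sig <- vapply(c(0, -0.005, -0.01), function(a) {
    integrate_shielding_all_nuclei(st, scheme_parameter("GRRO", alpha = a),
                                   grid)$sigma_av
  }, 0)
  expect_lt(abs(sig[2] - (sig[1] + sig[3]) / 2), 1e-8)
  ## and with a p-complete basis the GRRO total at small alpha stays close
  ## to the exact-by-symmetry common-origin value
  co <- integrate_shielding_all_nuclei(st, scheme_parameter("CO"), grid)
  expect_lt(abs(sig[2] - co$sigma_av), 0.5)
})

test_that("single-centre decomposition is exact for equal parameters", {
  st <- state_h2o()
  grid <- grid_h2o()
  a <- -0.0123
  uni <- integrate_shielding_all_nuclei(st, scheme_parameter("GRRO", alpha = a),
                                        grid)
  per <- integrate_shielding_all_nuclei(
    st, param_spec("GRRO", per_atom = rep(a, 3)), grid)
  expect_lt(max(abs(uni$sigma_av - per$sigma_av)), 1e-10)
  expect_lt(max(abs(uni$tensors - per$tensors)), 1e-10)
})

test_that("per-atom parameter switching has bounded cross-talk", {
  st <- state_h2()
  grid <- cached("grid_h2", function() molecular_grid(make_fixture("H2")))
  pa <- -0.3; pb <- -0.05
  mix <- integrate_shielding_all_nuclei(
    st, param_spec("GRRO", per_atom = c(pa, pb)), grid)
  ua <- integrate_shielding_all_nuclei(st, scheme_parameter("GRRO", alpha = pa),
                                       grid)
  ub <- integrate_shielding_all_nuclei(st, scheme_parameter("GRRO", alpha = pb),
                                       grid)
  ## nucleus 1 follows its own parameter up to the foreign-cell term,
  ## which is strictly smaller than the full parameter sensitivity
  drift <- abs(mix$sigma_av[1] - ua$sigma_av[1])
  span <- abs(ua$sigma_av[1] - ub$sigma_av[1])
  expect_lt(drift, span)
  expect_gt(span, 0)
})

test_that("shieldings are converged with respect to the default grid", {
  st <- state_he_et()
  g1 <- grid_he()
  g2 <- molecular_grid(make_fixture("He"), radial_n = 120, n_theta = 24,
                       n_phi = 48)
  p <- scheme_parameter("GRRO", alpha = -0.01)
  s1 <- integrate_shielding_all_nuclei(st, p, g1)$sigma_av
  s2 <- integrate_shielding_all_nuclei(st, p, g2)$sigma_av
  expect_lt(abs(s1 - s2), 0.05)
})

test_that("missing parameters are reported with atom and key", {
  st <- state_h2o()
  expect_error(
    integrate_shielding_all_nuclei(
      st, param_spec("GRRO", element = c(O = -0.004)), grid_h2o()),
    "atom 2 \\(H, key H\\[O\\]")
  expect_warning(
    .res <- integrate_shielding_all_nuclei(
      st, param_spec("GRRO", element = c(O = 0.01, H = -0.1)), grid_h2o()),
    "lower than zero")
})
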
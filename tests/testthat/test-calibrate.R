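test_that("the two-point fit solves the linear calibration exactly", {
  ## target equal to the first probe: zero correction
  f <- two_point_fit(-0.01, 25.0, -0.02, 30.0, 25.0)
  expect_equal(f$parameter, -0.01)
  ## synthetic line sigma(p) = a + b p: exact root recovery
  a <- 12.3; b <- -470
  set.seed(59)
  for (i in 1:10) {
    p <- sort(stats::runif(2, -0.5, 0))
    target <- a + b * stats::runif(1, -0.3, 0)
    f <- two_point_fit(p[1], a + b * p[1], p[2], a + b * p[2], target)
    expect_equal(f$parameter, (target - a) / b, tolerance = 1e-12)
    expect_equal(f$slope, b, tolerance = 1e-9)
    expect_equal(f$intercept, a, tolerance = 1e-9)
  }
  expect_error(two_point_fit(0, 1, 0, 2, 1.5), "must differ")
  expect_error(two_point_fit(0, 1, -0.01, 1, 1.5), "degenerate slope")
})

test_that("a planted alpha* is recovered through the full pipeline", {
  st <- state_he_et()
  grid <- grid_he()
  a_star <- -0.1234
  target <- integrate_shielding_all_nuclei(
    st, scheme_parameter("GRRO", alpha = a_star), grid)$sigma_av
  cal <- calibrate_molecule(st, stats::setNames(target, 1), scheme = "GRRO",
                            grid = grid)
  expect_equal(cal$parameter, a_star, tolerance = 1e-8)
  expect_lt(abs(cal$residual), 1e-8)
  ## re-integrating at the fitted parameter reproduces the target
  back <- integrate_shielding_all_nuclei(
    st, scheme_parameter("GRRO", alpha = cal$parameter), grid)$sigma_av
  expect_lt(abs(back - target), 0.01)
  ## probe-pair invariance (a direct consequence of linearity)
  cal2 <- calibrate_molecule(st, stats::setNames(target, 1), scheme = "GRRO",
                             probes = c(-0.003, -0.4), grid = grid)
  expect_equal(cal2$parameter, cal$parameter, tolerance = 1e-8)
})

test_that("planted parameters are recovered for every nucleus of a molecule", {
  st <- state_h2o()
  grid <- grid_h2o()
  for (scheme in c("GRRO", "GPRO")) {
    p_star <- if (scheme == "GRRO") -0.0371 else -0.21
    par <- if (scheme == "GRRO") {
      scheme_parameter("GRRO", alpha = p_star)
    } else scheme_parameter("GPRO", beta = p_star)
    target <- integrate_shielding_all_nuclei(st, par, grid)$sigma_av
    cal <- calibrate_molecule(st, stats::setNames(target, 1:3),
                              scheme = scheme, grid = grid)
    expect_equal(cal$parameter, rep(p_star, 3), tolerance = 1e-8)
    ## symmetry: the two hydrogens calibrate to identical parameters even
    ## against independent (symmetry-equivalent) references
    expect_lt(abs(cal$parameter[2] - cal$parameter[3]), 1e-6)
  }
})

test_that("slopes are orders of magnitude stiffer for heavy nuclei than for protons", {
  slope <- ch4_grro_slopes()
  sC <- slope[1]; sH <- slope[2]
  expect_lt(sC, 0)                      # shielding grows as alpha decreases
  expect_gt(abs(sC) / abs(sH), 50)      # element hierarchy
  expect_gt(abs(sC), 1e3); expect_lt(abs(sC), 1e6)
  expect_gt(abs(sH), 1); expect_lt(abs(sH), 1e3)
})

test_that("aggregation reproduces hand-computed statistics", {
  rec <- data.frame(nucleus = 1:2, element = c("H", "H"),
                    key = c("H[O][H]", "H[O][H]"), scheme = "GRRO",
                    slope = c(-11, -12), intercept = c(20, 21),
                    parameter = c(-0.3, -0.4), reference = c(25, 26),
                    residual = c(0, 0), flagged = FALSE,
                    stringsAsFactors = FALSE)
  class(rec) <- c("ctocd_calibration", "data.frame")
  tab <- aggregate_parameters(rec, "element")
  expect_equal(tab$mean, -0.35)
  expect_equal(tab$sd, 0.0707, tolerance = 1e-3)   # sample (n-1) deviation
  expect_equal(tab$n, 2L)
  tab1 <- aggregate_parameters(rec[1, ], "element")
  expect_equal(tab1$sd, 0)
  expect_equal(tab1$n, 1L)
})

test_that("environment grouping never exceeds element-level within-group variance", {
  ## law of total variance, checked against a brute-force decomposition
  set.seed(61)
  n <- 40
  key <- sample(c("C[C,H,H,H]", "C[C,O,O]", "C[C,C,H,N]"), n, replace = TRUE)
  par <- -0.005 + as.numeric(factor(key)) * 0.001 + stats::rnorm(n, 0, 2e-4)
  rec <- data.frame(nucleus = 1:n, element = "C", key = key,
                    scheme = "GRRO", slope = -2e4, intercept = 0,
                    parameter = par, reference = 0, residual = 0,
                    flagged = FALSE, stringsAsFactors = FALSE)
  class(rec) <- c("ctocd_calibration", "data.frame")
  tab_el <- aggregate_parameters(rec, "element")
  tab_ce <- aggregate_parameters(rec, "environment")
  ## brute-force variance decomposition: within-group sum of squares can
  ## never exceed the total sum of squares
  ss_tot <- sum((par - mean(par))^2)
  ss_within <- sum(vapply(split(par, key), function(v) {
    sum((v - mean(v))^2)
  }, 0))
  expect_lte(ss_within, ss_tot + 1e-15)
  ## the same statement through the aggregated tables
  expect_lte(sum((tab_ce$n - 1) * tab_ce$sd^2),
             (tab_el$n - 1) * tab_el$sd^2 + 1e-15)
})

test_that("error propagation is |slope| x dispersion", {
  ## worked numbers quoted for protons and carbons: 11 x 0.05 and
  ## 23750 x 0.00016 give 0.6 and 3.8 ppm after rounding
  expect_equal(round(propagate_error(11, 0.05), 1), 0.6)
  expect_equal(round(propagate_error(23750, 0.00016), 1), 3.8)
  expect_equal(propagate_error(-60, 0.011), 0.66)
  expect_identical(propagate_error(123, 0), 0)
})

test_that("parameter tables convert to usable specs and round-trip via JSON", {
  rec <- data.frame(nucleus = 1:3, element = c("O", "H", "H"),
                    key = c("O[H,H]", "H[O][H]", "H[O][H]"),
                    scheme = "GRRO", slope = -100, intercept = 0,
                    parameter = c(-0.004, -0.3, -0.32), reference = 0,
                    residual = 0, flagged = FALSE, stringsAsFactors = FALSE)
  attr(rec, "provenance") <- list(basis = "STO-3G", method = "HF")
  class(rec) <- c("ctocd_calibration", "data.frame")
  tab <- aggregate_parameters(rec, "environment")
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_table(tab, path)
  tab2 <- read_parameter_table(path)
  expect_equal(tab2$mean, tab$mean)
  expect_identical(attr(tab2, "scheme"), "GRRO")
  spec <- param_table_as_spec(tab2)
  expect_s3_class(spec, "ctocd_param_spec")
  expect_equal(unname(spec$environment["H[O][H]"]), -0.31)
})
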
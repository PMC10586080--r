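# Closed-form force expressions and the shared tip-shape parametrization.

test_that("tip radius parametrization is the stated linear form", {
  td <- tip_descriptors(100e-9, 50e-9, 0, 0)
  expect_equal(tip_radius_at(td, gx = 1, gy = 0, d = 0), 150e-9)
  # a=b=c=0: constant radius at any gradient/depth
  td0 <- tip_descriptors(80e-9)
  expect_equal(tip_radius_at(td0, gx = 2, gy = -3, d = c(0, 1e-7, 8e-7)),
               rep(80e-9, 3))
  # depth coupling can drive the radius nonpositive; reported, not clamped
  tdneg <- tip_descriptors(10e-9, 0, 0, -1)
  r <- tip_radius_at(tdneg, 0, 0, 20e-9)
  expect_lt(r, 0)
  expect_false(geometry_ok(r))
})

test_that("force expressions match an independent straight transcription", {
  # values frozen from a transcription script written before the package
  expect_equal(hs_force(sigma = 1e3, E = 1e4, R = 1e-6, d = 1e-7,
                        poisson = 0.5),
               8.3640338347994831e-10, tolerance = 1e-12)
  expect_equal(hertz_force(E = 1e4, R = 1e-6, d = 1e-7, poisson = 0.5),
               5.6218269514104528e-10, tolerance = 1e-12)
  expect_equal(sneddon_force(E = 1e4, theta = pi / 9, d = 1e-7,
                             poisson = 0.5),
               3.089475302494999e-11, tolerance = 1e-12)
  expect_equal(cslc_force(tension = 1e-3, r_cell = 1e-5, R = 1e-6, d = 1e-7),
               1.3823007675795088e-09, tolerance = 1e-12)
})

test_that("limiting behaviour and power laws hold", {
  R <- 1e-7; d <- 2e-7; E <- 5e3
  # all models vanish at zero depth and are continuous on [0, d_max]
  expect_equal(hs_force(2e3, E, R, 0), 0)
  expect_equal(hertz_force(E, R, 0), 0)
  expect_equal(sneddon_force(E, pi / 9, 0), 0)
  expect_equal(cslc_force(1e-3, 1e-5, R, 0), 0)
  dd <- seq(0, 8e-7, by = 1e-9)
  expect_true(all(is.finite(hs_force(-5e3, E, R, dd))))
  # Hertz: linear in E, F(2d)/F(d) = 2^1.5
  expect_equal(hertz_force(2 * E, R, d), 2 * hertz_force(E, R, d))
  expect_equal(hertz_force(E, R, 2 * d) / hertz_force(E, R, d), 2^1.5)
  # Sneddon: quadratic law; angle domain enforced
  expect_equal(sneddon_force(E, pi / 9, 2 * d) / sneddon_force(E, pi / 9, d),
               4)
  expect_error(sneddon_force(E, pi / 2, d), "half-angle")
  # CSLC: linear in depth; R -> Inf limit dominated by R/r_cell term
  expect_equal(cslc_force(1e-3, 1e-5, R, 2 * d),
               2 * cslc_force(1e-3, 1e-5, R, d))
  Rbig <- 1
  expect_equal(cslc_force(1e-3, 1e-5, Rbig, d),
               4 * pi * 1e-3 * d * Rbig / 1e-5, tolerance = 1e-4)
  # prestress-only HS term is positive and monotone in d for sigma > 0
  fs <- hs_force(1e3, 0, R, dd)
  expect_true(all(diff(fs) > 0))
  expect_true(all(fs[-1] > 0))
})

test_that("HS nests Hertz at sigma = 0 to machine precision", {
  set.seed(42)
  for (i in 1:20) {
    R <- runif(1, 2e-8, 2e-6); d <- runif(1, 0, 8e-7)
    E <- runif(1, 5e2, 5e4); g <- runif(1, 0, 0.49)
    expect_identical(hs_force(0, E, R, d, g), hertz_force(E, R, d, g))
  }
})

test_that("angle factor equals cos(atan(sqrt(2R/d))) over a wide range", {
  x <- 10^seq(-6, 6, length.out = 200)  # x = sqrt(2R/d)
  expect_equal(1 / sqrt(1 + x^2), cos(atan(x)), tolerance = 1e-15)
  R <- 1e-7
  d <- 2 * R / x^2
  expect_equal(hs_angle_factor(d, R), cos(atan(sqrt(2 * R / d))),
               tolerance = 1e-12)
})

test_that("compressive prestress gives negative shallow force with a zero
           crossing matching an independent root-finder", {
  set.seed(7)
  for (i in 1:25) {
    sigma <- -runif(1, 1e3, 3e4)
    E <- runif(1, 2e3, 3e4)
    R <- runif(1, 3e-8, 5e-7)
    dstar <- hs_zero_crossing(sigma, E, R, d_max = 5e-6)
    if (is.na(dstar)) next
    # shallow range is negative, beyond the crossing positive
    expect_lt(hs_force(sigma, E, R, dstar * 0.5), 0)
    expect_gt(hs_force(sigma, E, R, dstar * 2), 0)
    ind <- stats::uniroot(function(d) hs_force(sigma, E, R, d),
                          c(5e-12, 5e-6), tol = 1e-15)$root
    expect_lt(abs(dstar - ind) / ind, 1e-3)
  }
})

test_that("basis columns reproduce the forward models by dot product", {
  td <- tip_descriptors(1e-7, 2e-8, -1e-8, 0.03)
  d <- seq(0, 5e-7, by = 2.5e-8)
  gx <- 0.4; gy <- -0.2
  R <- tip_radius_at(td, gx, gy, d)
  set.seed(3)
  for (i in 1:20) {
    sigma <- rnorm(1, 0, 2e4); E <- runif(1, 1e3, 3e4)
    X <- basis_functions("hs", td, gx, gy, d)
    expect_equal(as.numeric(X %*% c(sigma, E)),
                 hs_force(sigma, E, R, d), tolerance = 1e-12)
  }
  Xh <- basis_functions("hertz", td, gx, gy, d)
  expect_equal(as.numeric(Xh) * 7e3, hertz_force(7e3, R, d),
               tolerance = 1e-12)
  tda <- tip_descriptors(pi / 9, 0.01, 0.02, 1e4, kind = "angle")
  theta <- tip_radius_at(tda, gx, gy, d)
  Xs <- basis_functions("sneddon", tda, gx, gy, d)
  expect_equal(as.numeric(Xs) * 7e3, sneddon_force(7e3, theta, d),
               tolerance = 1e-12)
  Xc <- basis_functions("cslc", td, gx, gy, d, r_cell = 8e-6)
  expect_equal(as.numeric(Xc) * 2e-3,
               cslc_force(2e-3, 8e-6, R, d), tolerance = 1e-12)
  # columns vanish at d = 0; geometry violations are flagged, not hidden
  expect_equal(unname(basis_functions("hs", td, 0, 0, 0)[1, ]), c(0, 0))
  bad <- basis_functions("hs", tip_descriptors(1e-9, 0, 0, -1), 0, 0,
                         c(0, 1e-7))
  expect_false(attr(bad, "geometry_ok"))
})
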
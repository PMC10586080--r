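# Map assembly, depth windows, radial profiles, line-scan statistics.

test_that("build_maps recovers the phantom stress field and copies
           topography exactly", {
  ph <- live_phantom(nx = 16, ny = 16, noise_rms = 3e-11, seed = 31)
  img <- sim_img(ph, seed = 31)
  maps <- build_maps(fit_map(img, "hs", ph$td), img)
  expect_identical(maps$topography$values, img$topography)
  expect_equal(maps$stress$units, "Pa")
  # error stays within the noise-propagated OLS bound per pixel
  grads <- topography_gradients(img)
  bound2 <- matrix(NA_real_, 16, 16)
  for (iy in 1:16) for (ix in 1:16) {
    cv <- curve_at(img, ix, iy)
    X <- basis_functions("hs", ph$td, grads$gx[iy, ix], grads$gy[iy, ix],
                         cv$d)
    bound2[iy, ix] <- (3e-11)^2 * solve(t(X) %*% X)[1, 1]
  }
  err <- maps$stress$values - ph$sigma1
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1.5 * sqrt(mean(bound2)))
  expect_gt(cor(as.vector(maps$stress$values), as.vector(ph$sigma1)), 0.95)
})

test_that("stress and topography are decoupled: permuting the stress field
           changes the stress map but not the topography map", {
  ph1 <- live_phantom(nx = 8, ny = 8, seed = 32)
  ph2 <- ph1
  set.seed(1)
  perm <- sample(length(ph1$sigma1))
  ph2$sigma1 <- matrix(ph1$sigma1[perm], ph1$ny, ph1$nx)
  ph2$sigma2 <- ph2$sigma1
  img1 <- sim_img(ph1, seed = 32)
  img2 <- sim_img(ph2, seed = 32)
  m1 <- build_maps(fit_map(img1, "hs", ph1$td), img1)
  m2 <- build_maps(fit_map(img2, "hs", ph2$td), img2)
  expect_identical(m1$topography$values, m2$topography$values)
  expect_false(isTRUE(all.equal(m1$stress$values, m2$stress$values)))
})

test_that("depth-windowed maps separate the two stress layers", {
  ph <- two_layer_phantom(nx = 12, ny = 12, sigma1 = 4e3, sigma2 = 3e3,
                          interface = 150e-9, noise_rms = 1e-11, seed = 33)
  img <- sim_img(ph, seed = 33)
  dw <- depth_windowed_maps(img, ph$td, "hs", c(100e-9, 800e-9))
  expect_equal(dw[[1]]$label, "cortex")
  expect_equal(dw[[2]]$label, "nucleoskeleton")
  s_shallow <- mean(dw[[1]]$maps$stress$values, na.rm = TRUE)
  s_full <- mean(dw[[2]]$maps$stress$values, na.rm = TRUE)
  expect_lt(abs(s_shallow - 4e3) / 4e3, 0.10)  # cortex recovered
  expect_gt(s_full, 3e3)                       # between the layer stresses,
  expect_lt(s_full, 4e3)                       # closer to the deep one
  expect_lt(abs(s_full - 3e3), abs(s_full - 4e3))
  # single full-depth window equals the plain map fit
  one <- depth_windowed_maps(img, ph$td, "hs", 900e-9)
  plain <- fit_map(img, "hs", ph$td)
  expect_equal(one[[1]]$fit$grids$sigma, plain$grids$sigma)
  expect_error(depth_windowed_maps(img, ph$td, "hs", numeric(0)), "empty")
  # a window below the 4th sample masks every pixel in that window
  tiny <- depth_windowed_maps(img, ph$td, "hs", 2.5e-8)
  expect_true(all(tiny[[1]]$fit$flags$too_shallow))
})

test_that("radial profiles reproduce an analytic radial field and normalize
           to unit maximum", {
  pitch <- 0.5e-6
  n <- 33
  ctr <- c(17, 17)
  vals <- outer(seq_len(n), seq_len(n), function(iy, ix) {
    r <- pitch * sqrt((ix - 17)^2 + (iy - 17)^2)
    1e3 * exp(-(r / 4e-6)^2)
  })
  map <- scalar_map(vals, "Pa", provenance = list(pixel_pitch = pitch))
  rp <- radial_profile(map, ctr, r_max = 7e-6, n_bins = 14)
  got <- rp$profile
  pred <- 1e3 * exp(-(got$r_mid / 4e-6)^2)
  expect_lt(max(abs(got$mean - pred) / pred), 0.08)  # discretization only
  # constant map: flat profile, ones after normalization, any center
  cmap <- scalar_map(matrix(5, 9, 9), "m",
                     provenance = list(pixel_pitch = pitch))
  for (ctr2 in list(c(5, 5), c(2, 7))) {
    rpc <- radial_profile(cmap, ctr2, r_max = 3e-6, n_bins = 6,
                          normalize = TRUE)
    expect_true(all(rpc$profile$mean[rpc$profile$count > 0] == 1))
  }
  # masked region near the center: bins still averaged from unmasked pixels
  msk <- matrix(FALSE, 9, 9); msk[4:6, 4:6] <- TRUE
  mmap <- scalar_map(matrix(2, 9, 9), "Pa", mask = msk,
                     provenance = list(pixel_pitch = pitch))
  rpm <- radial_profile(mmap, c(5, 5), r_max = 3e-6, n_bins = 6)
  expect_true(all(rpm$profile$mean[rpm$profile$count > 0] == 2))
  expect_true(any(rpm$profile$count == 0))  # innermost bins are empty
  expect_error(radial_profile(mmap, c(50, 5), 3e-6), "center")
})

test_that("line-scan statistics recover plateau fractions and reject bad
           windows", {
  # time-constant series: flat outputs
  ser0 <- linescan_series(times = seq(0, 300, 30),
                          stress = matrix(7e3, 11, 40),
                          height = matrix(2e-6, 11, 40), pitch = 0.5e-6)
  st0 <- linescan_stats(ser0)
  expect_equal(diff(range(st0$mean_stress)), 0)
  expect_equal(diff(range(st0$height)), 0)
  # exponential decay to a 50% plateau, as in a compression response
  ls <- make_linescan_series(nx = 64, times = seq(0, 3600, 30),
                             sigma0 = 40e3, plateau_frac = 0.5, tau = 600,
                             noise_rel = 0.005, seed = 2)
  st <- linescan_stats(ls$series)
  pf <- plateau_fraction(st$mean_stress)
  expect_lt(abs(pf - 0.5), 0.05)
  # height trend recovered (75% increase over the run)
  ls2 <- make_linescan_series(nx = 64, height_change = 0.75,
                              noise_rel = 0.002, seed = 3)
  st2 <- linescan_stats(ls2$series)
  expect_equal(st2$height[length(st2$height)] / st2$height[1], 1.75,
               tolerance = 0.03)
  expect_error(linescan_stats(ls$series, window_width = 1), "beyond")
})
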
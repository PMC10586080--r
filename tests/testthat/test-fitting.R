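# Per-curve OLS, vectorized map fits, train/test splitting, prediction error.

test_that("noiseless curve round-trips exactly through fit_curve_linear", {
  td <- tip_descriptors(1e-7, 2e-8, 3e-8, 0.04)
  gx <- 0.3; gy <- -0.5
  d <- seq(0, 6e-7, by = 1e-8)
  R <- tip_radius_at(td, gx, gy, d)
  f <- hs_force(2e3, 8e3, R, d)
  fit <- fit_curve_linear(force_curve(d, f), "hs", td, gx, gy)
  expect_equal(unname(fit$params["sigma"]), 2e3, tolerance = 1e-10)
  expect_equal(unname(fit$params["E"]), 8e3, tolerance = 1e-10)
  expect_lt(fit$residual_rms, 1e-20)
  # all-zero force: zero coefficients, zero residual
  z <- fit_curve_linear(force_curve(d, 0 * d), "hs", td, gx, gy)
  expect_equal(unname(z$params), c(0, 0))
  expect_equal(z$residual_rms, 0)
})

test_that("OLS equals an independent normal-equations oracle", {
  set.seed(11)
  for (i in 1:30) {
    td <- tip_descriptors(runif(1, 5e-8, 3e-7), rnorm(1, 0, 3e-8),
                          rnorm(1, 0, 3e-8), runif(1, -0.05, 0.2))
    gx <- rnorm(1, 0, 0.5); gy <- rnorm(1, 0, 0.5)
    d <- sort(runif(20, 0, 8e-7)); d[1] <- 0
    R <- tip_radius_at(td, gx, gy, d)
    if (any(R <= 0)) next
    f <- hs_force(rnorm(1, 0, 2e4), runif(1, 1e3, 3e4), R, d) +
      rnorm(20, 0, 5e-11)
    fit <- fit_curve_linear(force_curve(d, f), "hs", td, gx, gy)
    X <- basis_functions("hs", td, gx, gy, d)
    beta <- solve(t(X) %*% X, t(X) %*% f)
    expect_equal(unname(fit$params), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("degenerate designs are flagged, not raised", {
  td <- tip_descriptors(1e-7)
  # all depths equal -> singular design
  d <- rep(1e-7, 6); d[1] <- 0
  cv <- force_curve(cummax(d), rep(1e-9, 6))
  fit <- fit_curve_linear(cv, "hs", td, 0, 0)
  expect_true("singular" %in% fit$flags)
  # geometry violation
  fitg <- fit_curve_linear(
    force_curve(seq(0, 5e-7, by = 1e-8), rep(1e-10, 51)), "hs",
    tip_descriptors(1e-8, 0, 0, -1), 0, 0)
  expect_true("geometry_violation" %in% fitg$flags)
  # negative fitted modulus flagged, value retained
  dd <- seq(0, 5e-7, by = 2e-8)
  fneg <- -hertz_force(5e3, 1e-7, dd)
  fitn <- fit_curve_linear(force_curve(dd, fneg), "hertz", td, 0, 0)
  expect_true("negative_E" %in% fitn$flags)
  expect_lt(unname(fitn$params["E"]), 0)
})

test_that("vectorized fit_map agrees with per-curve fits pixel by pixel", {
  ph <- live_phantom(nx = 8, ny = 8, noise_rms = 2e-11, seed = 3)
  img <- sim_img(ph, seed = 3)
  grads <- topography_gradients(img)
  for (model in c("hs", "hertz", "cslc")) {
    td <- if (model == "sneddon") tip_descriptors(pi / 9, kind = "angle")
          else ph$td
    fm <- fit_map(img, model, td)
    for (px in list(c(1, 1), c(5, 3), c(8, 8), c(2, 7))) {
      pc <- fit_curve_linear(curve_at(img, px[1], px[2]), model, td,
                             grads$gx[px[2], px[1]], grads$gy[px[2], px[1]])
      for (p in model_params(model))
        expect_equal(fm$grids[[p]][px[2], px[1]], unname(pc$params[p]),
                     tolerance = 1e-9)
      expect_equal(fm$residual_rms[px[2], px[1]], pc$residual_rms,
                   tolerance = 1e-9)
    }
  }
})

test_that("map objective reaches ~zero at truth, rises when descriptors move,
           and ignores pixel ordering", {
  ph <- live_phantom(nx = 8, ny = 8, seed = 4)
  img <- sim_img(ph, seed = 4)
  f0 <- fit_map(img, "hs", ph$td)
  expect_lt(f0$objective, 1e-40)
  for (fac in c(0.7, 0.9, 1.1, 1.3)) {
    td2 <- ph$td; td2$r <- ph$td$r * fac
    expect_gt(fit_map(img, "hs", td2)$objective, f0$objective)
  }
  # sum objective as the selectable alternative
  expect_lt(fit_map(img, "hs", ph$td, objective = "sum")$objective, 1e-35)
})

test_that("masked pixels are excluded from the objective but kept as NA", {
  ph <- live_phantom(nx = 8, ny = 8, seed = 5)
  img <- sim_img(ph, seed = 5)
  img$curves[10] <- list(NULL)  # drop one pixel, keep the slot
  fit <- fit_map(img, "hs", ph$td)
  expect_true(is.na(fit$grids$sigma[2, 2]))  # pixel 10 = (ix=2, iy=2)
  expect_true(fit$flags$missing[2, 2])
  expect_equal(fit$n_ok, 63)
  expect_true(is.finite(fit$objective))
})

test_that("train/test split is deterministic, disjoint, depth-stratified and
           close to the nominal 1/8", {
  ph <- live_phantom(nx = 8, ny = 8, seed = 6)
  img <- sim_img(ph, seed = 6)
  s1 <- split_train_test(img, seed = 42)
  s2 <- split_train_test(img, seed = 42)
  expect_identical(s1$test, s2$test)
  s3 <- split_train_test(img, seed = 43)
  expect_false(identical(s1$test, s3$test))
  n_tot <- sum(vapply(img$curves, function(cv) length(cv$d), integer(1)))
  n_test <- sum(lengths(s1$test))
  expect_gte(n_test / n_tot, 0.115)
  expect_lte(n_test / n_tot, 0.135)
  # one test point per consecutive depth block of 8; indices valid
  for (i in c(1, 20, 64)) {
    ti <- s1$test[[i]]
    n <- length(img$curves[[i]]$d)
    expect_true(all(ti >= 1 & ti <= n))
    expect_equal(length(ti), n %/% 8)
    expect_true(all(diff(ti) >= 1))
    blocks <- (ti - 1) %/% 8
    expect_equal(blocks, seq_along(ti) - 1)  # exactly one per block
  }
})

test_that("prediction error is ~zero for the generating model, larger for a
           mismatched model, and at the noise floor under iid noise", {
  ph <- live_phantom(nx = 8, ny = 8, seed = 7)
  img <- sim_img(ph, seed = 7)
  split <- split_train_test(img, seed = 7)
  pe_hs <- prediction_error(img, "hs", ph$td, split)
  expect_lt(pe_hs$rms, 1e-15)
  pe_h <- prediction_error(img, "hertz", ph$td, split)
  expect_gt(pe_h$rms, 100 * max(pe_hs$rms, 1e-18))
  # iid noise of known rms: prediction error close to that rms
  noise <- 3e-11
  phn <- live_phantom(nx = 8, ny = 8, noise_rms = noise, seed = 8)
  imgn <- sim_img(phn, seed = 8)
  pen <- prediction_error(imgn, "hs", phn$td, split_train_test(imgn, seed = 8))
  expect_gt(pen$rms, 0.8 * noise)
  expect_lt(pen$rms, 1.25 * noise)
})
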
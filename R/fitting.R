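# Per-curve linear regression of model variates and map-wide aggregation.
#
# Every contact model here is linear in its material variates (sigma, E or
# T) once the tip descriptors are fixed, so per-pixel fitting is ordinary
# least squares on the basis columns of basis_functions(). fit_map() runs a
# vectorized implementation over an NA-padded sample matrix (one column per
# pixel) so that a full-map objective evaluation costs a handful of
# elementwise matrix operations -- this is what makes the MCMC descriptor
# search tractable. fit_curve_linear() is the per-curve reference path.

run_with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(eval.parent(substitute(expr)))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Fit one curve by ordinary least squares
#'
#' Regresses the measured force on the model's basis columns (see
#' [basis_functions()]); no non-negativity constraint is imposed, so a
#' negative fitted modulus sets the `negative_E` flag rather than being
#' clamped. Geometry violations and singular designs are flagged, not
#' raised, so a map fit can mask the pixel and continue.
#'
#' @param curve a [force_curve()].
#' @param model model id (`"hs"`, `"hertz"`, `"sneddon"`, `"cslc"`).
#' @param td a [tip_descriptors()].
#' @param gx,gy topographic gradients at the curve's pixel.
#' @param config a [model_config()] (poisson ratio, cell radius).
#' @param use_idx optional integer vector of sample indices to fit on
#'   (training subset); default all samples.
#' @return An object of class `pixel_fit`: list with `params` (named numeric:
#'   `sigma`/`E` for HS, `E` for Hertz/Sneddon, `T` for CSLC),
#'   `residual_rms` (N), `n_samples`, `flags`.
#' @export
fit_curve_linear <- function(curve, model, td, gx = 0, gy = 0,
                             config = model_config(model), use_idx = NULL) {
  pnames <- model_params(model)
  empty <- function(flags) {
    structure(list(params = stats::setNames(rep(NA_real_, length(pnames)),
                                            pnames),
                   residual_rms = NA_real_, n_samples = 0L, flags = flags),
              class = "pixel_fit")
  }
  if (is.null(curve) || "missing" %in% curve$flags) return(empty("missing"))
  d <- curve$d; f <- curve$f
  if (!is.null(use_idx)) { d <- d[use_idx]; f <- f[use_idx] }
  keep <- is.finite(d) & is.finite(f)
  d <- d[keep]; f <- f[keep]
  if (length(d) < 4L) return(empty("too_shallow"))
  X <- basis_functions(model, td, gx, gy, d, poisson = config$poisson,
                       r_cell = config$r_cell)
  if (!attr(X, "geometry_ok")) return(empty("geometry_violation"))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(empty("singular"))
  beta <- qr.coef(qrx, f)
  resid <- f - X %*% beta
  flags <- character()
  if ("E" %in% pnames && is.finite(beta[match("E", pnames)]) &&
      beta[match("E", pnames)] < 0)
    flags <- c(flags, "negative_E")
  structure(list(params = stats::setNames(as.numeric(beta), pnames),
                 residual_rms = sqrt(mean(resid^2)),
                 n_samples = length(d), flags = flags),
            class = "pixel_fit")
}

# ---- vectorized map representation -----------------------------------------

# NA-padded per-pixel sample matrices: D, F are m x P (P = nx*ny pixels in
# row-major pixel_index() order); gradient matrices are broadcast to the
# same shape once so each objective evaluation is purely elementwise.
curve_matrix <- function(img, grads = NULL) {
  if (is.null(grads)) grads <- topography_gradients(img)
  P <- img$nx * img$ny
  lens <- vapply(img$curves, function(cv) {
    if (is.null(cv) || "missing" %in% cv$flags) 0L else length(cv$d)
  }, integer(1))
  m <- max(lens, 1L)
  D <- matrix(NA_real_, m, P)
  F <- matrix(NA_real_, m, P)
  for (i in seq_len(P)) {
    if (lens[i] > 0L) {
      D[seq_len(lens[i]), i] <- img$curves[[i]]$d
      F[seq_len(lens[i]), i] <- img$curves[[i]]$f
    }
  }
  gx <- as.vector(t(grads$gx))  # row-major to match pixel_index()
  gy <- as.vector(t(grads$gy))
  list(D = D, F = F, m = m, P = P, nx = img$nx, ny = img$ny,
       GX = matrix(gx, m, P, byrow = TRUE),
       GY = matrix(gy, m, P, byrow = TRUE),
       missing = lens == 0L)
}

# Vectorized OLS over all pixels. use_mask: logical m x P, TRUE = use the
# sample. Returns per-pixel coefficients, residual rms, flags, objective
# ingredients. Matches fit_curve_linear() pixel by pixel (tested).
cm_fit <- function(cm, model, td, poisson = 0.5, r_cell = 10e-6,
                   use_mask = NULL, min_samples = 4L) {
  D <- cm$D
  geom <- td$r + td$a * cm$GX + td$b * cm$GY + td$c * D
  kind <- if (model == "sneddon") "angle" else "radius"
  W <- !is.na(D) & !is.na(cm$F)
  if (!is.null(use_mask)) W <- W & use_mask
  viol <- W & !geometry_ok(geom, kind)
  viol_frac <- sum(viol) / max(sum(W), 1L)
  geomp <- pmax(geom, .Machine$double.xmin)
  kE <- (4 / 3) * (1 / (1 - poisson^2))
  if (model == "hs") {
    P1 <- 4 * pi * geomp * D * sqrt(D / (D + 2 * geomp))
    P2 <- kE * sqrt(geomp) * D^1.5
  } else if (model == "hertz") {
    P1 <- kE * sqrt(geomp) * D^1.5; P2 <- NULL
  } else if (model == "sneddon") {
    P1 <- (2 * tan(pmin(geomp, pi / 2 - 1e-12)) / pi) *
      (1 / (1 - poisson^2)) * D^2
    P2 <- NULL
  } else if (model == "cslc") {
    P1 <- 4 * pi * D * (geomp / r_cell + 1); P2 <- NULL
  } else stop("cm_fit: unknown model ", model, call. = FALSE)
  Fw <- cm$F
  Fw[!W] <- 0
  P1[!W] <- 0
  n_used <- colSums(W)
  if (!is.null(P2)) {
    P2[!W] <- 0
    S11 <- colSums(P1 * P1); S12 <- colSums(P1 * P2); S22 <- colSums(P2 * P2)
    b1 <- colSums(P1 * Fw); b2 <- colSums(P2 * Fw)
    det <- S11 * S22 - S12^2
    singular <- !(det > 1e-12 * S11 * S22) | n_used < 2L
    det[singular] <- 1
    th1 <- (S22 * b1 - S12 * b2) / det
    th2 <- (S11 * b2 - S12 * b1) / det
    th1[singular] <- NA_real_; th2[singular] <- NA_real_
    Fhat <- P1 * matrix(th1, cm$m, cm$P, byrow = TRUE) +
      P2 * matrix(th2, cm$m, cm$P, byrow = TRUE)
    coefs <- rbind(th1, th2)
  } else {
    S11 <- colSums(P1 * P1)
    b1 <- colSums(P1 * Fw)
    singular <- S11 <= 0
    S11[singular] <- 1
    th1 <- b1 / S11
    th1[singular] <- NA_real_
    Fhat <- P1 * matrix(th1, cm$m, cm$P, byrow = TRUE)
    coefs <- rbind(th1)
  }
  rownames(coefs) <- model_params(model)
  Rres <- (Fw - Fhat)
  Rres[!W] <- 0
  Rres[, singular] <- 0
  rss <- colSums(Rres^2)
  rms <- ifelse(n_used > 0, sqrt(rss / pmax(n_used, 1L)), NA_real_)
  geom_viol <- colSums(viol) > 0
  too_shallow <- !cm$missing & n_used < min_samples
  ok <- !cm$missing & !geom_viol & !too_shallow & !singular
  coefs[, !ok] <- NA_real_
  rms[!ok] <- NA_real_
  neg_E <- rep(FALSE, cm$P)
  if ("E" %in% rownames(coefs))
    neg_E <- ok & coefs["E", ] < 0
  list(coefs = coefs, rms = rms, rss = rss, n_used = n_used, ok = ok,
       missing = cm$missing, geometry_violation = geom_viol,
       too_shallow = too_shallow, singular = singular & !cm$missing,
       negative_E = neg_E, viol_frac = viol_frac,
       resid = Rres, W = W, basis = list(P1 = P1, P2 = P2))
}

cm_objective <- function(fit, objective = c("variance", "sum")) {
  objective <- match.arg(objective)
  r <- fit$rms[fit$ok]
  if (length(r) < 2L) return(Inf)
  if (objective == "variance") stats::var(r) else sum(fit$rss[fit$ok])
}

vec_to_grid <- function(v, ny, nx) matrix(v, ny, nx, byrow = TRUE)

#' Fit every pixel of a force-volume image
#'
#' Independent per-pixel OLS fits with a shared set of tip descriptors,
#' aggregated into a map-wide objective: by default the variance, across
#' pixels, of the per-curve residual rms ("fitting error"), which is the
#' quantity fed back to the MCMC descriptor search; a summed squared
#' residual ("accumulative") objective is also available. Flagged pixels
#' (missing, tip-geometry violation, too-shallow window, singular design)
#' are excluded from the objective but retained in the grids as `NA`.
#'
#' @param img a [spectrum_image()].
#' @param model model id.
#' @param td a [tip_descriptors()].
#' @param config a [model_config()].
#' @param depth_window optional maximum depth (m); samples deeper than this
#'   are excluded before fitting (see [truncate_to_depth()]).
#' @param objective `"variance"` or `"sum"`.
#' @param split optional [split_train_test()] result; with
#'   `use = "train"` only training samples enter the fits.
#' @param use which samples to fit on when `split` is given.
#' @param grads optional precomputed [topography_gradients()].
#' @param cm internal: precomputed curve matrix (avoids rebuilds in loops).
#' @return An object of class `map_fit_result`: per-parameter `ny x nx`
#'   grids (`$grids$sigma`, `$grids$E`, ...), `$residual_rms` grid,
#'   `$flags` (list of logical grids), `$objective`, `$objective_type`,
#'   `$td`, `$model`, `$n_ok`, and a `$warning` field when more than half
#'   of the pixels are flagged.
#' @export
fit_map <- function(img, model, td, config = model_config(model),
                    depth_window = NULL, objective = c("variance", "sum"),
                    split = NULL, use = c("all", "train"), grads = NULL,
                    cm = NULL) {
  objective <- match.arg(objective)
  use <- match.arg(use)
  if (is.null(cm)) cm <- curve_matrix(img, grads)
  use_mask <- NULL
  if (!is.null(depth_window)) {
    if (!is.numeric(depth_window) || depth_window <= 0)
      stop("fit_map: `depth_window` must be > 0", call. = FALSE)
    use_mask <- !is.na(cm$D) & cm$D <= depth_window
  }
  if (!is.null(split) && use == "train") {
    train <- !split_test_mask(split, cm)
    use_mask <- if (is.null(use_mask)) train else (use_mask & train)
  }
  fit <- cm_fit(cm, model, td, poisson = config$poisson,
                r_cell = config$r_cell, use_mask = use_mask)
  obj <- cm_objective(fit, objective)
  grids <- lapply(seq_len(nrow(fit$coefs)), function(i)
    vec_to_grid(fit$coefs[i, ], img$ny, img$nx))
  names(grids) <- rownames(fit$coefs)
  flags <- lapply(fit[c("missing", "geometry_violation", "too_shallow",
                        "singular", "negative_E")],
                  vec_to_grid, ny = img$ny, nx = img$nx)
  res <- structure(list(
    grids = grids,
    residual_rms = vec_to_grid(fit$rms, img$ny, img$nx),
    flags = flags, n_ok = sum(fit$ok),
    objective = obj, objective_type = objective,
    td = td, model = model, config = config,
    depth_window = depth_window), class = "map_fit_result")
  if (res$n_ok < 0.5 * img$nx * img$ny)
    res$warning <- sprintf("more than 50%% of pixels flagged (%d of %d usable)",
                           res$n_ok, img$nx * img$ny)
  res
}

#' @export
print.map_fit_result <- function(x, ...) {
  cat(sprintf("<map_fit_result> model %s, %d usable pixels, objective (%s) = %.4g\n",
              x$model, x$n_ok, x$objective_type, x$objective))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Split samples into training and test groups
#'
#' Splits the samples of every curve into a training group (7/8 by default)
#' and a held-out test group (1/8), used to turn in-sample fitting error
#' into out-of-sample prediction error for model selection. The split is
#' per-point within each curve -- every curve keeps training points, so its
#' variates stay estimable -- and stratified over depth: the depth-ordered
#' samples are cut into consecutive blocks of `round(1/fraction_test)` and
#' one sample per complete block is drawn at random. Curves with fewer than
#' one full block contribute no test points (noted in `$short_curves`).
#'
#' @param img a [spectrum_image()].
#' @param fraction_test test fraction (default 1/8).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return An object of class `fd_split`: list of per-pixel integer vectors
#'   of test-sample indices, plus bookkeeping fields.
#' @export
split_train_test <- function(img, fraction_test = 1 / 8, seed = 1L) {
  stopifnot(fraction_test > 0, fraction_test < 0.5)
  B <- max(2L, round(1 / fraction_test))
  P <- img$nx * img$ny
  short <- integer(0)
  test <- run_with_seed(seed, lapply(seq_len(P), function(i) {
    cv <- img$curves[[i]]
    if (is.null(cv) || "missing" %in% cv$flags) return(integer(0))
    n <- length(cv$d)
    nb <- n %/% B
    if (nb == 0L) { short <<- c(short, i); return(integer(0)) }
    offs <- sample.int(B, nb, replace = TRUE)
    sort((seq_len(nb) - 1L) * B + offs)
  }))
  structure(list(test = test, fraction_test = fraction_test, seed = seed,
                 block = B, short_curves = short, nx = img$nx, ny = img$ny),
            class = "fd_split")
}

# logical m x P mask of test samples aligned with a curve matrix
split_test_mask <- function(split, cm) {
  M <- matrix(FALSE, cm$m, cm$P)
  for (i in seq_len(cm$P)) {
    ti <- split$test[[i]]
    if (length(ti)) M[ti, i] <- TRUE
  }
  M
}

#' Out-of-sample prediction error of a model
#'
#' Fits every pixel's variates on its training samples only, predicts force
#' at the held-out test depths, and returns the rms difference between
#' predicted and measured force over all test points. This is the model
#' selection criterion: the model generating the data attains (up to noise)
#' the lowest prediction error.
#'
#' @inheritParams fit_map
#' @param split a [split_train_test()] result.
#' @return An object of class `prediction_error`: list with `rms` (N,
#'   overall), `per_pixel` (`ny x nx` grid of per-pixel test rms), `n_test`
#'   (test points used). Pixels with no test points or flagged training
#'   fits are skipped.
#' @export
prediction_error <- function(img, model, td, split,
                             config = model_config(model),
                             depth_window = NULL, grads = NULL, cm = NULL) {
  if (is.null(cm)) cm <- curve_matrix(img, grads)
  test <- split_test_mask(split, cm)
  avail <- !is.na(cm$D) & !is.na(cm$F)
  if (!is.null(depth_window)) avail <- avail & cm$D <= depth_window
  fit <- cm_fit(cm, model, td, poisson = config$poisson,
                r_cell = config$r_cell, use_mask = avail & !test)
  # rebuild predictions on the test samples from the fitted coefficients
  fitall <- cm_fit(cm, model, td, poisson = config$poisson,
                   r_cell = config$r_cell, use_mask = avail)
  Fhat <- fitall$basis$P1 * matrix(fit$coefs[1, ], cm$m, cm$P, byrow = TRUE)
  if (nrow(fit$coefs) > 1L)
    Fhat <- Fhat + fitall$basis$P2 *
      matrix(fit$coefs[2, ], cm$m, cm$P, byrow = TRUE)
  usable <- test & avail & matrix(fit$ok, cm$m, cm$P, byrow = TRUE)
  resid <- cm$F - Fhat
  resid[!usable] <- NA_real_
  n_px <- colSums(usable)
  sq <- resid^2
  sq[!usable] <- 0
  per_pixel <- ifelse(n_px > 0, sqrt(colSums(sq) / pmax(n_px, 1L)), NA_real_)
  n_test <- sum(n_px)
  if (n_test == 0L)
    stop("prediction_error: no usable test points", call. = FALSE)
  structure(list(rms = sqrt(sum(sq) / n_test),
                 per_pixel = vec_to_grid(per_pixel, img$ny, img$nx),
                 n_test = n_test, model = model),
            class = "prediction_error")
}

#' @export
print.prediction_error <- function(x, ...) {
  cat(sprintf("<prediction_error> model %s: rms = %.4g nN over %d test points\n",
              x$model, 1e9 * x$rms, x$n_test))
  invisible(x)
}
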
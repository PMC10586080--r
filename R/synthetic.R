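# Virtual-cell phantom generator. Every validation and acceptance
# experiment in this package runs against phantoms with known ground truth:
# a dome-shaped cell body, tensile fiber segments over a compressive
# background (the tensegrity picture: tensed actin cables, compressed
# microtubule struts), an optional two-layer stress structure (cortex over
# nucleoskeleton), a depth/gradient-dependent effective tip radius, optional
# scan-direction synchronization error, and additive Gaussian force noise.

#' Build a virtual-cell phantom
#'
#' Constructs the ground-truth fields the curve simulator samples from. The
#' topography is a truncated paraboloid dome (smooth, analytically
#' differentiable gradients); the shallow-layer stress field is a
#' compressive background plus tensile fiber segments; an optional nucleus
#' disk carries a distinct deep-layer stress below the cortex thickness.
#'
#' @param nx,ny grid size (pixels).
#' @param pitch pixel pitch (m).
#' @param dome list `(height, radius, center)`: dome apex height (m),
#'   footprint radius (m), center in meters (default: field center).
#' @param sigma_bg background (compressive, `< 0`) prestress (Pa).
#' @param fibers list of fiber segments, each
#'   `list(from = c(x, y), to = c(x, y), width, sigma)` in meters / Pa.
#' @param nucleus `NULL` for a single-layer phantom, or
#'   `list(center = c(x, y), radius, sigma_deep, cortex_thickness)`:
#'   below depth `cortex_thickness` (m), pixels inside the disk carry
#'   stress `sigma_deep` (Pa).
#' @param E0 base Young's modulus (Pa).
#' @param fiber_E modulus on fiber pixels (default `E0`).
#' @param td true [tip_descriptors()].
#' @param sync_b scan-direction radius perturbation (m per unit slope)
#'   injected when curves are simulated with `sync_error = TRUE`.
#' @param noise_rms additive force noise rms (N).
#' @param seed integer seed (stored; used by the curve simulators).
#' @return An object of class `phantom` carrying the ground-truth grids
#'   (`topography`, `sigma1`, `sigma2`, `E`, gradient grids) and parameters.
#' @export
make_phantom <- function(nx = 32L, ny = 32L, pitch = 0.5e-6,
                         dome = list(height = 3e-6, radius = 6e-6,
                                     center = NULL),
                         sigma_bg = -5e3, fibers = list(), nucleus = NULL,
                         E0 = 20e3, fiber_E = E0,
                         td = tip_descriptors(1e-7, 3e-8, 5e-8, 0.05),
                         sync_b = 1e-7, noise_rms = 0, seed = 1L) {
  stopifnot(nx >= 2L, ny >= 2L, pitch > 0, dome$height > 0, dome$radius > 0)
  x <- (seq_len(nx) - 1) * pitch
  y <- (seq_len(ny) - 1) * pitch
  if (is.null(dome$center)) dome$center <- c(max(x) / 2, max(y) / 2)
  X <- matrix(rep(x, each = ny), ny, nx)
  Y <- matrix(rep(y, nx), ny, nx)
  rr2 <- (X - dome$center[1])^2 + (Y - dome$center[2])^2
  topo <- matrix(dome$height * pmax(0, 1 - rr2 / dome$radius^2), ny, nx)
  sigma1 <- matrix(sigma_bg, ny, nx)
  Emap <- matrix(E0, ny, nx)
  seg_dist <- function(px, py, p0, p1) {
    vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else pmin(pmax(((px - p0[1]) * vx +
                                          (py - p0[2]) * vy) / L2, 0), 1)
    sqrt((px - (p0[1] + t * vx))^2 + (py - (p0[2] + t * vy))^2)
  }
  for (fb in fibers) {
    dmat <- seg_dist(X, Y, fb$from, fb$to)
    on_fiber <- dmat <= fb$width / 2
    if (!any(on_fiber)) {
      warning("make_phantom: fiber lies outside the grid; clipped")
      next
    }
    sigma1[on_fiber] <- fb$sigma
    Emap[on_fiber] <- fiber_E
  }
  sigma2 <- sigma1
  t_cortex <- NA_real_
  if (!is.null(nucleus)) {
    stopifnot(nucleus$radius > 0, nucleus$cortex_thickness > 0)
    in_nuc <- (X - nucleus$center[1])^2 + (Y - nucleus$center[2])^2 <=
      nucleus$radius^2
    sigma2[in_nuc] <- nucleus$sigma_deep
    t_cortex <- nucleus$cortex_thickness
  }
  grads <- topography_gradients(topo, pitch)
  structure(list(nx = nx, ny = ny, pitch = pitch, topography = topo,
                 sigma1 = sigma1, sigma2 = sigma2, E = Emap,
                 two_layer = !is.null(nucleus), cortex_thickness = t_cortex,
                 td = td, sync_b = sync_b, noise_rms = noise_rms,
                 gx = grads$gx, gy = grads$gy, dome = dome,
                 nucleus = nucleus, seed = seed), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, pitch %.3g um, %s-layer, noise %.3g nN\n",
              x$nx, x$ny, 1e6 * x$pitch,
              if (x$two_layer) "two" else "single", 1e9 * x$noise_rms))
  invisible(x)
}

#' Simulate the forward force curve at one phantom pixel
#'
#' Forward HS model with the phantom's true depth/gradient-dependent tip
#' radius. Two-layer phantoms treat the layers as a series composite: for
#' `d <= t` the cortex law (`sigma1`) applies; past the interface the tip
#' presses into the deep layer (`sigma2`) as a fresh contact with depth
#' re-zeroed at `t`, added to the force already built up in the cortex,
#' `F(d) = F1(t) + F2(d - t)` -- continuous at the interface and dominated
#' by the deep layer at full depth. Gaussian noise of rms
#' `noise_rms` is added, and the curve is truncated at the first sample
#' reaching the force threshold, mirroring a force-trigger acquisition; if
#' the threshold is never reached the full grid is kept and the curve
#' flagged `"threshold_not_reached"`.
#'
#' @param ph a [make_phantom()] phantom.
#' @param ix,iy pixel (1-based).
#' @param d_grid depth samples (m), starting at 0.
#' @param sync_error inject the scan-direction synchronization artifact
#'   (adds `sync_b * dz/dy` to the effective radius)?
#' @param noise_rms force noise rms (N); default the phantom's. Uses the
#'   current RNG state (seed at the image level).
#' @param force_threshold trigger threshold (N); 3 nN is the mapping
#'   default, 1.5 nN the line-profile default.
#' @param poisson Poisson's ratio of the forward model.
#' @return a [force_curve()].
#' @export
simulate_curve <- function(ph, ix, iy, d_grid = seq(0, 800e-9, by = 10e-9),
                           sync_error = FALSE, noise_rms = ph$noise_rms,
                           force_threshold = 3e-9, poisson = 0.5) {
  stopifnot(ix >= 1L, ix <= ph$nx, iy >= 1L, iy <= ph$ny)
  gx <- ph$gx[iy, ix]; gy <- ph$gy[iy, ix]
  td <- ph$td
  b_eff <- td$b + if (sync_error) ph$sync_b else 0
  R <- td$r + td$a * gx + b_eff * gy + td$c * d_grid
  if (any(R <= 0))
    stop("simulate_curve: true tip geometry nonpositive at this pixel",
         call. = FALSE)
  if (ph$two_layer) {
    # layers respond in series: down to the interface the cortex law
    # applies; past it the tip presses into the deep layer as a fresh
    # contact (depth re-zeroed at the interface), on top of the force
    # already built up in the cortex. Continuous at d = t by construction.
    t <- ph$cortex_thickness
    s1 <- ph$sigma1[iy, ix]; s2 <- ph$sigma2[iy, ix]
    Rt <- td$r + td$a * gx + b_eff * gy + td$c * t
    f1_t <- hs_force(s1, ph$E[iy, ix], Rt, t, poisson)
    dd <- pmax(d_grid - t, 0)
    Rdd <- td$r + td$a * gx + b_eff * gy + td$c * dd
    f <- ifelse(d_grid <= t,
                hs_force(s1, ph$E[iy, ix], R, d_grid, poisson),
                f1_t + hs_force(s2, ph$E[iy, ix], Rdd, dd, poisson))
  } else {
    f <- hs_force(ph$sigma1[iy, ix], ph$E[iy, ix], R, d_grid, poisson)
  }
  if (noise_rms > 0) f <- f + stats::rnorm(length(f), 0, noise_rms)
  flags <- character()
  hit <- which(f >= force_threshold)
  if (length(hit)) {
    keep <- seq_len(hit[1])
    d_grid <- d_grid[keep]; f <- f[keep]
  } else flags <- "threshold_not_reached"
  force_curve(d_grid, f, contact_height = ph$topography[iy, ix],
              pixel = c(ix, iy), flags = flags)
}

#' Simulate a full force-volume spectrum image from a phantom
#'
#' @param ph a [make_phantom()] phantom.
#' @param d_max,d_step depth grid (m): `seq(0, d_max, by = d_step)`.
#' @param force_threshold trigger threshold (N).
#' @param sync_error inject the scan-direction synchronization artifact?
#' @param spring_constant cantilever spring constant metadata (N/m).
#' @param seed seed for the noise (default the phantom's seed); generation
#'   is exactly reproducible from (phantom, seed).
#' @return list with `img` (a [spectrum_image()]) and `truth` (per-pixel
#'   ground-truth grids `sigma1`, `sigma2`, `E`, the true descriptors and
#'   layer parameters).
#' @export
simulate_spectrum_image <- function(ph, d_max = 800e-9, d_step = 10e-9,
                                    force_threshold = 3e-9,
                                    sync_error = FALSE,
                                    spring_constant = 0.05,
                                    seed = ph$seed) {
  d_grid <- seq(0, d_max, by = d_step)
  curves <- vector("list", ph$nx * ph$ny)
  run_with_seed(seed, {
    for (iy in seq_len(ph$ny)) {
      for (ix in seq_len(ph$nx)) {
        curves[[(iy - 1L) * ph$nx + ix]] <-
          simulate_curve(ph, ix, iy, d_grid, sync_error = sync_error,
                         force_threshold = force_threshold)
      }
    }
  })
  img <- spectrum_image(curves, ph$topography, ph$pitch, spring_constant,
                        force_threshold)
  truth <- list(sigma1 = ph$sigma1, sigma2 = ph$sigma2, E = ph$E,
                td = ph$td, two_layer = ph$two_layer,
                cortex_thickness = ph$cortex_thickness,
                sync_error = sync_error, sync_b = ph$sync_b,
                noise_rms = ph$noise_rms, seed = seed)
  list(img = img, truth = truth)
}

#' Simulate a line-scan time series
#'
#' Generates repeated 1D stress/height profiles emulating a compressed-cell
#' time course: a dome-shaped line profile whose central stress relaxes
#' exponentially to a plateau fraction of its initial value, with an
#' optional monotone fractional height change over the run.
#'
#' @param nx points per line.
#' @param pitch point spacing (m).
#' @param times acquisition times (s).
#' @param sigma0 initial peak stress (Pa).
#' @param plateau_frac stress plateau as a fraction of the initial value
#'   (0.5 emulates a decay to 50%).
#' @param tau decay time constant (s).
#' @param height0 initial peak height (m).
#' @param height_change total fractional height change at the end of the
#'   series (e.g. `+0.75` for a 75% increase, `-0.85` for an 85% drop).
#' @param noise_rel relative (fraction-of-peak) Gaussian noise on both
#'   profiles.
#' @param seed integer seed.
#' @return list with `series` (a [linescan_series()]) and `truth`
#'   (the generating parameters).
#' @export
make_linescan_series <- function(nx = 64L, pitch = 0.5e-6,
                                 times = seq(0, 3600, by = 30),
                                 sigma0 = 40e3, plateau_frac = 0.5,
                                 tau = 600, height0 = 3e-6,
                                 height_change = 0, noise_rel = 0.01,
                                 seed = 1L) {
  x <- (seq_len(nx) - 1) * pitch
  xc <- max(x) / 2
  shape <- pmax(0, 1 - ((x - xc) / (0.4 * max(x)))^2)
  nt <- length(times)
  decay <- plateau_frac + (1 - plateau_frac) * exp(-times / tau)
  hfac <- 1 + height_change * (times - times[1]) / (max(times) - times[1])
  stress <- outer(decay, sigma0 * shape)
  height <- outer(hfac, height0 * shape)
  run_with_seed(seed, {
    stress <- stress + matrix(stats::rnorm(nt * nx, 0, noise_rel * sigma0),
                              nt, nx)
    height <- height + matrix(stats::rnorm(nt * nx, 0, noise_rel * height0),
                              nt, nx)
  })
  list(series = linescan_series(times, stress, height, pitch),
       truth = list(sigma0 = sigma0, plateau_frac = plateau_frac, tau = tau,
                    height0 = height0, height_change = height_change,
                    noise_rel = noise_rel, seed = seed))
}

#' Plateau fraction of a relaxation time course
#'
#' Ratio of the late-time plateau (mean over the trailing fraction of the
#' series) to the initial value (mean over the leading fraction), e.g. a
#' stress time course that relaxes to half its starting value gives 0.5.
#'
#' @param values time-ordered values.
#' @param head_frac,tail_frac fractions of the series used for the initial
#'   and plateau estimates.
#' @return scalar plateau fraction.
#' @export
plateau_fraction <- function(values, head_frac = 0.05, tail_frac = 0.25) {
  n <- length(values)
  nh <- max(1L, floor(head_frac * n))
  nt <- max(1L, floor(tail_frac * n))
  mean(values[(n - nt + 1L):n]) / mean(values[seq_len(nh)])
}
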
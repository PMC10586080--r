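#' Effective tip radius (or cone angle) at a pixel and depth
#'
#' Evaluates the linear tip-shape parametrization
#' `R(d) = r + a * gx + b * gy + c * d`, where `gx`, `gy` are the local
#' topographic gradients and `d` the indentation depth. The same form gives
#' the effective half-angle for the conical model. Nonpositive results are
#' returned as-is; callers must check `geometry_ok()` (the fitter treats a
#' violation as an infinite-penalty signal, never a silent clamp).
#'
#' @param td a [tip_descriptors()].
#' @param gx,gy topographic gradients dz/dx and dz/dy (dimensionless slope)
#'   at the pixel.
#' @param d depth (m), scalar or vector, `>= 0`.
#' @return numeric vector of effective radii (m) or angles (rad), one per
#'   depth sample.
#' @export
tip_radius_at <- function(td, gx, gy, d) {
  if (any(d < 0)) stop("tip_radius_at: depth must be >= 0", call. = FALSE)
  td$r + td$a * gx + td$b * gy + td$c * d
}

#' Check tip geometry validity
#'
#' A spherical-tip radius must be strictly positive; a cone half-angle must
#' lie in (0, pi/2).
#'
#' @param values radii (m) or angles (rad) from [tip_radius_at()].
#' @param kind `"radius"` or `"angle"`.
#' @return logical vector, `TRUE` where the geometry is valid.
#' @export
geometry_ok <- function(values, kind = c("radius", "angle")) {
  kind <- match.arg(kind)
  if (kind == "radius") values > 0 else (values > 0 & values < pi / 2)
}

#' Default HS angle factor
#'
#' The prestress term of the HS model carries the geometric factor
#' `cos(atan(sqrt(2 R / d)))`, which simplifies to `sqrt(d / (d + 2 R))`
#' (the identity `cos(atan(x)) = 1/sqrt(1 + x^2)`). It is exposed as a
#' pluggable function so an alternative reading of the angle argument can
#' be swapped in without touching the fitter.
#'
#' @param d depth (m), `>= 0`.
#' @param R tip radius (m), `> 0`.
#' @return dimensionless factor in `[0, 1)`; 0 at `d = 0`.
#' @export
hs_angle_factor <- function(d, R) sqrt(d / (d + 2 * R))

#' Hertzian-sphere force with horizontal prestress (HS model)
#'
#' Total indentation force for a spherical tip on a prestressed specimen:
#' `F = 4 pi R d sigma cos(atan(sqrt(2R/d))) + (4/3) (1/(1-g^2)) E sqrt(R) d^1.5`.
#' The first term is the upward component of the pre-existing in-plane
#' stress (tensile `sigma > 0` adds resistance; compressive `sigma < 0` can
#' make the total force negative at shallow depth); the second is the
#' classical Hertz elastic term.
#'
#' @param sigma prestress (Pa); tensile positive, compressive negative.
#' @param E Young's modulus (Pa).
#' @param R tip radius (m), `> 0`; may be a vector matched to `d` when the
#'   radius is depth dependent.
#' @param d depth (m), `>= 0`.
#' @param poisson Poisson's ratio.
#' @param angle_factor the prestress-term angle factor, by default
#'   [hs_angle_factor()].
#' @return force (N), same length as `d`.
#' @export
hs_force <- function(sigma, E, R, d, poisson = 0.5,
                     angle_factor = hs_angle_factor) {
  if (any(d < 0)) stop("hs_force: depth must be >= 0", call. = FALSE)
  if (any(R <= 0)) stop("hs_force: tip radius must be > 0", call. = FALSE)
  4 * pi * R * d * sigma * angle_factor(d, R) +
    (4 / 3) * (1 / (1 - poisson^2)) * E * sqrt(R) * d^1.5
}

#' Hertz force (spherical tip)
#'
#' `F = (4/3) (1/(1-g^2)) E sqrt(R) d^1.5`.
#'
#' @inheritParams hs_force
#' @return force (N).
#' @export
hertz_force <- function(E, R, d, poisson = 0.5) {
  if (any(d < 0)) stop("hertz_force: depth must be >= 0", call. = FALSE)
  if (any(R <= 0)) stop("hertz_force: tip radius must be > 0", call. = FALSE)
  (4 / 3) * (1 / (1 - poisson^2)) * E * sqrt(R) * d^1.5
}

#' Sneddon force (conical tip)
#'
#' `F = (2 tan(theta) / pi) (1/(1-g^2)) E d^2`, `theta` the half-angle.
#'
#' @param theta cone half-angle (rad), in (0, pi/2); may be a vector matched
#'   to `d`.
#' @inheritParams hs_force
#' @return force (N).
#' @export
sneddon_force <- function(E, theta, d, poisson = 0.5) {
  if (any(d < 0)) stop("sneddon_force: depth must be >= 0", call. = FALSE)
  if (!all(geometry_ok(theta, "angle")))
    stop("sneddon_force: half-angle must be in (0, pi/2)", call. = FALSE)
  (2 * tan(theta) / pi) * (1 / (1 - poisson^2)) * E * d^2
}

#' Cortical-shell-liquid-core (CSLC) force
#'
#' Non-Hertzian model treating the cell as a tensed cortical shell over a
#' liquid core: `F = 4 T (1/r_cell + 1/R) pi R d`, linear in depth and in
#' the cortical tension `T`.
#'
#' @param tension cortical tension `T` (N/m).
#' @param r_cell cell radius (m), `> 0`.
#' @inheritParams hs_force
#' @return force (N).
#' @export
cslc_force <- function(tension, r_cell, R, d) {
  if (any(d < 0)) stop("cslc_force: depth must be >= 0", call. = FALSE)
  if (any(R <= 0)) stop("cslc_force: tip radius must be > 0", call. = FALSE)
  if (r_cell <= 0) stop("cslc_force: cell radius must be > 0", call. = FALSE)
  4 * tension * (1 / r_cell + 1 / R) * pi * R * d
}

#' Design columns of the linear model variates
#'
#' Each contact model is linear in its material variates once the tip
#' geometry is fixed, so a per-curve fit is ordinary least squares of force
#' on these basis columns, evaluated with the depth-dependent effective
#' radius (or angle) from [tip_radius_at()]:
#' \itemize{
#'   \item HS: `Phi_sigma = 4 pi R d sqrt(d/(d+2R))` and
#'     `Phi_E = (4/3)(1/(1-g^2)) sqrt(R) d^1.5` (variates `sigma`, `E`);
#'   \item Hertz: `Phi_E` only;
#'   \item Sneddon: `Phi_E = (2 tan(theta)/pi)(1/(1-g^2)) d^2`;
#'   \item CSLC: `Phi_T = 4 pi d (R/r_cell + 1)` (variate `T`).
#' }
#'
#' @param model `"hs"`, `"hertz"`, `"sneddon"` or `"cslc"`.
#' @param td a [tip_descriptors()] (kind `"angle"` for Sneddon).
#' @param gx,gy topographic gradients at the pixel.
#' @param d depth samples (m).
#' @param poisson Poisson's ratio.
#' @param r_cell cell radius (m), CSLC only.
#' @param angle_factor HS prestress angle factor, see [hs_force()].
#' @return numeric matrix with one row per depth sample and one named
#'   column per variate, with attribute `geometry_ok` (logical scalar:
#'   `FALSE` if any sample violated the tip-geometry domain).
#' @export
basis_functions <- function(model, td, gx, gy, d, poisson = 0.5,
                            r_cell = 10e-6, angle_factor = hs_angle_factor) {
  geom <- tip_radius_at(td, gx, gy, d)
  kind <- if (model == "sneddon") "angle" else "radius"
  ok <- all(geometry_ok(geom, kind))
  X <- switch(model,
    hs = {
      R <- pmax(geom, .Machine$double.xmin)  # keeps columns finite when flagged
      cbind(sigma = 4 * pi * R * d * angle_factor(d, R),
            E = (4 / 3) * (1 / (1 - poisson^2)) * sqrt(R) * d^1.5)
    },
    hertz = cbind(
      E = (4 / 3) * (1 / (1 - poisson^2)) * sqrt(pmax(geom, 0)) * d^1.5),
    sneddon = cbind(
      E = (2 * tan(pmin(pmax(geom, 0), pi / 2 - 1e-12)) / pi) *
        (1 / (1 - poisson^2)) * d^2),
    cslc = cbind(T = 4 * pi * d * (geom / r_cell + 1)),
    stop("basis_functions: unknown model ", model, call. = FALSE))
  attr(X, "geometry_ok") <- ok
  X
}

#' Model variate names
#' @param model model id.
#' @return character vector of variate names in basis-column order.
#' @export
model_params <- function(model) {
  switch(model, hs = c("sigma", "E"), hertz = "E", sneddon = "E",
         cslc = "T", stop("unknown model ", model, call. = FALSE))
}

#' Depth at which a compressive-prestress force curve crosses zero
#'
#' For `sigma < 0` and `E > 0` the HS force is negative in the shallow
#' indentation range (the compressed element bends away from the tip) and
#' crosses zero at a finite depth where the elastic term overtakes the
#' prestress term. Found by bisection on the forward model.
#'
#' @inheritParams hs_force
#' @param d_max upper bracket for the search (m).
#' @param tol relative tolerance on the root.
#' @return crossover depth (m), or `NA` if the force does not cross zero in
#'   `(0, d_max]`.
#' @export
hs_zero_crossing <- function(sigma, E, R, d_max = 2e-6, poisson = 0.5,
                             tol = 1e-10) {
  stopifnot(sigma < 0, E > 0, R > 0)
  fn <- function(d) hs_force(sigma, E, R, d, poisson)
  lo <- d_max * 1e-9
  hi <- d_max
  if (fn(lo) >= 0 || fn(hi) <= 0) return(NA_real_)
  while ((hi - lo) / hi > tol) {
    mid <- 0.5 * (lo + hi)
    if (fn(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}
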
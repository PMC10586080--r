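#' Force-deformation curve for one pixel
#'
#' A post-contact force-deformation (f-d) curve: deformation samples `d`
#' (m, nondecreasing, starting at 0 at contact) and force samples `f` (N),
#' together with the contact height (the piezo height at which tip-cell
#' contact begins, which defines the topography map) and the pixel index.
#'
#' @param d numeric vector of deformation samples (m), nondecreasing,
#'   `d[1] == 0` at contact.
#' @param f numeric vector of force samples (N), same length as `d`.
#' @param contact_height contact height (m).
#' @param pixel integer pair `c(ix, iy)` (1-based column, row).
#' @param flags character vector of quality flags (e.g.
#'   `"threshold_not_reached"`, `"too_shallow"`).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(d, f, contact_height = NA_real_,
                        pixel = c(NA_integer_, NA_integer_),
                        flags = character()) {
  d <- as.numeric(d); f <- as.numeric(f)
  if (length(d) != length(f))
    stop("force_curve: `d` and `f` must have the same length", call. = FALSE)
  if (length(d) < 1L)
    stop("force_curve: empty curve", call. = FALSE)
  if (!isTRUE(all(diff(d) >= 0)))
    stop("force_curve: `d` must be nondecreasing", call. = FALSE)
  if (abs(d[1]) > .Machine$double.eps)
    stop("force_curve: `d[1]` must be 0 at contact", call. = FALSE)
  if (any(d < 0))
    stop("force_curve: deformation must be >= 0 after contact", call. = FALSE)
  if (length(d) < 4L) flags <- union(flags, "too_shallow")
  structure(list(d = d, f = f, contact_height = as.numeric(contact_height),
                 pixel = as.integer(pixel), flags = flags),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, d in [0, %.1f nm], max |f| = %.3f nN",
              length(x$d), 1e9 * max(x$d), 1e9 * max(abs(x$f))))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Force-volume spectrum image
#'
#' A grid of force-deformation curves acquired over a scan area, with the
#' simultaneously collected topography (one contact height per pixel) and
#' acquisition metadata. Curves are stored row-major: pixel `(ix, iy)` is
#' element `(iy - 1) * nx + ix` of `curves`; a missing pixel is `NULL`.
#'
#' @param curves list of [force_curve()] objects (or `NULL` for missing
#'   pixels), length `nx * ny`, row-major.
#' @param topography `ny x nx` numeric matrix of contact heights (m).
#' @param pixel_pitch pixel pitch (m).
#' @param spring_constant cantilever spring constant (N/m).
#' @param force_threshold force trigger threshold (N).
#' @param scan_axis fast-scan direction, `"x"` or `"y"`.
#' @param threshold_tol tolerance on the `max(f) <= force_threshold`
#'   invariant, as a fraction of the threshold (accounts for the one-sample
#'   trigger overshoot plus noise).
#' @return An object of class `spectrum_image`.
#' @export
spectrum_image <- function(curves, topography, pixel_pitch, spring_constant,
                           force_threshold, scan_axis = c("y", "x"),
                           threshold_tol = 0.25) {
  scan_axis <- match.arg(scan_axis)
  if (!is.matrix(topography) || !is.numeric(topography))
    stop("spectrum_image: `topography` must be a numeric matrix", call. = FALSE)
  ny <- nrow(topography); nx <- ncol(topography)
  if (nx < 2L || ny < 2L)
    stop("spectrum_image: grid must be at least 2 x 2", call. = FALSE)
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("spectrum_image: `pixel_pitch` must be > 0", call. = FALSE)
  if (!is.list(curves) || length(curves) != nx * ny)
    stop(sprintf(
      "spectrum_image: `curves` must be a list of length nx * ny = %d", nx * ny),
      call. = FALSE)
  ok <- vapply(curves, function(cv) is.null(cv) || inherits(cv, "force_curve"),
               logical(1))
  if (!all(ok))
    stop("spectrum_image: curves must be force_curve objects or NULL",
         call. = FALSE)
  fmax <- force_threshold * (1 + threshold_tol)
  for (cv in curves) {
    if (!is.null(cv) && any(is.finite(cv$f)) &&
        max(cv$f, na.rm = TRUE) > fmax)
      stop("spectrum_image: curve force exceeds force_threshold beyond tolerance",
           call. = FALSE)
  }
  structure(list(nx = nx, ny = ny, pixel_pitch = pixel_pitch,
                 spring_constant = spring_constant,
                 force_threshold = force_threshold, scan_axis = scan_axis,
                 topography = topography, curves = curves),
            class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  n_missing <- sum(vapply(x$curves, is.null, logical(1)))
  cat(sprintf(
    "<spectrum_image> %d x %d pixels, pitch %.3g um, k = %.3g N/m, trigger %.3g nN\n",
    x$nx, x$ny, 1e6 * x$pixel_pitch, x$spring_constant,
    1e9 * x$force_threshold))
  cat(sprintf("  scan axis: %s; missing pixels: %d\n", x$scan_axis, n_missing))
  invisible(x)
}

#' Linear pixel index into the curve list
#' @param img a [spectrum_image()].
#' @param ix,iy 1-based column / row pixel indices.
#' @return integer index into `img$curves`.
#' @export
pixel_index <- function(img, ix, iy) (iy - 1L) * img$nx + ix

#' Retrieve the curve at a pixel (or NULL if missing)
#' @inheritParams pixel_index
#' @return a [force_curve()] or `NULL`.
#' @export
curve_at <- function(img, ix, iy) img$curves[[pixel_index(img, ix, iy)]]

#' Tip-shape descriptors
#'
#' The effective tip radius (spherical models) or half-angle (conical model)
#' at a pixel and depth is a linear combination of a constant term and
#' topographic-gradient and depth couplings:
#' `R = r + a * dz/dx + b * dz/dy + c * d` (and likewise for the cone angle
#' `theta = theta0 + a * dz/dx + b * dz/dy + c * d`). These four
#' coefficients are the quantities the MCMC search optimizes; the gradient
#' terms absorb topography-coupled artifacts such as scanner/indenter
#' synchronization error, which acts mainly along the scan direction.
#'
#' @param r constant term: base tip radius (m), or base half-angle (rad)
#'   when `kind = "angle"`.
#' @param a,b gradient coupling coefficients (m per unit slope; rad per unit
#'   slope for the conical model).
#' @param c depth coupling coefficient (dimensionless; rad/m for the
#'   conical model).
#' @param kind `"radius"` (HS/Hertz/CSLC) or `"angle"` (Sneddon).
#' @return An object of class `tip_descriptors`.
#' @export
tip_descriptors <- function(r, a = 0, b = 0, c = 0,
                            kind = c("radius", "angle")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(r), is.numeric(a), is.numeric(b), is.numeric(c))
  structure(list(r = r, a = a, b = b, c = c, kind = kind),
            class = "tip_descriptors")
}

#' @export
print.tip_descriptors <- function(x, ...) {
  if (x$kind == "radius")
    cat(sprintf("<tip_descriptors> r = %.4g nm, a = %.4g nm, b = %.4g nm, c = %.4g\n",
                1e9 * x$r, 1e9 * x$a, 1e9 * x$b, x$c))
  else
    cat(sprintf("<tip_descriptors> theta0 = %.4g rad, a = %.4g, b = %.4g, c = %.4g rad/m\n",
                x$r, x$a, x$b, x$c))
  invisible(x)
}

#' Tip descriptors as a named numeric vector
#' @param td a [tip_descriptors()].
#' @return named numeric `c(r, a, b, c)`.
#' @export
td_vector <- function(td) c(r = td$r, a = td$a, b = td$b, c = td$c)

#' @export
as.double.tip_descriptors <- function(x, ...) td_vector(x)

#' Contact-mechanics model configuration
#'
#' @param model one of `"hs"` (Hertzian sphere + horizontal prestress),
#'   `"hertz"`, `"sneddon"` (cone), `"cslc"` (cortical shell, liquid core).
#' @param poisson Poisson's ratio of the specimen; 0.5 (incompressible) is
#'   the standard assumption for living cells.
#' @param r_cell cell radius (m), used by the CSLC model only.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model = c("hs", "hertz", "sneddon", "cslc"),
                         poisson = 0.5, r_cell = 10e-6) {
  model <- match.arg(model)
  if (!is.numeric(poisson) || poisson < 0 || poisson >= 0.5 + 1e-9)
    stop("model_config: `poisson` must be in [0, 0.5]", call. = FALSE)
  if (model == "cslc" && (!is.numeric(r_cell) || r_cell <= 0))
    stop("model_config: `r_cell` must be > 0 for the CSLC model", call. = FALSE)
  structure(list(model = model, poisson = poisson, r_cell = r_cell),
            class = "model_config")
}
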
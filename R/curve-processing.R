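#' Convert a raw approach trace to a force-deformation curve
#'
#' Converts a raw piezo/deflection approach trace into a post-contact f-d
#' curve. Force is spring constant times baseline-corrected deflection;
#' deformation is the deflection-corrected piezo travel past the contact
#' point, `d = (z - z0) - (defl - defl0)`, clipped to `>= 0`.
#'
#' Contact detection (`method = "baseline_mad"`, the default): a linear
#' baseline is fitted to the first 30% of the approach; the contact point
#' is the last sample before force first exceeds baseline + 5 x MAD of the
#' baseline residuals. If the force never clears that noise floor the curve
#' is flagged `"missing"`. The method argument is an enum so alternative
#' detectors can be added without changing callers.
#'
#' @param z_piezo piezo extension samples (m), monotone increasing approach.
#' @param deflection cantilever deflection samples (m), same length.
#' @param k cantilever spring constant (N/m), `> 0`.
#' @param method contact-detection method.
#' @param baseline_fraction fraction of the trace used for the baseline fit.
#' @param mad_mult noise-floor multiplier.
#' @param pixel optional pixel index for provenance.
#' @return a [force_curve()]; if no contact is found, a single-sample curve
#'   flagged `"missing"`.
#' @export
raw_to_fd <- function(z_piezo, deflection, k,
                      method = c("baseline_mad"),
                      baseline_fraction = 0.3, mad_mult = 5,
                      pixel = c(NA_integer_, NA_integer_)) {
  method <- match.arg(method)
  if (length(z_piezo) != length(deflection))
    stop("raw_to_fd: trace arrays must have the same length", call. = FALSE)
  if (k <= 0) stop("raw_to_fd: spring constant must be > 0", call. = FALSE)
  if (any(diff(z_piezo) < 0))
    stop("raw_to_fd: approach segment must be monotone in z", call. = FALSE)
  n <- length(z_piezo)
  nb <- max(4L, floor(baseline_fraction * n))
  base_fit <- stats::lm.fit(cbind(1, z_piezo[seq_len(nb)]),
                            deflection[seq_len(nb)])
  base <- cbind(1, z_piezo) %*% base_fit$coefficients
  corr <- deflection - as.numeric(base)
  noise <- stats::mad(corr[seq_len(nb)])
  floor_d <- max(mad_mult * noise, .Machine$double.eps)
  above <- which(corr > floor_d)
  above <- above[above > nb / 2]  # ignore spikes inside the baseline window
  if (!length(above)) {
    return(force_curve(0, 0, contact_height = NA_real_, pixel = pixel,
                       flags = "missing"))
  }
  i0 <- max(above[1] - 1L, 1L)
  z0 <- z_piezo[i0]
  defl0 <- deflection[i0]
  idx <- i0:n
  d <- (z_piezo[idx] - z0) - (deflection[idx] - defl0)
  f <- k * (deflection[idx] - defl0)
  d <- pmax(d, 0)
  d[1] <- 0
  d <- cummax(d)  # guard against sub-noise nonmonotonicity
  force_curve(d, f, contact_height = z0, pixel = pixel)
}

#' Truncate a curve to a depth window
#'
#' Keeps only samples with `d <= d_max`. Depth-windowed refits read
#' different structural layers: a shallow window (e.g. 100 nm) probes the
#' cortex, the full depth (e.g. 800 nm) is dominated by the deeper
#' nucleoskeletal response.
#'
#' @param curve a [force_curve()].
#' @param d_max window depth (m), `> 0`.
#' @return a [force_curve()]; if fewer than 4 samples remain it is flagged
#'   `"too_shallow"`.
#' @export
truncate_to_depth <- function(curve, d_max) {
  if (!is.numeric(d_max) || d_max <= 0)
    stop("truncate_to_depth: `d_max` must be > 0", call. = FALSE)
  keep <- which(curve$d <= d_max)
  force_curve(curve$d[keep], curve$f[keep],
              contact_height = curve$contact_height, pixel = curve$pixel,
              flags = setdiff(curve$flags, "too_shallow"))
}

#' Topographic gradient maps
#'
#' Central differences over the pixel pitch in the interior, one-sided at
#' the edges (via [pracma::gradient()]). `gx` is dz/dx (along columns),
#' `gy` is dz/dy (along rows); with the default `scan_axis = "y"` the
#' `gy` map is the gradient along the scan direction, which couples most
#' strongly to scanner/indenter synchronization error.
#'
#' @param img a [spectrum_image()], or a topography matrix if `pitch` given.
#' @param pitch pixel pitch (m) when `img` is a bare matrix.
#' @return list with `ny x nx` matrices `gx` and `gy`.
#' @export
topography_gradients <- function(img, pitch = NULL) {
  if (inherits(img, "spectrum_image")) {
    z <- img$topography; pitch <- img$pixel_pitch
  } else {
    z <- img
    if (is.null(pitch)) stop("topography_gradients: `pitch` required",
                             call. = FALSE)
  }
  g <- pracma::gradient(z, pitch, pitch)
  list(gx = g$X, gy = g$Y)
}
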
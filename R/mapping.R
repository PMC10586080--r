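#' A 2D physical-quantity map
#'
#' A scalar image (prestress, modulus, height, ...) with units, a mask of
#' invalid pixels, and provenance describing how it was produced.
#'
#' @param values `ny x nx` numeric matrix.
#' @param units unit string (SI: `"Pa"`, `"m"`, `"N/m"`).
#' @param mask logical matrix, `TRUE` where the pixel is invalid/masked;
#'   defaults to `!is.finite(values)`.
#' @param provenance named list (model, tip descriptors, depth window,
#'   pixel pitch, source id...).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, units, mask = NULL, provenance = list()) {
  if (!is.matrix(values)) stop("scalar_map: `values` must be a matrix",
                               call. = FALSE)
  if (!is.character(units) || !nzchar(units))
    stop("scalar_map: `units` is required", call. = FALSE)
  if (is.null(mask)) mask <- !is.finite(values)
  if (!identical(dim(mask), dim(values)))
    stop("scalar_map: mask shape must match values", call. = FALSE)
  structure(list(values = values, units = units, mask = mask,
                 provenance = provenance), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("<scalar_map> %d x %d (%s), range [%.4g, %.4g], %d masked\n",
              nrow(x$values), ncol(x$values), x$units,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(x$mask)))
  invisible(x)
}

#' Assemble stress / modulus / topography maps from a map fit
#'
#' The prestress map is signed: tensile stress positive, compressive
#' negative. The topography map is taken from the image's contact heights
#' and is therefore independent of the fitted mechanics -- the standard
#' control that stress contrast is not a topography artifact.
#'
#' @param fit a [fit_map()] result.
#' @param img the source [spectrum_image()].
#' @return named list of [scalar_map()]s: `stress` (HS), `modulus`
#'   (HS/Hertz/Sneddon), `tension` (CSLC), and always `topography`.
#' @export
build_maps <- function(fit, img) {
  prov <- list(model = fit$model, td = unclass(fit$td),
               depth_window = fit$depth_window,
               pixel_pitch = img$pixel_pitch)
  out <- list()
  if (!is.null(fit$grids$sigma))
    out$stress <- scalar_map(fit$grids$sigma, "Pa", provenance = prov)
  if (!is.null(fit$grids$E))
    out$modulus <- scalar_map(fit$grids$E, "Pa", provenance = prov)
  if (!is.null(fit$grids$T))
    out$tension <- scalar_map(fit$grids$T, "N/m", provenance = prov)
  out$topography <- scalar_map(img$topography, "m",
                               mask = matrix(FALSE, img$ny, img$nx),
                               provenance = list(pixel_pitch = img$pixel_pitch))
  out
}

#' Depth-windowed map sets
#'
#' Refits every pixel on truncated curves (`d <= d_max` per window) with a
#' fixed, map-level set of tip descriptors, producing one map set per
#' window. A shallow window (e.g. 100 nm) reads the cortical layer; the
#' full depth (e.g. 800 nm) is dominated by the nucleoskeletal response.
#' Windows are labeled `cortex` (shallowest) and `nucleoskeleton`
#' (deepest) accordingly.
#'
#' @param img a [spectrum_image()].
#' @param td tip descriptors (optimized once on full-depth curves).
#' @param model model id.
#' @param windows ascending numeric vector of window depths `d_max` (m).
#' @param config a [model_config()].
#' @return list (one element per window) of lists with `d_max`, `label`,
#'   `fit` (the [fit_map()] result) and `maps` (from [build_maps()]).
#' @export
depth_windowed_maps <- function(img, td, model, windows,
                                config = model_config(model)) {
  if (length(windows) < 1L)
    stop("depth_windowed_maps: empty window list", call. = FALSE)
  if (is.unsorted(windows, strictly = TRUE))
    stop("depth_windowed_maps: windows must be strictly ascending",
         call. = FALSE)
  grads <- topography_gradients(img)
  cm <- curve_matrix(img, grads)
  lapply(seq_along(windows), function(i) {
    w <- windows[i]
    label <- if (length(windows) == 1L) "full"
      else if (i == 1L) "cortex"
      else if (i == length(windows)) "nucleoskeleton"
      else sprintf("window_%d", i)
    fit <- fit_map(img, model, td, config = config, depth_window = w,
                   cm = cm)
    maps <- build_maps(fit, img)
    for (nm in setdiff(names(maps), "topography"))
      maps[[nm]]$provenance$depth_window_label <- label
    list(d_max = w, label = label, fit = fit, maps = maps)
  })
}

#' Radial profile of a map
#'
#' Mean of the unmasked pixels in equal-width radial bins around a center,
#' as used to quantify circularly shaped cells (height or stress versus
#' distance from the cell center). With `normalize = TRUE` the profile is
#' divided by its maximum absolute value, so the normalized profile has
#' max |value| = 1.
#'
#' @param map a [scalar_map()].
#' @param center pixel coordinates `c(ix, iy)` of the center (may be
#'   fractional).
#' @param r_max maximum radius (m).
#' @param n_bins number of equal-width bins.
#' @param normalize divide by max |value|?
#' @param pitch pixel pitch (m); defaults to the map's provenance.
#' @return An object of class `radial_profile`: data frame `$profile` with
#'   `r_mid` (m), `mean`, `count` (empty bins give `NaN` with count 0),
#'   plus `$center`, `$edges`, `$normalized`.
#' @export
radial_profile <- function(map, center, r_max, n_bins = 24L,
                           normalize = FALSE,
                           pitch = map$provenance$pixel_pitch) {
  if (is.null(pitch))
    stop("radial_profile: pixel pitch unknown; pass `pitch`", call. = FALSE)
  ny <- nrow(map$values); nx <- ncol(map$values)
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny)
    stop("radial_profile: center outside the map", call. = FALSE)
  ixg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  iyg <- matrix(rep(seq_len(ny), nx), ny, nx)
  rr <- pitch * sqrt((ixg - center[1])^2 + (iyg - center[2])^2)
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  bin <- findInterval(rr, edges, rightmost.closed = TRUE)
  usable <- !map$mask & bin >= 1L & bin <= n_bins
  sums <- tapply(map$values[usable], bin[usable], sum)
  cnts <- tapply(map$values[usable], bin[usable], length)
  mean_v <- rep(NaN, n_bins); count <- rep(0L, n_bins)
  idx <- as.integer(names(sums))
  mean_v[idx] <- sums / cnts
  count[idx] <- as.integer(cnts)
  if (normalize) {
    mx <- max(abs(mean_v[count > 0]))
    if (mx > 0) mean_v <- mean_v / mx
  }
  structure(list(profile = data.frame(
    r_mid = 0.5 * (edges[-1] + edges[-length(edges)]),
    mean = mean_v, count = count),
    center = center, edges = edges, normalized = normalize,
    units = map$units), class = "radial_profile")
}

#' Line-scan time series
#'
#' Repeated 1D indentation line scans: per repetition a stress profile and
#' a height profile along the same line.
#'
#' @param times acquisition times (s), strictly increasing.
#' @param stress `nt x nx` matrix (Pa), one row per repetition.
#' @param height `nt x nx` matrix (m).
#' @param pitch point spacing along the line (m).
#' @return An object of class `linescan_series`.
#' @export
linescan_series <- function(times, stress, height, pitch) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0))
    stop("linescan_series: times must be strictly increasing", call. = FALSE)
  if (!is.matrix(stress) || !is.matrix(height) ||
      !identical(dim(stress), dim(height)) || nrow(stress) != length(times))
    stop("linescan_series: stress/height must be nt x nx matrices matching times",
         call. = FALSE)
  structure(list(times = times, stress = stress, height = height,
                 pitch = pitch), class = "linescan_series")
}

#' Time statistics of a line-scan series
#'
#' For each repetition: the mean stress within a central window (default
#' width 5 um) and a height statistic over the same window (the window
#' maximum by default, configurable to the mean).
#'
#' @param series a [linescan_series()].
#' @param window_center window center position along the line (m); default
#'   the middle of the line.
#' @param window_width window width (m), default 5 um.
#' @param height_stat `"max"` or `"mean"`.
#' @return data frame with columns `time` (s), `mean_stress` (Pa),
#'   `height` (m).
#' @export
linescan_stats <- function(series, window_center = NULL,
                           window_width = 5e-6,
                           height_stat = c("max", "mean")) {
  height_stat <- match.arg(height_stat)
  nx <- ncol(series$stress)
  x <- (seq_len(nx) - 1) * series$pitch
  if (is.null(window_center)) window_center <- max(x) / 2
  lo <- window_center - window_width / 2
  hi <- window_center + window_width / 2
  if (lo < 0 || hi > max(x))
    stop("linescan_stats: window extends beyond the scanned line",
         call. = FALSE)
  sel <- x >= lo & x <= hi
  if (!any(sel)) stop("linescan_stats: window contains no points",
                      call. = FALSE)
  hfun <- if (height_stat == "max") function(v) max(v) else function(v) mean(v)
  data.frame(time = series$times,
             mean_stress = rowMeans(series$stress[, sel, drop = FALSE]),
             height = apply(series$height[, sel, drop = FALSE], 1, hfun))
}
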
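# Container I/O. The force-volume container is a directory:
#   meta.json        nx, ny, pixel_pitch_m, spring_constant_N_per_m,
#                    force_threshold_N, scan_axis, missing_pixels,
#                    curve_flags
#   topography.csv   ny x nx contact heights (m), plain CSV, full precision
#   curves/<iy>_<ix>.tsv   two columns d_m, f_N with header, one file per
#                          non-missing pixel (1-based row/column indices)
# All values are strict SI; units are encoded in the field names and never
# guessed on read.

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

#' Write a force-volume container
#'
#' @param img a [spectrum_image()].
#' @param path target directory.
#' @param format container dialect; only `"tsv_dir"` is supported in this
#'   build (`"hdf5"` raises an error).
#' @param overwrite overwrite an existing non-empty container?
#' @return `path`, invisibly.
#' @export
write_force_volume <- function(img, path, format = c("tsv_dir", "hdf5"),
                               overwrite = FALSE) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("write_force_volume: the HDF5 dialect is not supported in this ",
         "build; use format = \"tsv_dir\"", call. = FALSE)
  stopifnot(inherits(img, "spectrum_image"))
  if (dir.exists(path) && length(dir(path)) > 0 && !overwrite)
    stop("write_force_volume: `", path,
         "` exists and is not empty; use overwrite = TRUE", call. = FALSE)
  dir.create(file.path(path, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  missing_px <- character(0)
  curve_flags <- list()
  for (iy in seq_len(img$ny)) {
    for (ix in seq_len(img$nx)) {
      key <- sprintf("%d_%d", iy, ix)
      cv <- curve_at(img, ix, iy)
      if (is.null(cv)) { missing_px <- c(missing_px, key); next }
      con <- file(file.path(path, "curves", paste0(key, ".tsv")), "w")
      writeLines("d_m\tf_N", con)
      writeLines(paste(fmt_full(cv$d), fmt_full(cv$f), sep = "\t"), con)
      close(con)
      if (length(cv$flags)) curve_flags[[key]] <- as.list(cv$flags)
    }
  }
  meta <- list(nx = img$nx, ny = img$ny, pixel_pitch_m = img$pixel_pitch,
               spring_constant_N_per_m = img$spring_constant,
               force_threshold_N = img$force_threshold,
               scan_axis = img$scan_axis,
               missing_pixels = missing_px, curve_flags = curve_flags)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  topo <- apply(img$topography, 1, function(row)
    paste(fmt_full(row), collapse = ","))
  writeLines(topo, file.path(path, "topography.csv"))
  invisible(path)
}

#' Read a force-volume container
#'
#' Validates the layout strictly: a missing metadata field (units are part
#' of the field names) or a topography shape mismatch is an error naming
#' the offending field; pixels listed in `missing_pixels` are kept as
#' explicit `NULL` entries, never silently dropped.
#'
#' @param path container directory.
#' @param format container dialect (`"tsv_dir"` only in this build).
#' @return a [spectrum_image()].
#' @export
read_force_volume <- function(path, format = c("tsv_dir", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("read_force_volume: the HDF5 dialect is not supported in this ",
         "build; use format = \"tsv_dir\"", call. = FALSE)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("read_force_volume: missing meta.json in `", path, "`",
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("nx", "ny", "pixel_pitch_m", "spring_constant_N_per_m",
                "force_threshold_N", "scan_axis")
  for (fld in required) {
    if (is.null(meta[[fld]]))
      stop("read_force_volume: meta.json is missing required field `",
           fld, "`", call. = FALSE)
  }
  topo_path <- file.path(path, "topography.csv")
  if (!file.exists(topo_path))
    stop("read_force_volume: missing topography.csv", call. = FALSE)
  topo <- as.matrix(utils::read.table(topo_path, sep = ",", header = FALSE))
  dimnames(topo) <- NULL
  if (nrow(topo) != meta$ny || ncol(topo) != meta$nx)
    stop(sprintf(
      "read_force_volume: topography shape (%d x %d) does not match meta nx/ny (%d x %d)",
      nrow(topo), ncol(topo), meta$ny, meta$nx), call. = FALSE)
  missing_px <- unlist(meta$missing_pixels)
  curves <- vector("list", meta$nx * meta$ny)
  for (iy in seq_len(meta$ny)) {
    for (ix in seq_len(meta$nx)) {
      key <- sprintf("%d_%d", iy, ix)
      idx <- (iy - 1L) * meta$nx + ix
      if (key %in% missing_px) { curves[idx] <- list(NULL); next }
      fp <- file.path(path, "curves", paste0(key, ".tsv"))
      if (!file.exists(fp))
        stop("read_force_volume: curve file missing for pixel `", key,
             "` and the pixel is not flagged missing", call. = FALSE)
      hdr <- readLines(fp, n = 1L)
      if (!identical(hdr, "d_m\tf_N"))
        stop("read_force_volume: curve `", key,
             "` lacks the required `d_m\tf_N` header", call. = FALSE)
      tab <- utils::read.table(fp, sep = "\t", header = TRUE)
      flags <- unlist(meta$curve_flags[[key]])
      if (is.null(flags)) flags <- character()
      curves[[idx]] <- force_curve(tab$d_m, tab$f_N,
                                   contact_height = topo[iy, ix],
                                   pixel = c(ix, iy), flags = flags)
    }
  }
  spectrum_image(curves, topo, meta$pixel_pitch_m,
                 meta$spring_constant_N_per_m, meta$force_threshold_N,
                 scan_axis = meta$scan_axis)
}

# ---- map export -------------------------------------------------------------

# Minimal single-strip little-endian baseline TIFF with IEEE float32
# samples (SampleFormat = 3). Written by hand because no installed R
# package emits float TIFFs; tiff::readTIFF reads the result and is used
# as the independent check in the tests.
write_float_tiff <- function(values, path) {
  ny <- nrow(values); nx <- ncol(values)
  data <- as.numeric(t(values))
  data[is.na(data)] <- NaN
  nbytes <- 4L * nx * ny
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42L)
  w4(8L + nbytes)                      # IFD follows the pixel data
  writeBin(data, con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  w2(10L)                              # entry count
  entry(256L, 4L, 1L, nx)              # ImageWidth
  entry(257L, 4L, 1L, ny)              # ImageLength
  entry(258L, 3L, 1L, 32L)             # BitsPerSample
  entry(259L, 3L, 1L, 1L)              # Compression: none
  entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)              # StripOffsets
  entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
  entry(278L, 4L, 1L, ny)              # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)          # StripByteCounts
  entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
  w4(0L)                               # no next IFD
  invisible(path)
}

#' Export a scalar map
#'
#' Formats: `"csv"` writes a `# units=<u>` header line followed by the
#' row-major values at full float64 text precision (masked pixels are empty
#' cells); `"tiff32"` writes a 32-bit float TIFF (masked pixels NaN);
#' `"png_preview"` writes a diverging-palette preview with tensile
#' (positive) values in red and compressive (negative) values in green.
#'
#' @param map a [scalar_map()] (units are mandatory).
#' @param path output file.
#' @param format `"csv"`, `"tiff32"` or `"png_preview"`.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path, format = c("csv", "tiff32", "png_preview"),
                       overwrite = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(map, "scalar_map"))
  if (is.null(map$units) || !nzchar(map$units))
    stop("export_map: map units missing", call. = FALSE)
  if (file.exists(path) && !overwrite)
    stop("export_map: `", path, "` exists; use overwrite = TRUE",
         call. = FALSE)
  v <- map$values
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# units=", map$units), con)
    for (iy in seq_len(nrow(v))) {
      row <- fmt_full(v[iy, ])
      row[map$mask[iy, ]] <- ""
      writeLines(paste(row, collapse = ","), con)
    }
  } else if (format == "tiff32") {
    v[map$mask] <- NaN
    write_float_tiff(v, path)
  } else {
    finite <- v[!map$mask & is.finite(v)]
    mx <- if (length(finite)) max(abs(finite)) else 1
    if (mx == 0) mx <- 1
    s <- v / mx
    s[map$mask | !is.finite(s)] <- 0
    rgb <- array(0, dim = c(nrow(v), ncol(v), 3L))
    rgb[, , 1] <- pmin(pmax(s, 0), 1)
    rgb[, , 2] <- pmin(pmax(-s, 0), 1)
    gray <- map$mask
    rgb[, , 1][gray] <- 0.5; rgb[, , 2][gray] <- 0.5; rgb[, , 3][gray] <- 0.5
    png::writePNG(rgb, path)
  }
  invisible(path)
}

#' Re-import a CSV map written by [export_map()]
#'
#' @param path CSV file.
#' @return list with `values` (numeric matrix, `NA` at masked cells) and
#'   `units`.
#' @export
read_map_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# units="))
    stop("read_map_csv: missing `# units=` header", call. = FALSE)
  units <- sub("^# units=", "", first)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                      skip = 1L,
                                      na.strings = c("", "NA")))
  dimnames(vals) <- NULL
  list(values = vals, units = units)
}

#' Write the synthetic ground-truth sidecar
#'
#' JSON (descriptors, layer parameters, noise, seed) plus CSV grids of the
#' true stress and modulus fields, written alongside a simulated container.
#'
#' @param truth the `truth` element of [simulate_spectrum_image()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  head <- truth[c("two_layer", "cortex_thickness", "sync_error", "sync_b",
                  "noise_rms", "seed")]
  head$td <- unclass(truth$td)
  jsonlite::write_json(head, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wr <- function(m, name) writeLines(
    apply(m, 1, function(row) paste(fmt_full(row), collapse = ",")),
    file.path(dir, name))
  wr(truth$sigma1, "sigma_cortex_Pa.csv")
  wr(truth$sigma2, "sigma_deep_Pa.csv")
  wr(truth$E, "modulus_Pa.csv")
  invisible(dir)
}
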
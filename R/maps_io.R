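#' Construct an elemental map
#'
#' An `ElementalMap` holds one element's 2D fluorescence image together with
#' the physical pixel step sizes of the raster scan. The first matrix index is
#' the slow (y) scan axis and the second index is the fast (x) axis; this
#' convention is applied consistently throughout the package.
#'
#' @param values Numeric matrix of fluorescence signal (counts or areal
#'   concentration). Must be at least 4 x 4, all finite.
#' @param dx,dy Pixel step sizes along the fast (x) and slow (y) axes, in
#'   micrometers. Must be positive.
#' @param element Element label, e.g. `"Ca"`.
#' @param dwell_ms Optional per-pixel exposure time in milliseconds (metadata
#'   only; not used in computations).
#' @param source Provenance string: a file path, or `"synthetic"`.
#'
#' @return An object of class `ElementalMap`: a list with fields `values`,
#'   `dx`, `dy`, `element`, `dwell_ms`, `source`.
#' @examples
#' m <- elemental_map(matrix(1:16, 4, 4), dx = 1, dy = 2, element = "Ca")
#' dim(m$values)
#' @export
elemental_map <- function(values, dx, dy, element = "unknown",
                          dwell_ms = NA_real_, source = "memory") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  storage.mode(values) <- "double"
  stop_if_not_scalar_pos(dx, "dx")
  stop_if_not_scalar_pos(dy, "dy")
  if (nrow(values) < 4L || ncol(values) < 4L) {
    stop("map must have at least 4 rows and 4 columns", call. = FALSE)
  }
  bad_row <- apply(values, 1L, function(r) all(!is.finite(r)))
  bad_col <- apply(values, 2L, function(r) all(!is.finite(r)))
  if (any(bad_row) || any(bad_col)) {
    stop("map contains entirely missing rows or columns", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("map contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  }
  structure(
    list(values = values, dx = dx, dy = dy, element = as.character(element),
         dwell_ms = dwell_ms, source = as.character(source)),
    class = "ElementalMap"
  )
}

#' @export
print.ElementalMap <- function(x, ...) {
  cat(sprintf("ElementalMap '%s': %d x %d pixels, dx = %g um, dy = %g um\n",
              x$element, nrow(x$values), ncol(x$values), x$dx, x$dy))
  cat(sprintf("  range [%g, %g], source: %s\n",
              min(x$values), max(x$values), x$source))
  invisible(x)
}

#' Read an elemental map from file
#'
#' Supported formats: single-plane TIFF, delimited text (comma or
#' whitespace separated), and HDF5 (requires the `rhdf5` package). Values are
#' never rescaled or offset on reading.
#'
#' For HDF5, `dataset` names the internal dataset holding either a single 2D
#' plane or a 3D per-element stack (such as written by fluorescence
#' spectrum-fitting pipelines); for a 3D stack the plane is selected by
#' `channel` (integer index) or by matching `element` against the names read
#' from `channel_names_dataset`. No single vendor layout is assumed.
#'
#' @param path File path.
#' @param format One of `"csv"` (delimited text), `"tiff"`, `"hdf5"`. Guessed
#'   from the file extension when omitted.
#' @param element Element label to record (and, for HDF5 stacks, to look up).
#' @param dx,dy Pixel step sizes in micrometers.
#' @param dwell_ms Optional dwell time metadata, ms.
#' @param dataset HDF5 only: internal dataset path.
#' @param channel HDF5 only: 1-based plane index into a 3D stack.
#' @param channel_names_dataset HDF5 only: dataset of channel names used to
#'   resolve `element` into a plane index.
#' @return An [elemental_map()].
#' @export
read_map <- function(path, format = c("auto", "csv", "tiff", "hdf5"),
                     element = "unknown", dx = 1, dy = 1,
                     dwell_ms = NA_real_, dataset = NULL, channel = NULL,
                     channel_names_dataset = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "tiff",
      h5 = , hdf5 = , nxs = "hdf5",
      "csv")
  }
  values <- switch(format,
    csv = read_map_text(path),
    tiff = read_map_tiff(path),
    hdf5 = read_map_hdf5(path, dataset, element, channel, channel_names_dataset)
  )
  elemental_map(values, dx = dx, dy = dy, element = element,
                dwell_ms = dwell_ms, source = normalizePath(path))
}

read_map_text <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character",
                          strip.white = TRUE, blank.lines.skip = TRUE)
  m <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (anyNA(m)) stop("non-numeric value in delimited-text map", call. = FALSE)
  unname(m)
}

read_map_tiff <- function(path) {
  # as.is = TRUE returns raw integer sample values; the reader never rescales
  img <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("TIFF has multiple planes; expected one", call. = FALSE)
    img <- img[, , 1L]
  }
  if (length(dim(img)) != 2L) stop("TIFF data is not 2D", call. = FALSE)
  unname(img)
}

read_map_hdf5 <- function(path, dataset, element, channel, channel_names_dataset) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("HDF5 support requires the 'rhdf5' package", call. = FALSE)
  }
  if (is.null(dataset)) stop("HDF5 input requires 'dataset'", call. = FALSE)
  arr <- tryCatch(rhdf5::h5read(path, dataset),
                  error = function(e) stop(sprintf(
                    "dataset '%s' not found in %s", dataset, path), call. = FALSE))
  nd <- length(dim(arr))
  if (nd == 2L) return(unname(as.matrix(arr)))
  if (nd != 3L) stop("HDF5 dataset is not 2D or 3D", call. = FALSE)
  if (is.null(channel)) {
    if (is.null(channel_names_dataset)) {
      stop("3D HDF5 stack: supply 'channel' or 'channel_names_dataset'",
           call. = FALSE)
    }
    nms <- as.character(rhdf5::h5read(path, channel_names_dataset))
    channel <- match(element, trimws(nms))
    if (is.na(channel)) {
      stop(sprintf("element '%s' not found among channels: %s",
                   element, paste(trimws(nms), collapse = ", ")), call. = FALSE)
    }
  }
  # stack axis is whichever axis matches neither image dimension ordering;
  # convention here: the channel axis is the first axis (channel, y, x)
  if (channel < 1L || channel > dim(arr)[1]) {
    stop("channel index out of range", call. = FALSE)
  }
  unname(as.matrix(arr[channel, , ]))
}

#' Write an elemental map to file
#'
#' TIFF output stores non-negative integer values (photon counts) as 16- or
#' 32-bit integer samples, so counts round-trip bit-exactly; maps with
#' fractional or negative values (e.g. concentration maps or Wiener-filtered
#' output) must use delimited text, which writes full-precision values.
#'
#' @param map An [elemental_map()].
#' @param path Output path.
#' @param format `"csv"` or `"tiff"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("auto", "csv", "tiff")) {
  stopifnot(inherits(map, "ElementalMap"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) "tiff" else "csv"
  }
  if (format == "tiff") {
    v <- map$values
    if (any(v < 0) || any(v != round(v)) || max(v) >= 2^32) {
      stop("TIFF output requires non-negative integer values below 2^32; ",
           "use format = 'csv' for fractional or signed maps", call. = FALSE)
    }
    bits <- if (max(v) < 2^16) 16L else 32L
    tiff::writeTIFF(v / (2^bits - 1), path, bits.per.sample = bits,
                    reduce = FALSE)
  } else {
    utils::write.table(format(map$values, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Write a machine-readable analysis report
#'
#' Serializes one or more resolution fits (and optionally a photometry
#' summary) as JSON with full floating-point precision, suitable for
#' mechanical downstream checks. Re-reading with [read_report()] reproduces
#' the written values exactly.
#'
#' @param fits A single `PowerLawFit` or a list of them (see
#'   [fit_resolution()]).
#' @param path Output path.
#' @param photometry Optional named list, e.g. from [photometry_summary()].
#' @param extra Optional named list of run metadata (seed, config hash, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(fits, path, photometry = NULL, extra = NULL) {
  if (inherits(fits, "PowerLawFit")) fits <- list(fits)
  if (length(fits) < 1L) stop("at least one completed fit is required", call. = FALSE)
  records <- lapply(fits, function(f) {
    stopifnot(inherits(f, "PowerLawFit"))
    list(
      element = f$element,
      sector = list(mode = f$sector$mode, half_angle_deg = f$sector$half_angle),
      P = f$P, a = f$a, S_nf = f$S_nf, SNR_res = f$SNR_res,
      u_knee_per_um = f$u_knee, u_res_per_um = f$u_res,
      delta_res_um = f$delta_res,
      ranges = list(signal_lo = f$ranges$signal_lo,
                    signal_hi = f$ranges$signal_hi,
                    noise_lo = f$ranges$noise_lo,
                    noise_hi = f$ranges$noise_hi),
      valid = f$valid, out_of_band = f$out_of_band
    )
  })
  report <- list(schema_version = "1.0",
                 tool = "xrfres",
                 tool_version = as.character(utils::packageVersion("xrfres")),
                 records = records)
  if (!is.null(photometry)) report$photometry <- photometry
  if (!is.null(extra)) report$run <- extra
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write report to %s", path), call. = FALSE))
  on.exit(close(con))
  # I(17) significant digits: doubles round-trip exactly through the report
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"), con)
  invisible(path)
}

#' Read back an analysis report written by [write_report()]
#'
#' @param path Report path.
#' @return Nested list mirroring the written structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
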
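#' Read a hyperspectral cube from TIFF
#'
#' Reads a multi-page TIFF into the package's `(t, z, c, y, x)` convention.
#' If a JSON sidecar (`<path>.json`, written by [write_cube()]) is present
#' its recorded dimensions and spectral axis are used; otherwise
#' `axis_order_hint` must say how the pages are laid out. Missing `t`/`z`
#' axes become size 1.
#'
#' @param path TIFF file path.
#' @param axis_order_hint Axis order of the stored data, e.g. `"cyx"`,
#'   `"zcyx"` or `"tzcyx"`; page order is the product of the leading
#'   (non-`yx`) axes, slowest first. Ignored when a sidecar exists.
#' @param axis A [spectral_axis()] used when no sidecar specifies one.
#' @param lib Optional [spectral_library()] to validate the channel count
#'   against.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, axis_order_hint = NULL, axis = spectral_axis(),
                      lib = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dims <- as.integer(meta$dims)               # (t, z, c, y, x)
    axis <- spectral_axis(meta$axis$n_channels, meta$axis$start_nm,
                          meta$axis$step_nm)
    scale <- meta$scale %||% 1
    integer_data <- isTRUE(meta$integer_data)
  } else {
    if (is.null(axis_order_hint)) stop("axis order required")
    hint <- tolower(axis_order_hint)
    if (!grepl("c", hint) || !grepl("yx$", hint))
      stop("axis order required: hint must contain 'c' and end in 'yx'")
    lead <- strsplit(sub("yx$", "", hint), "")[[1]]
    sizes <- c(t = 1L, z = 1L, c = 1L)
    n_pages <- length(pages)
    if (length(lead) == 1L) {
      sizes[lead] <- n_pages
    } else stop("axis order required: pass page counts via a sidecar for ",
                "multi-axis stacks")
    dims <- c(sizes[["t"]], sizes[["z"]], sizes[["c"]], ny, nx)
    scale <- 1
    integer_data <- FALSE
  }
  if (prod(dims[1:3]) != length(pages))
    stop("axis mismatch: ", length(pages), " pages but dims imply ",
         prod(dims[1:3]))
  # pages stored slowest-first (t, z, c); rebuild the 5-D array
  arr <- array(0, dims)
  p <- 1L
  for (t in seq_len(dims[1])) for (z in seq_len(dims[2]))
    for (ch in seq_len(dims[3])) {
      arr[t, z, ch, , ] <- pages[[p]] * scale
      p <- p + 1L
    }
  # stored as float32 fractions of the scale; rounding restores integer DL
  if (integer_data) arr <- round(arr)
  if (dims[3] != axis$n_channels)
    axis <- spectral_axis(dims[3], axis$start_nm, axis$step_nm)
  cube <- hyper_cube(arr, axis, metadata = list(source = path))
  if (!is.null(lib)) validate_cube(cube, lib)
  cube
}

#' Write a hyperspectral cube (or any 5-D result) to TIFF with a sidecar
#'
#' Pages are written slowest-first over `(t, z, c)`. Values are stored as
#' 32-bit floats scaled into `[0, 1]`; the scale factor and the full axis
#' description go into a JSON sidecar at `<path>.json`, making the
#' round-trip lossless for integer DL data.
#'
#' @param cube A [hyper_cube()], or a bare 5-D array plus `axis`.
#' @param path Output TIFF path.
#' @param axis Spectral axis when `cube` is a bare array.
#' @param extra Extra named fields merged into the sidecar (seeds, configs).
#' @return Invisibly, `path`.
#' @export
write_cube <- function(cube, path, axis = spectral_axis(), extra = list()) {
  if (inherits(cube, "hyper_cube")) {
    arr <- cube$data; axis <- cube$axis
  } else arr <- cube
  d <- dim(arr)
  mx <- max(arr)
  scale <- if (mx > 0) mx else 1
  pages <- list()
  p <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    pg <- arr[t, z, ch, , ]
    dim(pg) <- d[4:5]
    pages[[p]] <- pg / scale
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- c(list(format_version = 1L, dims = d, scale = scale,
                    integer_data = all(arr == round(arr)),
                    axis = list(n_channels = axis$n_channels,
                                start_nm = axis$start_nm,
                                step_nm = axis$step_nm)),
               extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectral library from CSV
#'
#' Expects a wavelength column (named `wavelength`, `lambda` or `nm`, or
#' the first column) plus one column per end-member. Wavelengths are
#' snapped to the nearest channel of the target axis; rows must be
#' monotone increasing in wavelength. Off-axis wavelengths (within half a
#' channel) are flagged in the result's metadata rather than rejected.
#'
#' @param path CSV path.
#' @param axis Target [spectral_axis()].
#' @return A normalized [spectral_library()].
#' @export
read_library <- function(path, axis = spectral_axis()) {
  # read.csv silently mangles duplicated header names; check the raw header
  hdr <- strsplit(gsub('"', "", readLines(path, n = 1L)), ",")[[1]]
  if (anyDuplicated(hdr)) stop("duplicate end-member names")
  df <- utils::read.csv(path, check.names = FALSE)
  wl_col <- intersect(c("wavelength", "lambda", "nm"), tolower(names(df)))
  wi <- if (length(wl_col)) match(wl_col[1], tolower(names(df))) else 1L
  wl <- df[[wi]]
  if (is.unsorted(wl, strictly = TRUE)) stop("non-monotone wavelengths")
  vals <- df[, -wi, drop = FALSE]
  if (any(vapply(vals, function(v) all(!is.finite(v)) || sum(v, na.rm = TRUE) == 0,
                 logical(1))))
    stop("empty end-member column")
  ch <- vapply(wl, function(w) which.min(abs(axis$centers - w)), integer(1))
  if (anyDuplicated(ch)) stop("axis mismatch: wavelengths collapse onto the same channel")
  resampled <- any(abs(wl - axis$centers[ch]) > 1e-9)
  sp <- matrix(0, ncol(vals), axis$n_channels)
  for (k in seq_len(ncol(vals))) sp[k, ch] <- vals[[k]]
  lib <- spectral_library(sp, names(vals), axis)
  lib <- normalize_library(lib)
  if (resampled) lib$resampled <- TRUE
  lib
}

#' Write a spectral library to CSV
#'
#' @param lib A [spectral_library()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(lib, path) {
  df <- data.frame(wavelength = lib$axis$centers, t(lib$spectra),
                   check.names = FALSE)
  names(df)[-1] <- lib$names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
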
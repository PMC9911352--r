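#' Spectral detection axis
#'
#' Describes the spectral channel layout of a hyperspectral detector: the
#' number of channels, the wavelength of the first channel centre and the
#' channel width. The default reproduces a 32-channel confocal spectral
#' detector covering 410.5--694.9 nm at 8.9 nm binning.
#'
#' @param n_channels Integer number of spectral channels (>= 2).
#' @param start_nm Wavelength of the first channel centre, in nm.
#' @param step_nm Channel width, in nm (> 0).
#' @return An object of class `spectral_axis` with fields `n_channels`,
#'   `start_nm`, `step_nm` and `centers` (channel-centre wavelengths, nm).
#' @examples
#' ax <- spectral_axis()
#' ax$n_channels   # 32
#' range(ax$centers)
#' @export
spectral_axis <- function(n_channels = 32L, start_nm = 410.5, step_nm = 8.9) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L)
    stop("spectral axis needs at least 2 channels")
  if (!is.finite(step_nm) || step_nm <= 0)
    stop("step_nm must be positive")
  centers <- start_nm + (seq_len(n_channels) - 0.5) * step_nm
  structure(
    list(n_channels = n_channels, start_nm = start_nm, step_nm = step_nm,
         centers = centers),
    class = "spectral_axis"
  )
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d channels, %.1f-%.1f nm (step %.1f nm)\n",
              x$n_channels, x$centers[1] - x$step_nm / 2,
              x$centers[x$n_channels] + x$step_nm / 2, x$step_nm))
  invisible(x)
}

#' Hyperspectral image cube
#'
#' Wraps a 5-D nonnegative intensity array with axis order `(t, z, c, y, x)`
#' -- time, depth, spectral channel, row, column -- in detector digital
#' levels (DL). Arrays of lower dimensionality are promoted by adding
#' leading size-1 `t`/`z` axes when `dim_hint` says how.
#'
#' @param data Numeric array. Either already 5-D `(t, z, c, y, x)` or 3-D
#'   `(c, y, x)` / 4-D `(z, c, y, x)`, which are promoted.
#' @param axis A [spectral_axis()]; its channel count must match `dim(data)[3]`
#'   after promotion.
#' @param metadata Optional named list of provenance information.
#' @return An object of class `hyper_cube` with fields `data`, `axis`,
#'   `metadata`.
#' @export
hyper_cube <- function(data, axis = spectral_axis(), metadata = list()) {
  nd <- length(dim(data))
  if (nd == 3L) dim(data) <- c(1L, 1L, dim(data))
  else if (nd == 4L) dim(data) <- c(1L, dim(data))
  else if (nd != 5L) stop("cube data must be 3-, 4- or 5-dimensional")
  if (anyNA(data) || !all(is.finite(data)))
    stop("cube contains missing or non-finite intensities")
  if (any(data < 0)) stop("negative intensity")
  if (dim(data)[3] != axis$n_channels)
    stop("axis mismatch: cube has ", dim(data)[3], " channels, axis has ",
         axis$n_channels)
  structure(list(data = data, axis = axis, metadata = metadata),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> t=%d z=%d c=%d y=%d x=%d; total DL %.4g\n",
              d[1], d[2], d[3], d[4], d[5], sum(x$data)))
  invisible(x)
}

#' Reference spectral library of end-members
#'
#' Holds one reference emission spectrum (end-member) per fluorophore or
#' autofluorescent species, all on a shared spectral axis. Linear unmixing
#' expresses each measured spectrum as a nonnegative combination of these
#' rows.
#'
#' @param spectra Numeric `i x c` matrix, one nonnegative row per end-member.
#' @param names Character vector of `i` end-member labels.
#' @param axis A [spectral_axis()] with `n_channels == ncol(spectra)`.
#' @param normalized Logical; `TRUE` when every row sums to 1.
#' @return An object of class `spectral_library`.
#' @seealso [normalize_library()]
#' @export
spectral_library <- function(spectra, names = NULL, axis = spectral_axis(),
                             normalized = FALSE) {
  spectra <- as.matrix(spectra)
  i <- nrow(spectra)
  if (is.null(names)) names <- paste0("em", seq_len(i))
  if (anyDuplicated(names)) stop("duplicate end-member names")
  if (length(names) != i) stop("names length must match number of spectra")
  if (ncol(spectra) != axis$n_channels)
    stop("axis mismatch: spectra have ", ncol(spectra), " channels")
  if (i < 1L || i > axis$n_channels)
    stop("underdetermined system: number of end-members (", i,
         ") may not exceed the number of channels (", axis$n_channels, ")")
  if (any(!is.finite(spectra)) || any(spectra < 0))
    stop("library spectra must be finite and nonnegative")
  if (any(rowSums(spectra) == 0)) stop("degenerate end-member: all-zero row")
  rn <- spectra / rowSums(spectra)
  if (i > 1L && any(duplicated(round(rn, 12L))))
    stop("degenerate end-member: identical spectra after normalization")
  rownames(spectra) <- names
  structure(list(names = names, spectra = spectra, axis = axis,
                 normalized = isTRUE(normalized)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d end-members x %d channels%s: %s\n",
              nrow(x$spectra), ncol(x$spectra),
              if (x$normalized) " (normalized)" else "",
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Normalize a spectral library so every row sums to one
#'
#' Unmixing assumes end-member spectra on a comparable scale; a library whose
#' rows each sum to 1 makes the recovered ratios directly interpretable as
#' fractions of the per-pixel intensity integral. Idempotent.
#'
#' @param lib A [spectral_library()].
#' @return The library with every row scaled to unit sum and
#'   `normalized = TRUE`.
#' @examples
#' lib <- spectral_library(rbind(c(2, 2, rep(0, 30)), c(0, 1, 1, rep(0, 29))))
#' normalize_library(lib)$spectra[1, 1:3]
#' @export
normalize_library <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  rs <- rowSums(lib$spectra)
  if (any(rs == 0)) stop("degenerate end-member: all-zero row")
  lib$spectra <- lib$spectra / rs
  lib$normalized <- TRUE
  lib
}

#' Validate a cube/library pair for unmixing
#'
#' Checks that the cube and library share a channel axis, that the cube holds
#' only nonnegative finite intensities, and that the system is not
#' underdetermined (no more end-members than channels). Returns the pair
#' unchanged so the call can be chained.
#'
#' @param cube A [hyper_cube()].
#' @param lib A [spectral_library()].
#' @return Invisibly, `list(cube = cube, lib = lib)`.
#' @export
validate_cube <- function(cube, lib) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(lib, "spectral_library"))
  if (dim(cube$data)[3] != lib$axis$n_channels ||
      ncol(lib$spectra) != dim(cube$data)[3])
    stop("axis mismatch: cube and library disagree on channel count")
  if (nrow(lib$spectra) > dim(cube$data)[3])
    stop("underdetermined system")
  if (any(cube$data < 0)) stop("negative intensity")
  invisible(list(cube = cube, lib = lib))
}

#' Detector noise configuration
#'
#' Parameters of the detection model that converts emitted photons into
#' digital levels: analog gain, additive Gaussian read noise, saturation
#' bit depth, and laser lines blocked by the dichroic mirror.
#'
#' @param gain_dl_per_photon Analog conversion factor, DL per photon (> 0).
#' @param read_noise_sd Gaussian read-noise standard deviation, DL (>= 0).
#' @param bit_depth Saturation exponent; intensities clip at `2^bit_depth - 1`.
#' @param dichroic_lines_nm Numeric vector of laser wavelengths (nm) whose
#'   containing channels are masked out by the dichroic mirror.
#' @param poisson Logical; draw Poisson photon noise (`FALSE` gives the
#'   noiseless expected photon field, used for ground-truth runs).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(gain_dl_per_photon = 30, read_noise_sd = 5,
                         bit_depth = 16L, dichroic_lines_nm = numeric(0),
                         poisson = TRUE) {
  if (!is.finite(gain_dl_per_photon) || gain_dl_per_photon <= 0)
    stop("gain must be positive")
  if (!is.finite(read_noise_sd) || read_noise_sd < 0)
    stop("read noise SD must be nonnegative")
  structure(list(gain_dl_per_photon = gain_dl_per_photon,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 dichroic_lines_nm = dichroic_lines_nm,
                 poisson = isTRUE(poisson)),
            class = "noise_config")
}

# internal: per-pixel spectral intensity integral, shape (t, z, y, x)
cube_totals <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(1, 2, 4, 5, 3)), ncol = d[3])
  tot <- rowSums(m)
  array(tot, dim = d[-3])
}

# internal: cube as pixels-by-channels matrix, pixel order = (t,z,y,x) in
# column-major flattening of the (t,z,y,x) array
cube_pixel_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(aperm(cube$data, c(1, 2, 4, 5, 3)), ncol = d[3])
}

# internal: rebuild a (t,z,i,y,x) array from a pixels-by-i matrix in the
# same pixel order cube_pixel_matrix uses
pixel_matrix_to_cube <- function(m, dims_tzyx) {
  i <- ncol(m)
  arr <- array(m, dim = c(dims_tzyx, i))      # (t,z,y,x,i)
  aperm(arr, c(1, 2, 5, 3, 4))                # (t,z,i,y,x)
}
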
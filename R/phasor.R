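#' Spectral phasor transform
#'
#' Maps each pixel's normalized emission spectrum to a point `(G, S)` in the
#' phasor plane: the real and imaginary parts of one Fourier harmonic of the
#' spectrum,
#' \deqn{G(n) = \frac{\sum_j I_j \cos(n\omega j)}{\sum_j I_j}, \quad
#'       S(n) = \frac{\sum_j I_j \sin(n\omega j)}{\sum_j I_j}, \quad
#'       \omega = 2\pi/c,}
#' with `j = 1..c` the channel index. Similar spectra land at nearby phasor
#' positions; a mixture of two spectra lies on the segment joining their
#' phasors, weighted by total intensity. A uniform spectrum maps exactly to
#' the origin under the 1-based channel-index convention used here.
#'
#' @param cube A [hyper_cube()].
#' @param harmonic Integer Fourier harmonic `n >= 1`. Convention in this
#'   package: harmonic 2 for labelled fluorophores, harmonic 1 for broad
#'   autofluorescent signals.
#' @param intensity_threshold Pixels whose spectral integral is `<=` this
#'   value (DL) are flagged invalid and carry `(G, S) = (0, 0)`.
#' @return An object of class `phasor_field` with per-pixel arrays `G`, `S`,
#'   `total` (all shaped `(t, z, y, x)`), the `harmonic`, and a logical
#'   `valid_mask`.
#' @examples
#' lib <- default_library()
#' cube <- hyper_cube(array(rep(lib$spectra[1, ], each = 16), c(32, 4, 4)))
#' pf <- phasor_transform(cube, harmonic = 2)
#' range(pf$G)  # identical spectra, identical phasor position
#' @export
phasor_transform <- function(cube, harmonic = 2L, intensity_threshold = 0) {
  stopifnot(inherits(cube, "hyper_cube"), harmonic >= 1)
  d <- dim(cube$data)
  cc <- d[3]
  w <- 2 * pi / cc
  j <- seq_len(cc)
  cosw <- cos(harmonic * w * j)
  sinw <- sin(harmonic * w * j)
  m <- cube_pixel_matrix(cube)                 # n_pixels x c
  tot <- rowSums(m)
  g <- as.vector(m %*% cosw)
  s <- as.vector(m %*% sinw)
  valid <- tot > intensity_threshold
  g <- ifelse(valid, g / ifelse(tot > 0, tot, 1), 0)
  s <- ifelse(valid, s / ifelse(tot > 0, tot, 1), 0)
  if (!any(valid)) warning("empty phasor: all pixels at or below threshold")
  dims <- d[-3]
  structure(list(G = array(g, dims), S = array(s, dims),
                 total = array(tot, dims), harmonic = as.integer(harmonic),
                 valid_mask = array(valid, dims),
                 threshold = intensity_threshold),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field> harmonic %d, %d/%d valid pixels\n",
              x$harmonic, sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

# median of three vectors, elementwise, exact
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

# shift a y-by-x matrix by (dy, dx) with nearest-neighbour edge replication
shift_nn <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[pmin(pmax(seq_len(ny) + dy, 1L), ny), pmin(pmax(seq_len(nx) + dx, 1L), nx),
    drop = FALSE]
}

# vectorised 3x3 median filter on a matrix (nearest-neighbour padding):
# sort the three values in each row of the window, then take the median of
# the column maxima/medians/minima -- an exact median-of-9 identity
median3x3 <- function(m) {
  lo <- vector("list", 3); mi <- vector("list", 3); hi <- vector("list", 3)
  for (r in 1:3) {
    a <- shift_nn(m, r - 2L, -1L)
    b <- shift_nn(m, r - 2L, 0L)
    c <- shift_nn(m, r - 2L, 1L)
    lo[[r]] <- pmin(a, b, c)
    hi[[r]] <- pmax(a, b, c)
    mi[[r]] <- med3(a, b, c)
  }
  med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
       med3(mi[[1]], mi[[2]], mi[[3]]),
       pmin(hi[[1]], hi[[2]], hi[[3]]))
}

#' Phasor-plane median denoising
#'
#' Applies `passes` successive 3x3 spatial median filters to the per-pixel
#' `G` and `S` maps of each `(t, z)` plane. Median filtering in phasor space
#' suppresses Poisson and instrumental noise in the spectral coordinates
#' while leaving the intensity data untouched, so image resolution is not
#' degraded. Edges use nearest-neighbour padding; pixels flagged invalid are
#' restored to `(0, 0)` after filtering; `passes = 0` is the identity.
#'
#' @param field A [phasor_transform()] result.
#' @param passes Integer number of median-filter passes, typically 0--5.
#' @return The filtered `phasor_field`.
#' @export
denoise_phasor <- function(field, passes = 1L) {
  stopifnot(inherits(field, "phasor_field"), passes >= 0)
  if (passes == 0) return(field)
  d <- dim(field$G)
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    g <- field$G[t, z, , ]; s <- field$S[t, z, , ]
    dim(g) <- d[3:4]; dim(s) <- d[3:4]
    for (p in seq_len(passes)) {
      g <- median3x3(g)
      s <- median3x3(s)
    }
    field$G[t, z, , ] <- g
    field$S[t, z, , ] <- s
  }
  field$G[!field$valid_mask] <- 0
  field$S[!field$valid_mask] <- 0
  field
}

#' Phasor encoding: bin pixels on the 2-D phasor histogram
#'
#' Assigns every valid pixel to a square bin of the `(G, S)` histogram, so
#' that pixels with similar spectra share a bin. This encoding is what lets
#' hybrid unmixing solve once per occupied bin instead of once per pixel.
#' Bins are half-open `[lo, hi)` with the top edge closed at the extent
#' maximum; out-of-extent coordinates are clamped to the edge bins.
#'
#' @param field A [phasor_transform()] (optionally denoised) result.
#' @param n_bins Histogram bins per axis (default 256).
#' @param extent Numeric length-2 range covered by each axis, default
#'   `c(-1, 1)`.
#' @return An object of class `phasor_encoding` with `bin_index` (flat bin id
#'   per pixel, `NA` for invalid pixels), `counts` (`n_bins x n_bins`
#'   occupancy matrix), `n_bins`, `extent`, and an empty `bin_mean_spectrum`
#'   slot to be filled by [average_spectra_by_bin()].
#' @export
phasor_encode <- function(field, n_bins = 256L, extent = c(-1, 1)) {
  stopifnot(inherits(field, "phasor_field"), n_bins >= 2)
  n_bins <- as.integer(n_bins)
  lo <- extent[1]; width <- extent[2] - extent[1]
  ix <- function(v) pmin(pmax(floor((v - lo) / width * n_bins) + 1L, 1L), n_bins)
  bg <- ix(as.vector(field$G))
  bs <- ix(as.vector(field$S))
  flat <- (bs - 1L) * n_bins + bg
  flat[!as.vector(field$valid_mask)] <- NA_integer_
  counts <- matrix(tabulate(flat, nbins = n_bins * n_bins), n_bins, n_bins)
  structure(list(n_bins = n_bins, extent = extent, bin_index = flat,
                 counts = counts, bin_mean_spectrum = NULL,
                 field_dims = dim(field$G)),
            class = "phasor_encoding")
}

#' @export
print.phasor_encoding <- function(x, ...) {
  cat(sprintf("<phasor_encoding> %dx%d bins, %d occupied, %d pixels encoded\n",
              x$n_bins, x$n_bins, sum(x$counts > 0), sum(x$counts)))
  invisible(x)
}

#' Average pixel spectra within each phasor bin
#'
#' For each occupied bin, computes the mean spectrum of its member pixels.
#' Summing similar spectra averages out photon noise, producing cleaner
#' spectra than any single low-photon pixel provides -- the core denoising
#' step of hybrid unmixing. Averaging is conservative: the count-weighted
#' sum of bin means equals the total spectral sum of all encoded pixels.
#'
#' @param cube The [hyper_cube()] the encoding was derived from.
#' @param enc A [phasor_encode()] result.
#' @return The encoding with `bin_mean_spectrum` filled: a matrix with one
#'   row per occupied bin (rownames = flat bin id) and `c` columns, plus
#'   `bin_count` giving each occupied bin's pixel count.
#' @export
average_spectra_by_bin <- function(cube, enc) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(enc, "phasor_encoding"))
  if (!identical(dim(cube$data)[-3], enc$field_dims))
    stop("axis mismatch: encoding was derived from a cube of different shape")
  m <- cube_pixel_matrix(cube)
  keep <- !is.na(enc$bin_index)
  sums <- rowsum(m[keep, , drop = FALSE], enc$bin_index[keep])
  cnt <- as.vector(rowsum(rep(1, sum(keep)), enc$bin_index[keep]))
  enc$bin_mean_spectrum <- sums / cnt
  enc$bin_count <- cnt
  enc
}

#' Export a phasor histogram and bin spectra
#'
#' Writes the occupancy histogram as a single-channel float TIFF and, when
#' bin-average spectra are present, a CSV with one row per occupied bin
#' (bin coordinates plus one column per spectral channel).
#'
#' @param enc A [phasor_encoding()].
#' @param histogram_path TIFF output path, or `NULL` to skip.
#' @param spectra_path CSV output path, or `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
export_phasor <- function(enc, histogram_path = NULL, spectra_path = NULL) {
  written <- character(0)
  if (!is.null(histogram_path)) {
    img <- enc$counts / max(1, max(enc$counts))
    tiff::writeTIFF(img, histogram_path, bits.per.sample = 32L,
                    reduce = TRUE)
    written <- c(written, histogram_path)
  }
  if (!is.null(spectra_path)) {
    if (is.null(enc$bin_mean_spectrum))
      stop("bin spectra not computed; run average_spectra_by_bin() first")
    flat <- as.integer(rownames(enc$bin_mean_spectrum))
    bg <- (flat - 1L) %% enc$n_bins + 1L
    bs <- (flat - 1L) %/% enc$n_bins + 1L
    df <- data.frame(bin_g = bg, bin_s = bs, count = enc$bin_count,
                     enc$bin_mean_spectrum)
    names(df)[-(1:3)] <- paste0("ch", seq_len(ncol(enc$bin_mean_spectrum)))
    utils::write.csv(df, spectra_path, row.names = FALSE)
    written <- c(written, spectra_path)
  }
  invisible(written)
}
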
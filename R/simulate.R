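#' Discretized Gaussian emission spectrum
#'
#' Builds a normalized reference spectrum by integrating a Gaussian emission
#' profile over each spectral channel band. Used to construct synthetic
#' end-member libraries with realistic overlap.
#'
#' @param peak_nm Emission peak wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm, > 0).
#' @param axis A [spectral_axis()].
#' @return Numeric length-`c` vector summing to 1.
#' @export
gaussian_spectrum <- function(peak_nm, fwhm_nm, axis = spectral_axis()) {
  if (!is.finite(fwhm_nm) || fwhm_nm <= 0) stop("fwhm must be positive")
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  lo <- axis$centers - axis$step_nm / 2
  hi <- axis$centers + axis$step_nm / 2
  mass <- stats::pnorm(hi, peak_nm, sigma) - stats::pnorm(lo, peak_nm, sigma)
  if (sum(mass) <= 0) stop("peak lies entirely outside the detection range")
  mass / sum(mass)
}

#' Default synthetic four-fluorophore library
#'
#' Four spectrally overlapping Gaussian end-members emulating the emission
#' peaks of citrine (~529 nm), mKO2 (~565 nm), tdTomato (~581 nm) and
#' mRuby (~600 nm), plus an optional broad autofluorescence-like component
#' centred near 480 nm. The heavy overlap of the red/orange trio is what
#' makes this library a demanding unmixing test.
#'
#' @param n_endmembers Number of end-members, 2--8. The first four are the
#'   fluorophore-like peaks; 5 adds the autofluorescence-like spectrum;
#'   beyond 5, additional evenly spaced Gaussians are appended.
#' @param axis A [spectral_axis()].
#' @return A normalized [spectral_library()].
#' @export
default_library <- function(n_endmembers = 4L, axis = spectral_axis()) {
  peaks <- c(529, 565, 581, 600, 480)
  fwhms <- c(40, 45, 55, 50, 110)
  nms <- c("citrine", "mKO2", "tdTomato", "mRuby", "autofluor")
  if (n_endmembers > 5L) {
    extra <- seq(440, 670, length.out = n_endmembers - 5L)
    peaks <- c(peaks, extra)
    fwhms <- c(fwhms, rep(45, length(extra)))
    nms <- c(nms, paste0("extra", seq_along(extra)))
  }
  k <- seq_len(n_endmembers)
  sp <- t(vapply(k, function(j) gaussian_spectrum(peaks[j], fwhms[j], axis),
                 numeric(axis$n_channels)))
  spectral_library(sp, nms[k], axis, normalized = TRUE)
}

#' Dichroic transmission mask
#'
#' Per-channel transmission factor emulating a narrow dichroic mirror:
#' transmission 0 in each channel whose band contains one of the listed
#' laser lines, 1 elsewhere. Lines outside the detection range leave the
#' mask untouched.
#'
#' @param lines_nm Numeric vector of laser wavelengths (nm).
#' @param axis A [spectral_axis()].
#' @return Numeric length-`c` vector in `[0, 1]`.
#' @examples
#' which(detection_mask(488, spectral_axis()) == 0)
#' @export
detection_mask <- function(lines_nm = numeric(0), axis = spectral_axis()) {
  m <- rep(1, axis$n_channels)
  lo <- axis$centers - axis$step_nm / 2
  hi <- axis$centers + axis$step_nm / 2
  for (ln in lines_nm) m[ln >= lo & ln < hi] <- 0
  m
}

new_ground_truth <- function(true_ratios, true_photons, lib, gain) {
  structure(list(true_ratios = true_ratios, true_photons = true_photons,
                 library = lib, true_total_dl = gain * true_photons),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$true_ratios)
  cat(sprintf("<ground_truth> t=%d z=%d i=%d y=%d x=%d; mean photons %.3g\n",
              d[1], d[2], d[3], d[4], d[5], mean(x$true_photons)))
  invisible(x)
}

#' Render stochastic photon emission
#'
#' Draws per-pixel, per-channel photon counts as independent Poisson
#' variates whose means follow the pixel's mixed reference spectrum scaled
#' by its photon budget, after applying the dichroic transmission mask
#' (spectral profile renormalized over unmasked channels so the budget is
#' spent on detectable photons). Reducing the photon budget emulates
#' photon starvation.
#'
#' @param truth A `ground_truth` object (ratios + per-pixel photon budgets).
#' @param mask Per-channel transmission from [detection_mask()].
#' @param poisson If `FALSE`, return the noiseless expected photon field
#'   instead of Poisson draws.
#' @return Array `(t, z, c, y, x)` of photon counts (integers when
#'   `poisson = TRUE`).
#' @export
render_photons <- function(truth, mask = NULL, poisson = TRUE) {
  lib <- normalize_library(truth$library)
  d <- dim(truth$true_ratios)
  i <- d[3]
  cc <- ncol(lib$spectra)
  if (is.null(mask)) mask <- rep(1, cc)
  Rm <- matrix(aperm(truth$true_ratios, c(1, 2, 4, 5, 3)), ncol = i)
  spec <- Rm %*% lib$spectra                       # n_px x c, rows sum to 1
  spec <- spec * rep(mask, each = nrow(spec))
  rs <- rowSums(spec)
  pos <- rs > 0
  spec[pos, ] <- spec[pos, , drop = FALSE] / rs[pos]
  lam <- spec * as.vector(truth$true_photons)
  counts <- if (poisson) {
    matrix(stats::rpois(length(lam), as.vector(lam)), nrow = nrow(lam))
  } else lam
  aperm(array(counts, c(d[-3], cc)), c(1, 2, 5, 3, 4))
}

#' Apply detector noise and digitization
#'
#' Converts a photon-count array to detector digital levels:
#' `DL = clip(round(gain * photons + N(0, read_sd)), 0, 2^bit_depth - 1)`.
#' In the fully noiseless mode (`poisson = FALSE`, `read_noise_sd = 0`) the
#' continuous expected DL is returned without digitization, so noiseless
#' simulations are exactly representable by the library.
#'
#' @param photons Array `(t, z, c, y, x)` of photon counts.
#' @param cfg A [noise_config()].
#' @param axis A [spectral_axis()].
#' @return A [hyper_cube()] in DL.
#' @export
apply_detection_noise <- function(photons, cfg = noise_config(),
                                  axis = spectral_axis()) {
  dl <- cfg$gain_dl_per_photon * photons
  if (cfg$read_noise_sd > 0)
    dl <- dl + stats::rnorm(length(dl), 0, cfg$read_noise_sd)
  # digitize only when a stochastic detection path is active: the fully
  # noiseless mode (no Poisson, no read noise) keeps continuous expected DL
  if (cfg$poisson || cfg$read_noise_sd > 0) dl <- round(dl)
  dl <- pmin(pmax(dl, 0), 2^cfg$bit_depth - 1)
  dim(dl) <- dim(photons)
  hyper_cube(dl, axis, metadata = list(noise = unclass(cfg)))
}

#' Overlap-matrix simulation design
#'
#' Configuration for the spatially-random, spectrally-overlapping design:
#' a given percentage of pixels carry a randomized mixture of all `n`
#' end-members (ratios uniform on the simplex) while the remaining pixels
#' are pure, with the end-member chosen uniformly.
#'
#' @param n_endmembers Number of end-members, 2--8.
#' @param overlap_pct Percentage of mixed pixels, 0--100 in steps of 10.
#' @param image_size Pixels per side of the square frame.
#' @param photons_per_spectrum Expected emitted photons per pixel spectrum.
#' @param seed RNG seed.
#' @return An object of class `overlap_design`.
#' @export
overlap_design <- function(n_endmembers = 4L, overlap_pct = 50,
                           image_size = 1024L, photons_per_spectrum = 64,
                           seed = 1L) {
  if (!overlap_pct %in% seq(0, 100, 10))
    stop("overlap_pct must be one of 0, 10, ..., 100")
  if (n_endmembers < 2L || n_endmembers > 8L)
    stop("n_endmembers must be between 2 and 8")
  structure(list(n_endmembers = as.integer(n_endmembers),
                 overlap_pct = overlap_pct,
                 image_size = as.integer(image_size),
                 photons_per_spectrum = photons_per_spectrum,
                 seed = as.integer(seed)),
            class = "overlap_design")
}

# uniform (flat Dirichlet) simplex sample, n rows x k columns
runif_simplex <- function(n, k) {
  e <- matrix(stats::rexp(n * k), n, k)
  e / rowSums(e)
}

#' Simulate the spatially/spectrally overlapping design
#'
#' Generates a square single-frame cube in which exactly
#' `round(overlap_pct/100 * n_pixels)` pixels carry a randomized ratio of
#' all end-members and the rest are pure, every pixel sharing the same
#' expected photon budget; photon emission and detection follow
#' [render_photons()] and [apply_detection_noise()]. Fully deterministic
#' under the design seed.
#'
#' @param design An [overlap_design()].
#' @param lib A [spectral_library()]; defaults to [default_library()] with
#'   the design's end-member count.
#' @param cfg A [noise_config()].
#' @return `list(cube = hyper_cube, truth = ground_truth)`.
#' @export
simulate_overlap <- function(design, lib = NULL, cfg = noise_config()) {
  stopifnot(inherits(design, "overlap_design"))
  if (is.null(lib)) lib <- default_library(design$n_endmembers)
  lib <- normalize_library(lib)
  if (nrow(lib$spectra) != design$n_endmembers)
    stop("library size does not match design n_endmembers")
  set.seed(design$seed)
  n_px <- design$image_size^2
  n_mixed <- round(design$overlap_pct / 100 * n_px)
  R <- matrix(0, n_px, design$n_endmembers)
  mixed <- if (n_mixed > 0) sample.int(n_px, n_mixed) else integer(0)
  pure <- setdiff(seq_len(n_px), mixed)
  if (length(mixed))
    R[mixed, ] <- runif_simplex(length(mixed), design$n_endmembers)
  if (length(pure))
    R[cbind(pure, sample.int(design$n_endmembers, length(pure),
                             replace = TRUE))] <- 1
  dims <- c(1L, 1L, design$image_size, design$image_size)
  truth <- new_ground_truth(
    pixel_matrix_to_cube(R, dims),
    array(design$photons_per_spectrum, dims),
    lib, cfg$gain_dl_per_photon)
  mask <- detection_mask(cfg$dichroic_lines_nm, lib$axis)
  photons <- render_photons(truth, mask, poisson = cfg$poisson)
  cube <- apply_detection_noise(photons, cfg, lib$axis)
  cube$metadata$design <- unclass(design)
  list(cube = cube, truth = truth)
}

# periodic Gaussian smoothing of a square white-noise field via FFT
smooth_field <- function(n, sigma) {
  x <- matrix(stats::rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  k2 <- outer(f^2, f^2, "+")
  g <- exp(-2 * pi^2 * sigma^2 * k2)
  sm <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n^2
  (sm - mean(sm)) / stats::sd(sm)
}

#' Simulate a biologically shaped hyperspectral image
#'
#' Emulates the spatial statistics of labelled tissue: each end-member
#' occupies a smooth blob/filament mask obtained by thresholding a
#' band-passed (Gaussian-smoothed) noise field, per-pixel photon budgets
#' follow a log-normal distribution scaled to the target mean, and pixels
#' covered by several masks become mixtures with ratios proportional to the
#' local mask field strengths. Pixels outside every mask are empty
#' background.
#'
#' @param photons_target Mean expected photons per pixel spectrum over
#'   foreground pixels.
#' @param lib A [spectral_library()] (default four-fluorophore library).
#' @param cfg A [noise_config()].
#' @param image_size Pixels per side.
#' @param seed RNG seed; the full generation is deterministic given it.
#' @param blur_sigma Gaussian smoothing length of the mask fields, px.
#' @param coverage Fraction of the frame each end-member's mask covers.
#' @param budget_sdlog Log-normal sdlog of the per-pixel photon budgets.
#' @return `list(cube = hyper_cube, truth = ground_truth)`.
#' @export
simulate_biological <- function(photons_target = 16, lib = default_library(),
                                cfg = noise_config(), image_size = 256L,
                                seed = 1L, blur_sigma = 8, coverage = 0.4,
                                budget_sdlog = 0.5) {
  lib <- normalize_library(lib)
  set.seed(seed)
  n <- as.integer(image_size)
  i <- nrow(lib$spectra)
  fields <- lapply(seq_len(i), function(k) smooth_field(n, blur_sigma))
  thr <- vapply(fields, function(f) stats::quantile(f, 1 - coverage),
                numeric(1))
  strength <- vapply(seq_len(i),
                     function(k) pmax(as.vector(fields[[k]]) - thr[k], 0),
                     numeric(n * n))
  fg <- rowSums(strength) > 0
  R <- matrix(0, n * n, i)
  R[fg, ] <- strength[fg, , drop = FALSE] / rowSums(strength)[fg]
  budget <- numeric(n * n)
  raw <- stats::rlnorm(sum(fg), meanlog = 0, sdlog = budget_sdlog)
  budget[fg] <- raw * photons_target / mean(raw)
  dims <- c(1L, 1L, n, n)
  truth <- new_ground_truth(pixel_matrix_to_cube(R, dims),
                            array(budget, dims), lib,
                            cfg$gain_dl_per_photon)
  mask <- detection_mask(cfg$dichroic_lines_nm, lib$axis)
  photons <- render_photons(truth, mask, poisson = cfg$poisson)
  cube <- apply_detection_noise(photons, cfg, lib$axis)
  cube$metadata$design <- list(type = "biological", seed = seed,
                               photons_target = photons_target,
                               image_size = n)
  list(cube = cube, truth = truth)
}
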
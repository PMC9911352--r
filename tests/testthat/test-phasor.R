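test_that("phasor transform maps canonical spectra to known coordinates", {
  # uniform spectrum: full-period cosine/sine sums vanish
  pf <- phasor_transform(hyper_cube(array(3, c(32, 2, 2))), harmonic = 1)
  expect_equal(max(abs(pf$G)), 0, tolerance = 1e-12)
  expect_equal(max(abs(pf$S)), 0, tolerance = 1e-12)
  # delta spectrum in channel 8 of 32 at n = 1 sits at angle pi/2
  delta <- array(0, c(32, 2, 2)); delta[8, , ] <- 5
  pf <- phasor_transform(hyper_cube(delta), harmonic = 1)
  expect_equal(pf$G[1, 1, 1, 1], cos(pi / 2), tolerance = 1e-12)
  expect_equal(pf$S[1, 1, 1, 1], 1, tolerance = 1e-12)
  # equal-total mix of delta-at-8 (0,1) and delta-at-24 (0,-1) lands at the
  # segment midpoint (0,0)
  mix <- array(0, c(32, 1, 1)); mix[8, , ] <- 2; mix[24, , ] <- 2
  pf <- phasor_transform(hyper_cube(mix), harmonic = 1)
  expect_equal(abs(pf$G[1, 1, 1, 1]) + abs(pf$S[1, 1, 1, 1]), 0,
               tolerance = 1e-12)
})

test_that("phasor coordinates obey the unit-disc bound, collinearity and scale invariance", {
  set.seed(11)
  for (h in 1:3) {
    arr <- array(stats::runif(32 * 6 * 6), c(32, 6, 6))
    pf <- phasor_transform(hyper_cube(arr), harmonic = h)
    expect_true(all(pf$G^2 + pf$S^2 <= 1 + 1e-9))
    # scale invariance
    pf2 <- phasor_transform(hyper_cube(17.3 * arr), harmonic = h)
    expect_equal(pf2$G, pf$G, tolerance = 1e-12)
    expect_equal(pf2$S, pf$S, tolerance = 1e-12)
  }
  # collinearity: mixture by total intensity interpolates the phasors
  a <- stats::runif(32); a <- a / sum(a)
  b <- stats::runif(32); b <- b / sum(b)
  ph <- function(s) {
    f <- phasor_transform(hyper_cube(array(s, c(32, 1, 1))), 1)
    c(f$G[1, 1, 1, 1], f$S[1, 1, 1, 1])
  }
  for (alpha in c(0, 0.25, 0.5, 0.9, 1)) {
    expect_equal(ph(alpha * a + (1 - alpha) * b),
                 alpha * ph(a) + (1 - alpha) * ph(b), tolerance = 1e-9)
  }
})

test_that("sub-threshold pixels are invalidated and an empty field warns", {
  arr <- array(0, c(32, 2, 2)); arr[, 1, 1] <- 10
  pf <- phasor_transform(hyper_cube(arr), 1, intensity_threshold = 5)
  expect_equal(sum(pf$valid_mask), 1)
  expect_true(all(pf$G[!pf$valid_mask] == 0))
  expect_warning(
    phasor_transform(hyper_cube(arr), 1, intensity_threshold = 1e6),
    "empty phasor")
})

test_that("phasor median denoising is an identity at 0 passes and composes", {
  set.seed(3)
  arr <- array(stats::rpois(32 * 12 * 12, 5), c(32, 12, 12))
  pf <- phasor_transform(hyper_cube(arr), 2)
  expect_identical(denoise_phasor(pf, 0), pf)
  # composition oracle: two single passes equal one double pass
  expect_equal(denoise_phasor(pf, 2),
               denoise_phasor(denoise_phasor(pf, 1), 1))
  # totals untouched
  expect_identical(denoise_phasor(pf, 3)$total, pf$total)
})

test_that("a single-pixel outlier in a constant plane is median-filtered away", {
  arr <- array(0, c(32, 9, 9))
  arr[5, , ] <- 100                       # constant spectra everywhere
  cube <- hyper_cube(arr)
  pf <- phasor_transform(cube, 1)
  g0 <- pf$G[1, 1, 1, 1]
  pf$G[1, 1, 5, 5] <- 0.9                 # inject outlier coordinate
  den <- denoise_phasor(pf, 1)
  expect_equal(den$G[1, 1, 5, 5], g0, tolerance = 1e-12)
  # constant planes are a fixed point (idempotence)
  expect_equal(denoise_phasor(den, 1)$G, den$G, tolerance = 1e-12)
})

test_that("phasor encoding conserves pixel counts and groups identical spectra", {
  set.seed(5)
  arr <- array(stats::runif(32 * 10 * 10), c(32, 10, 10))
  arr[, 3, 3] <- arr[, 7, 7]              # two pixels, identical spectra
  pf <- phasor_transform(hyper_cube(arr), 2)
  enc <- phasor_encode(pf, n_bins = 64)
  expect_equal(sum(enc$counts), 100)
  idx <- array(enc$bin_index, dim(pf$G))
  expect_equal(idx[1, 1, 3, 3], idx[1, 1, 7, 7])
})

test_that("bin assignment follows the half-open convention at exact edges", {
  # brute-force oracle over the 4 canonical edge cases on a tiny grid
  n_bins <- 4L; lo <- -1; width <- 2
  oracle <- function(v) {
    # half-open [edge_k, edge_{k+1}), top edge closed, clamped
    edges <- lo + width * (0:n_bins) / n_bins
    k <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    k
  }
  vals <- c(-1, -0.5, 0, 0.5)             # the 4 exact interior/lower edges
  for (v in vals) {
    pf <- structure(list(G = array(v, c(1, 1, 1, 1)),
                         S = array(v, c(1, 1, 1, 1)),
                         total = array(1, c(1, 1, 1, 1)), harmonic = 1L,
                         valid_mask = array(TRUE, c(1, 1, 1, 1))),
                    class = "phasor_field")
    enc <- phasor_encode(pf, n_bins = n_bins)
    g_bin <- (enc$bin_index[1] - 1L) %% n_bins + 1L
    # edge values belong to the *higher* bin
    expect_equal(g_bin, min(floor((v - lo) / width * n_bins) + 1L, n_bins))
    # findInterval's left-closed intervals are the same convention
    expect_equal(g_bin, oracle(v))
  }
  # the top edge is closed: +1 goes to the last bin, beyond-extent clamps
  pf <- structure(list(G = array(c(1), c(1, 1, 1, 1)),
                       S = array(1.7, c(1, 1, 1, 1)),
                       total = array(1, c(1, 1, 1, 1)), harmonic = 1L,
                       valid_mask = array(TRUE, c(1, 1, 1, 1))),
                  class = "phasor_field")
  enc <- phasor_encode(pf, n_bins = n_bins)
  expect_equal((enc$bin_index[1] - 1L) %% n_bins + 1L, n_bins)
  expect_equal((enc$bin_index[1] - 1L) %/% n_bins + 1L, n_bins)
})

test_that("bin-average spectra are conservative and correct on known bins", {
  # one- and two-member bins
  arr <- array(0, c(32, 1, 2))
  arr[1, 1, 1] <- 1                      # spectrum (1,0,...)
  arr[2, 1, 2] <- 1                      # spectrum (0,1,0,...)
  cube <- hyper_cube(arr)
  pf <- phasor_transform(cube, 1)
  enc <- average_spectra_by_bin(cube, phasor_encode(pf, n_bins = 2))
  # both deltas have |phasor| = 1 but different angles; if they share a bin
  # the mean is (0.5, 0.5, 0, ...), else each bin holds its own spectrum
  sums <- colSums(enc$bin_mean_spectrum * enc$bin_count)
  expect_equal(unname(sums), colSums(cube_matrix <- matrix(aperm(arr, c(2, 3, 1)), ncol = 32)))
  # random cube: count-weighted sum of bin means equals the global sum
  set.seed(9)
  arr <- array(stats::rpois(32 * 16 * 16, 20), c(32, 16, 16))
  cube <- hyper_cube(arr)
  enc <- average_spectra_by_bin(cube,
                                phasor_encode(phasor_transform(cube, 2), 64))
  glob <- rowSums(matrix(arr, nrow = 32))
  expect_equal(as.vector(colSums(enc$bin_mean_spectrum * enc$bin_count)),
               glob, tolerance = 1e-6)
})
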
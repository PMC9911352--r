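test_that("all four solvers recover pure and mixed noiseless spectra exactly", {
  lib <- lib4()
  solvers <- c("lstsq", "nnls", "fcls", "nmf")
  for (sv in solvers) {
    sp <- solver_spec(sv)
    r <- solve_ratios(lib$spectra[1, ], lib, sp)
    expect_equal(unname(r), c(1, 0, 0, 0), tolerance = 1e-9)
    r <- solve_ratios(0.3 * lib$spectra[1, ] + 0.7 * lib$spectra[2, ], lib, sp)
    expect_equal(unname(r), c(0.3, 0.7, 0, 0), tolerance = 1e-9)
  }
  # disjoint-support end-members: orthogonal projection gives the totals split
  sp2 <- matrix(0, 2, 32); sp2[1, 1:16] <- 1 / 16; sp2[2, 17:32] <- 1 / 16
  lib2 <- spectral_library(sp2, c("a", "b"), normalized = TRUE)
  s <- 0.6 * sp2[1, ] + 0.4 * sp2[2, ]
  for (sv in solvers)
    expect_equal(unname(solve_ratios(s, lib2, solver_spec(sv))), c(0.6, 0.4),
                 tolerance = 1e-9)
})

test_that("degenerate inputs are flagged or rejected", {
  lib <- lib4()
  r <- solve_ratios(rep(0, 32), lib)
  expect_true(all(r == 0))
  expect_true(isTRUE(attr(r, "flagged")))
  # near-collinear end-members give a rank-deficient normal matrix
  base <- lib$spectra[1, ]
  tweaked <- base; tweaked[1] <- tweaked[1] * (1 + 1e-9) + 1e-12
  collinear <- spectral_library(rbind(a = base, b = tweaked / sum(tweaked)),
                                normalized = TRUE)
  expect_error(solve_ratios(base, collinear), "rank-deficient")
  expect_error(solve_ratios(rep(1, 8), lib), "axis mismatch")
  expect_error(solve_ratios(rep(1, 32), spectral_library(lib$spectra)),
               "normalized")
})

test_that("pixelwise unmixing recovers simulator truth on noiseless cubes", {
  mc <- mixture_cube()
  for (sv in c("lstsq", "nnls", "fcls", "nmf")) {
    res <- lu_pixelwise(mc$cube, lib4(), solver_spec(sv))
    expect_equal(ratio_matrix(res$ratios), mc$ratios, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # intensity conservation: per-pixel unmixed intensities sum to the
  # spectral integral
  res <- lu_pixelwise(mc$cube, lib4())
  expect_equal(rowSums(ratio_matrix(res$intensities)), mc$totals,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pixelwise unmixing handles single-member and degenerate cubes", {
  lib <- lib4()
  arr <- aperm(array(outer(rep(1, 36), 250 * lib$spectra[2, ]),
                     c(1, 1, 6, 6, 32)), c(1, 2, 5, 3, 4))
  res <- lu_pixelwise(hyper_cube(arr), lib)
  expect_equal(unname(res$intensities[1, 1, 2, 3, 3]), 250, tolerance = 1e-9)
  expect_equal(sum(res$intensities[1, 1, -2, , ]), 0, tolerance = 1e-9)
  # all-zero cube: all-zero output, no error
  res0 <- lu_pixelwise(hyper_cube(array(0, c(32, 4, 4))), lib)
  expect_true(all(res0$ratios == 0) && all(res0$intensities == 0))
})

test_that("hybrid unmixing equals pixelwise unmixing on pure-pixel images", {
  pc <- pure_cube()
  lu <- lu_pixelwise(pc$cube, lib4())
  hy <- hyu(pc$cube, lib4(), passes = 0, n_bins = 256)
  expect_equal(hy$intensities, lu$intensities, tolerance = 1e-6)
  expect_lte(hy$metadata$solver_calls, 256^2)
  expect_lte(hy$metadata$solver_calls, sum(pc$cube$data[1, 1, 1, , ] >= 0))
  # encoding is position-blind: identical spectra get identical ratios
  expect_equal(hy$metadata$solver_calls, 4)  # 4 distinct spectra -> 4 bins
})

test_that("hybrid unmixing converges to pixelwise as bins grow fine", {
  mc <- mixture_cube(ny = 6, nx = 6, seed = 13)
  lu <- lu_pixelwise(mc$cube, lib4())
  hy <- hyu(mc$cube, lib4(), passes = 0, n_bins = 4096)
  # 36 distinct spectra < occupied bins: every pixel solved on its own bin
  expect_equal(hy$intensities, lu$intensities, tolerance = 1e-6)
})

test_that("hybrid unmixing reports solver calls and warns on empty masks", {
  pc <- pure_cube()
  hy <- hyu(pc$cube, lib4(), passes = 1, n_bins = 64)
  expect_true(hy$metadata$solver_calls >= 1)
  expect_warning(
    expect_warning(res0 <- hyu(hyper_cube(array(0, c(32, 4, 4))), lib4()),
                   "empty phasor"),
    "empty valid mask")
  expect_true(all(res0$intensities == 0))
})

test_that("reconstruction inverts the forward model on exact mixtures", {
  mc <- mixture_cube()
  res <- lu_pixelwise(mc$cube, lib4())
  recon <- reconstruct(res, mc$cube)
  expect_equal(recon$data, mc$cube$data, tolerance = 1e-6)
  # pure-pixel reconstruction is the scaled end-member spectrum
  pc <- pure_cube(ny = 2, nx = 2, seed = 1)
  rp <- reconstruct(lu_pixelwise(pc$cube, lib4()), pc$cube)
  expect_equal(rp$data, pc$cube$data, tolerance = 1e-9)
  # all-zero result reconstructs to an all-zero cube
  z <- hyper_cube(array(0, c(32, 3, 3)))
  expect_true(all(reconstruct(lu_pixelwise(z, lib4()), z)$data == 0))
})

test_that("residuals vanish on representable cubes and capture unmodeled signal", {
  mc <- mixture_cube()
  res <- lu_pixelwise(mc$cube, lib4())
  rm <- residual_map(mc$cube, res)
  expect_lt(max(rm$relative), 1e-6)
  expect_lt(max(rm$absolute), 1e-3)
  # leakage oracle: signal in a channel outside the library support shows up
  # fully in the residual
  sp2 <- matrix(0, 2, 32); sp2[1, 5] <- 1; sp2[2, 10] <- 1
  lib2 <- spectral_library(sp2, c("a", "b"), normalized = TRUE)
  arr <- array(0, c(32, 2, 2))
  arr[5, , ] <- 100; arr[20, , ] <- 40    # channel 20 is unmodeled
  cube <- hyper_cube(arr)
  res2 <- lu_pixelwise(cube, lib2)
  rm2 <- residual_map(cube, res2)
  # recon puts the full 140 into ch 5: |140-100| + |0-40| = 80
  expect_equal(unname(rm2$absolute[1, 1, 1, 1]), 80, tolerance = 1e-9)
})

test_that("relative residual is bounded by [0, 200] for nonnegative reconstructions", {
  set.seed(21)
  for (k in 1:5) {
    arr <- array(stats::rpois(32 * 8 * 8, 2), c(32, 8, 8))
    cube <- hyper_cube(arr)
    res <- lu_pixelwise(cube, lib4())
    rel <- residual_map(cube, res, against = "original")$relative
    expect_true(all(rel >= 0 & rel <= 200 + 1e-9))
  }
})

test_that("hybrid residuals are evaluated on the encoded representation by default", {
  set.seed(31)
  sim <- simulate_biological(photons_target = 8, image_size = 48, seed = 31)
  hy <- hyu(sim$cube, lib4(), passes = 2)
  r_in <- residual_map(sim$cube, hy)$summary$mean
  r_or <- residual_map(sim$cube, hy, against = "original")$summary$mean
  # the bin-averaged input is closer to the library span than the raw
  # photon-sparse pixels, so the input-referenced residual is smaller
  expect_lt(r_in, r_or)
  lu <- lu_pixelwise(sim$cube, lib4())
  expect_equal(residual_map(sim$cube, lu)$relative,
               residual_map(sim$cube, lu, against = "original")$relative)
})
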
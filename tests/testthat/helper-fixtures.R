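# shared fixtures, all generated in code

lib4 <- function() default_library(4L)

# noiseless cube whose pixels are exact nonnegative combinations of the
# library rows; ratios returned alongside for oracle checks
mixture_cube <- function(lib = lib4(), ny = 8, nx = 8, seed = 42,
                         intensity = 1000) {
  set.seed(seed)
  i <- nrow(lib$spectra)
  R <- matrix(stats::rexp(ny * nx * i), ny * nx, i)
  R <- R / rowSums(R)
  tot <- stats::runif(ny * nx, 0.5, 1.5) * intensity
  S <- (R * tot) %*% (lib$spectra / rowSums(lib$spectra))
  arr <- aperm(array(S, c(1, 1, ny, nx, ncol(S))), c(1, 2, 5, 3, 4))
  list(cube = hyper_cube(arr, lib$axis), ratios = R, totals = tot)
}

# pure-pixel cube: each pixel is one end-member at a random intensity
pure_cube <- function(lib = lib4(), ny = 8, nx = 8, seed = 7) {
  set.seed(seed)
  i <- nrow(lib$spectra)
  who <- sample.int(i, ny * nx, replace = TRUE)
  R <- matrix(0, ny * nx, i)
  R[cbind(seq_len(ny * nx), who)] <- 1
  tot <- stats::runif(ny * nx, 100, 2000)
  S <- (R * tot) %*% (lib$spectra / rowSums(lib$spectra))
  arr <- aperm(array(S, c(1, 1, ny, nx, ncol(S))), c(1, 2, 5, 3, 4))
  list(cube = hyper_cube(arr, lib$axis), ratios = R)
}

ratio_matrix <- function(x) {
  i <- dim(x)[3]
  matrix(aperm(x, c(1, 2, 4, 5, 3)), ncol = i)
}
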
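#' Mean squared error against ground truth
#'
#' Compares unmixed intensity channels against the ground-truth intensities
#' (true ratios scaled by the noiseless expected DL total per pixel). Lower
#' is better; the overall value is the mean of squared differences over all
#' pixels and end-member channels, in DL^2.
#'
#' @param result An `unmixed_image`.
#' @param truth A `ground_truth`.
#' @return A list with `overall` (scalar MSE, DL^2) and `per_endmember`
#'   (named numeric vector).
#' @export
mse <- function(result, truth) {
  stopifnot(inherits(result, "unmixed_image"), inherits(truth, "ground_truth"))
  if (!identical(dim(result$intensities), dim(truth$true_ratios)))
    stop("shape mismatch between result and truth")
  i <- dim(truth$true_ratios)[3]
  Tm <- matrix(aperm(truth$true_ratios, c(1, 2, 4, 5, 3)), ncol = i)
  Im <- matrix(aperm(result$intensities, c(1, 2, 4, 5, 3)), ncol = i)
  sq <- (Im - Tm * as.vector(truth$true_total_dl))^2
  per <- colMeans(sq)
  names(per) <- result$library$names
  list(overall = mean(sq), per_endmember = per)
}

#' Relative MSE improvement of one method over another
#'
#' `100 * (mse_ref - mse_new) / mse_ref`: positive values mean the new
#' method (typically hybrid unmixing) outperforms the reference (typically
#' pixelwise LU).
#'
#' @param mse_lu Reference MSE (> 0).
#' @param mse_hyu Comparison MSE.
#' @return Percentage improvement; `NA` with a warning when `mse_lu` is 0.
#' @export
relative_mse_improvement <- function(mse_lu, mse_hyu) {
  out <- 100 * (mse_lu - mse_hyu) / mse_lu
  if (any(mse_lu == 0)) {
    warning("reference MSE is zero; improvement undefined")
    out[mse_lu == 0] <- NA_real_
  }
  out
}

#' Box-plot summary statistics of a residual map
#'
#' Median, quartiles and 1.5x-IQR whiskers (plus mean and SD) of a relative
#' residual map, optionally split by z slice to profile unmixing quality
#' versus imaging depth. Quartiles use linear interpolation (type 7).
#'
#' @param relative Residual array `(t, z, y, x)` (or any numeric array).
#' @param group_by `"none"` for one summary row, `"z"` for one row per z
#'   slice (requires a 4-D map).
#' @return A tibble with columns `z` (when grouped), `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
residual_stats <- function(relative, group_by = c("none", "z")) {
  group_by <- match.arg(group_by)
  one <- function(v, z = NA_integer_) {
    if (length(v) == 0) stop("empty selection")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    tibble::tibble(z = z, n = length(v), mean = mean(v), sd = stats::sd(v),
                   median = q[2], q1 = q[1], q3 = q[3],
                   whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
  }
  if (group_by == "none") {
    out <- one(as.vector(relative))
    out$z <- NULL
    return(out)
  }
  if (length(dim(relative)) != 4L) stop("z grouping needs a (t,z,y,x) map")
  dplyr::bind_rows(lapply(seq_len(dim(relative)[2]),
                          function(z) one(as.vector(relative[, z, , ]), z)))
}

#' RMS contrast of an image channel
#'
#' Standard deviation divided by mean over the pixels with nonzero support;
#' scale-invariant, zero for a constant image.
#'
#' @param img Nonnegative numeric array.
#' @return Scalar RMS contrast.
#' @export
contrast <- function(img) {
  v <- as.vector(img)
  v <- v[v > 0]
  if (length(v) == 0) stop("empty support")
  stats::sd(v) / mean(v)
}

#' Unmixing operation counts: pixelwise versus phasor-encoded
#'
#' Pixelwise unmixing solves once per voxel (`x * y * z * t` operations);
#' hybrid unmixing solves once per occupied phasor bin. For a typical
#' timelapse volume the ratio is more than a thousand-fold.
#'
#' @param dims Integer vector `(x, y, z, t)`.
#' @param encoding Optional [phasor_encoding()]; supplies the occupied-bin
#'   count for the hybrid figure.
#' @return A list: `pixelwise_ops`, `pixelwise_millions` (rounded to the
#'   nearest million), and `hyu_ops` (`NA` without an encoding).
#' @examples
#' operations_count(c(512, 768, 17, 6))$pixelwise_millions  # 40
#' @export
operations_count <- function(dims, encoding = NULL) {
  stopifnot(length(dims) == 4, all(dims > 0))
  px <- prod(as.numeric(dims))
  list(pixelwise_ops = px,
       pixelwise_millions = round(px / 1e6),
       hyu_ops = if (is.null(encoding)) NA_real_ else sum(encoding$counts > 0))
}
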
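#' Photon-starvation sweep: hybrid versus pixelwise unmixing
#'
#' Runs the full evaluation loop of the synthetic study: for every photon
#' level and seeded replicate, simulate a biologically shaped cube, unmix it
#' with pixelwise LU and with hybrid unmixing at each requested
#' median-filter count, and record MSE against ground truth plus the mean
#' relative unmixing residual. The phasor field is computed once per cube
#' and median passes are applied incrementally, so the per-filter hybrid
#' runs share work.
#'
#' @param photons Numeric vector of expected photons per spectrum. The
#'   default grid spans the ultralow (2--5) through saturated regimes.
#' @param filters Integer vector of median-filter pass counts for hybrid
#'   unmixing (pixelwise rows carry `filters = NA`).
#' @param replicates Number of seeded replicates per photon level.
#' @param image_size Pixels per side of each simulated frame.
#' @param lib Spectral library (default 4 Gaussian end-members).
#' @param cfg [noise_config()] for the detection model.
#' @param harmonic,n_bins Hybrid unmixing phasor parameters.
#' @param solver [solver_spec()] used by both methods.
#' @param base_seed Master seed; replicate seeds derive deterministically
#'   from it.
#' @return A tibble of class `hyu_sweep`, one row per
#'   (photons, replicate, method, filters): columns `photons`, `replicate`,
#'   `seed`, `method`, `filters`, `mse`, `mean_rel_residual`,
#'   `solver_calls`.
#' @seealso [summarize_sweep()], [autoplot.hyu_sweep()]
#' @export
photon_sweep <- function(photons = c(2, 4, 5, 8, 16, 32, 64, 128, 256),
                         filters = 0:5, replicates = 3L, image_size = 128L,
                         lib = default_library(), cfg = noise_config(),
                         harmonic = 2L, n_bins = 256L,
                         solver = solver_spec("lstsq"), base_seed = 1L) {
  lib <- normalize_library(lib)
  filters <- sort(unique(as.integer(filters)))
  rows <- list()
  for (pi in seq_along(photons)) {
    for (rep_i in seq_len(replicates)) {
      seed <- as.integer((as.double(base_seed) * 1000 + pi * 100 + rep_i) %%
                           .Machine$integer.max)
      sim <- simulate_biological(photons_target = photons[pi], lib = lib,
                                 cfg = cfg, image_size = image_size,
                                 seed = seed)
      res_lu <- lu_pixelwise(sim$cube, lib, solver)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        photons = photons[pi], replicate = rep_i, seed = seed,
        method = "lu", filters = NA_integer_,
        mse = mse(res_lu, sim$truth)$overall,
        mean_rel_residual = residual_map(sim$cube, res_lu)$summary$mean,
        solver_calls = res_lu$metadata$solver_calls)
      field <- phasor_transform(sim$cube, harmonic)
      passes_done <- 0L
      for (f in filters) {
        if (f > passes_done) {
          field <- denoise_phasor(field, f - passes_done)
          passes_done <- f
        }
        enc <- average_spectra_by_bin(sim$cube, phasor_encode(field, n_bins))
        res_h <- hyu_from_encoding(sim$cube, lib, enc, solver)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          photons = photons[pi], replicate = rep_i, seed = seed,
          method = "hyu", filters = f,
          mse = mse(res_h, sim$truth)$overall,
          mean_rel_residual = residual_map(sim$cube, res_h)$summary$mean,
          solver_calls = res_h$metadata$solver_calls)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hyu_sweep", class(out))
  attr(out, "params") <- list(image_size = image_size, n_bins = n_bins,
                              harmonic = harmonic, replicates = replicates,
                              base_seed = base_seed)
  out
}

#' Summarize a photon sweep across replicates
#'
#' Per (photons, method, filters) cell: mean MSE with a normal-approximation
#' 95% confidence interval, mean relative residual, and -- for hybrid rows
#' -- the mean relative MSE improvement over the matched pixelwise runs.
#'
#' @param sweep A [photon_sweep()] result.
#' @return A tibble with columns `photons`, `method`, `filters`, `n`,
#'   `mse_mean`, `mse_ci_lo`, `mse_ci_hi`, `residual_mean`,
#'   `improvement_pct` (hybrid rows only).
#' @export
summarize_sweep <- function(sweep) {
  lu <- dplyr::filter(sweep, .data$method == "lu") |>
    dplyr::select("photons", "replicate", lu_mse = "mse")
  sweep |>
    dplyr::left_join(lu, by = c("photons", "replicate")) |>
    dplyr::mutate(impr = dplyr::if_else(
      .data$method == "hyu",
      relative_mse_improvement(.data$lu_mse, .data$mse), NA_real_)) |>
    dplyr::group_by(.data$photons, .data$method, .data$filters) |>
    dplyr::summarize(
      n = dplyr::n(),
      mse_mean = mean(.data$mse),
      mse_se = stats::sd(.data$mse) / sqrt(dplyr::n()),
      residual_mean = mean(.data$mean_rel_residual),
      improvement_pct = mean(.data$impr),
      .groups = "drop") |>
    dplyr::mutate(mse_ci_lo = .data$mse_mean - 1.96 * .data$mse_se,
                  mse_ci_hi = .data$mse_mean + 1.96 * .data$mse_se) |>
    dplyr::select(-"mse_se")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep result
#'
#' Returns the per-replicate sweep rows as a plain tibble (broom
#' convention).
#'
#' @param x A `hyu_sweep`.
#' @param ... Unused.
#' @method tidy hyu_sweep
#' @export
tidy.hyu_sweep <- function(x, ...) tibble::as_tibble(unclass(x))

#' One-row summary of a sweep
#'
#' Overall comparison figures: best mean relative MSE improvement of hybrid
#' unmixing without and with median filters, and the mean residual
#' reduction relative to pixelwise unmixing.
#'
#' @param x A `hyu_sweep`.
#' @param ... Unused.
#' @method glance hyu_sweep
#' @export
glance.hyu_sweep <- function(x, ...) {
  s <- summarize_sweep(x)
  h0 <- dplyr::filter(s, .data$method == "hyu", .data$filters == 0)
  hf <- dplyr::filter(s, .data$method == "hyu", .data$filters > 0)
  maxf <- max(x$filters, na.rm = TRUE)
  lu <- dplyr::filter(x, .data$method == "lu")
  hy <- dplyr::filter(x, .data$method == "hyu", .data$filters == maxf)
  joined <- dplyr::inner_join(
    dplyr::select(lu, "photons", "replicate", lu_res = "mean_rel_residual"),
    dplyr::select(hy, "photons", "replicate", hy_res = "mean_rel_residual"),
    by = c("photons", "replicate"))
  tibble::tibble(
    max_improvement_unfiltered_pct =
      if (nrow(h0)) max(h0$improvement_pct) else NA_real_,
    max_improvement_filtered_pct =
      if (nrow(hf)) max(hf$improvement_pct) else NA_real_,
    residual_reduction_pct =
      mean(100 * (joined$lu_res - joined$hy_res) / joined$lu_res),
    n_conditions = nrow(s))
}

#' Tidy an unmixed image into a per-pixel tibble
#'
#' @param x An `unmixed_image`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `z`, `y`, `x`, one ratio and one
#'   intensity column per end-member.
#' @method tidy unmixed_image
#' @export
tidy.unmixed_image <- function(x, ...) {
  d <- dim(x$ratios)
  i <- d[3]
  idx <- expand.grid(t = seq_len(d[1]), z = seq_len(d[2]),
                     y = seq_len(d[4]), x = seq_len(d[5]))
  Rm <- matrix(aperm(x$ratios, c(1, 2, 4, 5, 3)), ncol = i)
  Im <- matrix(aperm(x$intensities, c(1, 2, 4, 5, 3)), ncol = i)
  colnames(Rm) <- paste0("ratio_", x$library$names)
  colnames(Im) <- paste0("intensity_", x$library$names)
  tibble::as_tibble(cbind(idx, Rm, Im))
}

#' @method glance unmixed_image
#' @export
glance.unmixed_image <- function(x, ...) {
  tibble::tibble(method = x$method, solver = x$solver,
                 n_endmembers = dim(x$ratios)[3],
                 n_pixels = prod(dim(x$ratios)[-3]),
                 solver_calls = x$metadata$solver_calls %||% NA_integer_,
                 total_intensity = sum(x$intensities))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot MSE versus photons per spectrum for a sweep
#'
#' Line plot of mean MSE (log-log) against the photon budget, one line per
#' method/filter combination, with shaded 95% confidence bands across
#' replicates.
#'
#' @param object A `hyu_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hyu_sweep
#' @export
autoplot.hyu_sweep <- function(object, ...) {
  s <- summarize_sweep(object)
  s$series <- ifelse(s$method == "lu", "LU",
                     paste0("HyU (", s$filters, " filters)"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$photons, y = .data$mse_mean,
                                  colour = .data$series,
                                  fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mse_ci_lo,
                                      ymax = .data$mse_ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "photons per spectrum", y = expression(MSE ~ (DL^2)),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phasor histogram
#'
#' Log-scaled occupancy of the 2-D phasor histogram, the standard phasor
#' plot.
#'
#' @param object A `phasor_encoding`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phasor_encoding
#' @export
autoplot.phasor_encoding <- function(object, ...) {
  occ <- which(object$counts > 0, arr.ind = TRUE)
  lo <- object$extent[1]
  w <- (object$extent[2] - object$extent[1]) / object$n_bins
  df <- tibble::tibble(G = lo + (occ[, 1] - 0.5) * w,
                       S = lo + (occ[, 2] - 0.5) * w,
                       count = object$counts[occ])
  ggplot2::ggplot(df, ggplot2::aes(.data$G, .data$S, fill = log10(.data$count))) +
    ggplot2::geom_tile(width = w, height = w) +
    ggplot2::coord_fixed(xlim = object$extent, ylim = object$extent) +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ count)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
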
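#' Preprocessing configuration
#'
#' Parameters of the three-stage preprocessing chain applied to every
#' spectrum: iterative modified-polynomial baseline removal, Savitzky-Golay
#' smoothing, then normalization to the paraformaldehyde internal-standard
#' band.
#'
#' @param baseline_order Polynomial degree of the baseline fit (default 5).
#' @param baseline_max_iter Maximum clipping iterations (default 100).
#' @param baseline_tol Relative-change stopping threshold on the fitted
#'   baseline (default 1e-4).
#' @param sg_window Savitzky-Golay window length in points; odd and greater
#'   than `sg_polyorder` (default 11).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param norm_center Center of the normalization band in cm^-1
#'   (default 1040, the PFA fixative signal).
#' @param norm_half_width Half-width of the closed normalization band in
#'   cm^-1 (default 2; 0 selects the single nearest channel window).
#' @param clip_sigma Noise tolerance of the baseline clipping, in units of
#'   the per-spectrum noise SD (robustly estimated from second differences):
#'   working points above `fit + clip_sigma * sd` are replaced by the fit.
#'   0 is the classic fully clipped iteration `work = min(work, fit)`,
#'   which settles on the lower envelope of the noise and biases corrected
#'   intensities upward by roughly one noise SD; the small default
#'   tolerance (0.25) removes that settling while keeping peak wings out
#'   of the fit, and vanishes identically on noise-free spectra.
#' @param baseline_presmooth Window (odd point count) of the Savitzky-Golay
#'   order-3 pre-smoothing applied to the baseline estimator's working copy
#'   of the spectrum (the spectrum itself is not altered). Heavy smoothing
#'   here suppresses the tendency of the clipped iteration to settle on the
#'   lower noise envelope, while leaving any polynomial baseline of degree
#'   <= 3 exactly unchanged. 0 disables. Default 51.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_order = 5, baseline_max_iter = 100,
                              baseline_tol = 1e-4,
                              sg_window = 11, sg_polyorder = 3,
                              norm_center = 1040, norm_half_width = 2,
                              clip_sigma = 0.25, baseline_presmooth = 0) {
  if (sg_window %% 2 == 0) {
    stop("sg_window must be odd", call. = FALSE)
  }
  if (sg_window <= sg_polyorder) {
    stop("sg_window must exceed sg_polyorder", call. = FALSE)
  }
  if (norm_half_width < 0) stop("norm_half_width must be >= 0", call. = FALSE)
  if (baseline_order < 0) stop("baseline_order must be >= 0", call. = FALSE)
  if (clip_sigma < 0) stop("clip_sigma must be >= 0", call. = FALSE)
  if (baseline_presmooth != 0 &&
      (baseline_presmooth < 5 || baseline_presmooth %% 2 == 0)) {
    stop("baseline_presmooth must be 0 or an odd count >= 5", call. = FALSE)
  }
  structure(list(baseline_order = baseline_order,
                 baseline_max_iter = baseline_max_iter,
                 baseline_tol = baseline_tol,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 norm_center = norm_center,
                 norm_half_width = norm_half_width,
                 clip_sigma = clip_sigma,
                 baseline_presmooth = as.integer(baseline_presmooth)),
            class = "preprocess_config")
}

# orthonormal polynomial basis (with intercept) on the grid; shared by the
# per-spectrum and batched baseline paths so both compute identical fits
baseline_basis <- function(grid, order) {
  if (length(grid) <= order + 1) {
    stop("fit error: grid length (", length(grid),
         ") must exceed baseline_order + 1 (", order + 1, ")", call. = FALSE)
  }
  u <- (grid - mean(grid)) / (max(grid) - min(grid))
  raw <- outer(u, 0:order, `^`)
  qr.Q(qr(raw))
}

# Lieber-style iterative modified polynomial fit on a matrix of spectra
# (rows), in compiled code; each row iterates independently, so the batched
# fit is identical to fitting each spectrum alone.
modpoly_matrix <- function(Y, basis, thr, max_iter, tol) {
  .modpoly_fit(Y, basis, thr, as.integer(max_iter), tol)
}

#' Robust per-spectrum noise scale
#'
#' Estimates the additive noise SD of a spectrum as
#' `mad(second differences) / sqrt(6)`: second differencing annihilates
#' smooth baseline and broad-peak structure while multiplying white-noise
#' variance by 6, and the median absolute deviation ignores the sparse
#' sharp-peak channels. Exactly 0 for noise-free polynomial input.
#'
#' @param intensities Numeric vector (or matrix with spectra in rows).
#' @return Numeric noise SD (one per spectrum row).
#' @export
estimate_noise_sd <- function(intensities) {
  if (is.matrix(intensities)) {
    d2 <- intensities[, -c(1, 2), drop = FALSE] -
      2 * intensities[, -c(1, ncol(intensities)), drop = FALSE] +
      intensities[, -c(ncol(intensities) - 1, ncol(intensities)),
                  drop = FALSE]
    apply(d2, 1L, stats::mad) / sqrt(6)
  } else {
    stats::mad(diff(intensities, differences = 2)) / sqrt(6)
  }
}

# sparse operator reproducing signal::sgolayfilt row-wise: interior points
# use the central projection row, terminal windows the first/last rows of
# the Savitzky-Golay projection matrix (polynomial evaluation in-window)
sg_operator <- function(n_points, order, window) {
  F <- unclass(signal::sgolay(p = order, n = window))
  k <- (window - 1L) %/% 2L
  n_int <- n_points - 2L * k
  ii <- c(rep(seq_len(k), each = window),
          rep(seq(k + 1L, n_points - k), each = window),
          rep(seq(n_points - k + 1L, n_points), each = window))
  jj <- c(rep(seq_len(window), times = k),
          as.vector(outer(seq(1L, window), seq(0L, n_int - 1L), `+`)),
          rep(seq(n_points - window + 1L, n_points), times = k))
  xx <- c(t(F[seq_len(k), , drop = FALSE]),
          rep(rev(F[k + 1L, ]), times = n_int),
          t(F[seq(k + 2L, window), , drop = FALSE]))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_points, n_points))
}

# pre-smoothed working copy for baseline estimation; window shrunk to the
# grid when needed, identity when the grid is too short for a cubic fit
presmooth_rows <- function(Y, window) {
  if (window == 0) return(Y)
  p <- ncol(Y)
  w <- min(window, if (p %% 2 == 1) p else p - 1L)
  if (w < 5) return(Y)
  as.matrix(Matrix::tcrossprod(Y, sg_operator(p, 3L, w)))
}

#' Fit an autofluorescence baseline to one spectrum
#'
#' Iterative modified polynomial fit: an order-`baseline_order` polynomial is
#' fitted by least squares, working intensities above the fit are clipped
#' down to it, and the fit is repeated until the baseline changes by less
#' than `baseline_tol` (relative) or `baseline_max_iter` iterations. The
#' clipping drives the polynomial under the Raman peaks while tracking the
#' smooth background. The estimator operates on a heavily pre-smoothed
#' working copy of the spectrum (`baseline_presmooth`), which keeps the
#' clipped iteration from settling on the lower envelope of the noise;
#' an optional noise tolerance (`clip_sigma`, see [estimate_noise_sd()])
#' serves the same purpose for spectra whose baseline is not smooth enough
#' to pre-smooth safely.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return An object of class `baseline_model` with fields `order`,
#'   `coefficients` (in the orthonormal polynomial basis) and
#'   `fitted_values` (baseline intensity per grid point).
#' @export
fit_baseline <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  basis <- baseline_basis(spectrum$grid, config$baseline_order)
  thr <- config$clip_sigma * estimate_noise_sd(spectrum$intensities)
  Yw <- presmooth_rows(matrix(spectrum$intensities, nrow = 1L),
                       config$baseline_presmooth)
  fit <- modpoly_matrix(Yw, basis, thr,
                        config$baseline_max_iter, config$baseline_tol)[1L, ]
  structure(list(order = config$baseline_order,
                 coefficients = as.numeric(crossprod(basis, fit)),
                 fitted_values = fit),
            class = "baseline_model")
}

#' Subtract the fitted baseline from a spectrum
#'
#' Small negative residuals are retained, not clipped: clipping would bias
#' downstream band statistics.
#'
#' @inheritParams fit_baseline
#' @return A baseline-corrected [raman_spectrum()].
#' @export
correct_baseline <- function(spectrum, config = preprocess_config()) {
  bl <- fit_baseline(spectrum, config)
  spectrum$intensities <- spectrum$intensities - bl$fitted_values
  spectrum
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the configured window and
#' order. Endpoints are handled by evaluating the fitted terminal-window
#' polynomials, so polynomials of degree <= `sg_polyorder` pass through
#' unchanged over the whole grid.
#'
#' @inheritParams fit_baseline
#' @return A smoothed [raman_spectrum()].
#' @export
smooth_spectrum <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  check_sg(config, length(spectrum$grid))
  spectrum$intensities <- signal::sgolayfilt(spectrum$intensities,
                                             p = config$sg_polyorder,
                                             n = config$sg_window)
  spectrum
}

check_sg <- function(config, n_points) {
  if (config$sg_window %% 2 == 0) stop("sg_window must be odd", call. = FALSE)
  if (config$sg_window > n_points) {
    stop("sg_window (", config$sg_window, ") exceeds grid length (",
         n_points, ")", call. = FALSE)
  }
  if (config$sg_window <= config$sg_polyorder) {
    stop("sg_window must exceed sg_polyorder", call. = FALSE)
  }
  invisible(TRUE)
}

norm_band_index <- function(grid, config) {
  lo <- config$norm_center - config$norm_half_width
  hi <- config$norm_center + config$norm_half_width
  idx <- which(grid >= lo & grid <= hi)
  if (!length(idx)) {
    stop("range error: normalization band [", lo, ", ", hi,
         "] is outside the grid", call. = FALSE)
  }
  idx
}

#' Normalize a spectrum to the PFA internal-standard band
#'
#' Divides every intensity by the mean intensity over the closed band
#' `norm_center +/- norm_half_width` (1040 +/- 2 cm^-1 by default), so the
#' band mean of the result is exactly 1. Normalizing to the fixative band
#' removes pixel-to-pixel excitation and collection-efficiency scale.
#'
#' @inheritParams fit_baseline
#' @return A normalized [raman_spectrum()].
#' @export
normalize_pfa <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  idx <- norm_band_index(spectrum$grid, config)
  m <- mean(spectrum$intensities[idx])
  if (!is.finite(m) || m <= 0) {
    stop("normalization error: band mean at ", config$norm_center,
         " cm^-1 is not positive (", format(m), ")", call. = FALSE)
  }
  spectrum$intensities <- spectrum$intensities / m
  spectrum
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, in order: baseline correction, Savitzky-Golay smoothing, and PFA
#' internal-standard normalization, row by row. Labels, cell ids and pixel
#' coordinates are untouched. Baseline fitting is vectorized across rows but
#' computes the same fit as [fit_baseline()] on each spectrum.
#'
#' @param dataset A [spectral_dataset()].
#' @param config A [preprocess_config()].
#' @return The preprocessed `spectral_dataset`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- n_spectra(dataset)
  if (n == 0L) return(dataset)
  check_sg(config, length(dataset$grid))
  basis <- baseline_basis(dataset$grid, config$baseline_order)
  Y <- dataset$intensities
  thr <- config$clip_sigma * estimate_noise_sd(Y)
  bl <- modpoly_matrix(presmooth_rows(Y, config$baseline_presmooth), basis,
                       thr, config$baseline_max_iter, config$baseline_tol)
  Y <- Y - bl
  S <- sg_operator(length(dataset$grid), config$sg_polyorder,
                   config$sg_window)
  Y <- as.matrix(Matrix::tcrossprod(Y, S))
  idx <- norm_band_index(dataset$grid, config)
  norms <- rowMeans(Y[, idx, drop = FALSE])
  bad <- which(!is.finite(norms) | norms <= 0)
  if (length(bad)) {
    stop("normalization error for spectra: ",
         paste(rownames(dataset$intensities)[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- Y / norms
  rownames(out) <- rownames(dataset$intensities)
  dataset$intensities <- out
  dataset
}

#' Per-spectrum band mean intensities
#'
#' Mean intensity over the closed window `center +/- half_width` for every
#' spectrum in a dataset; the unit of all reported band statistics.
#'
#' @param dataset A [spectral_dataset()].
#' @param center Band center in cm^-1.
#' @param half_width Band half-width in cm^-1.
#' @return Numeric vector, one band mean per spectrum.
#' @export
band_values <- function(dataset, center, half_width = 2) {
  idx <- which(dataset$grid >= center - half_width &
               dataset$grid <= center + half_width)
  if (!length(idx)) {
    stop("band [", center - half_width, ", ", center + half_width,
         "] does not intersect the grid", call. = FALSE)
  }
  rowMeans(dataset$intensities[, idx, drop = FALSE])
}
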
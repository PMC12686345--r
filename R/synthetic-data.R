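#' Default simulation wavenumber grid
#'
#' 300-5000 cm^-1 at 1 cm^-1 spacing (4701 channels). The integer grid makes
#' band lookup exact for the Raman-shift assignments used throughout.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(300, 5000, by = 1)

#' Describe one generative Raman peak
#'
#' @param center Peak center in cm^-1. Biological peaks may not sit inside
#'   the open Raman-silent interval (1800, 2800).
#' @param fwhm Full width at half maximum in cm^-1 (> 0).
#' @param mean_amplitude Expected peak height for this class, in
#'   post-normalization units (>= 0).
#' @param between_cell_sd SD of the log-normal cell-level amplitude
#'   multiplier (mean 1) applied to this peak.
#' @param within_cell_sd SD of the log-normal pixel-level amplitude
#'   multiplier (mean 1): intracellular heterogeneity, since spectra from
#'   different subcellular positions of one cell are not identical.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param silent_ok Internal: allow a center inside the silent region (used
#'   only for the paraformaldehyde internal standard, which is not biological
#'   and sits at 1040 cm^-1 anyway).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, fwhm, mean_amplitude, between_cell_sd = 0,
                      within_cell_sd = 0,
                      shape = c("gaussian", "lorentzian"), silent_ok = FALSE) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (mean_amplitude < 0) stop("mean_amplitude must be >= 0", call. = FALSE)
  if (between_cell_sd < 0) stop("between_cell_sd must be >= 0", call. = FALSE)
  if (within_cell_sd < 0) stop("within_cell_sd must be >= 0", call. = FALSE)
  if (!silent_ok && center > 1800 && center < 2800) {
    stop("biological peak center ", center,
         " lies in the Raman-silent region (1800, 2800)", call. = FALSE)
  }
  structure(list(center = center, fwhm = fwhm, shape = shape,
                 mean_amplitude = mean_amplitude,
                 between_cell_sd = between_cell_sd,
                 within_cell_sd = within_cell_sd),
            class = "peak_spec")
}

# unit-height line shape evaluated on a grid
peak_shape <- function(peak, grid) {
  d <- grid - peak$center
  if (peak$shape == "gaussian") {
    exp(-4 * log(2) * (d / peak$fwhm)^2)
  } else {
    hw <- peak$fwhm / 2
    hw^2 / (d^2 + hw^2)
  }
}

#' Generative description of one cell subtype
#'
#' Bundles the subtype's peak list with its autofluorescence baseline model,
#' pixel noise level, and the paraformaldehyde (PFA) internal-standard band
#' at 1040 cm^-1 that every fixed cell carries.
#'
#' Peak amplitudes are stated in post-normalization units; at generation time
#' they are multiplied by `amplitude_scale` (the expected raw PFA band mean),
#' so that dividing by the PFA band during preprocessing recovers them.
#'
#' @param class_name Subtype label.
#' @param peaks List of [peak_spec()] objects.
#' @param baseline_order Polynomial degree of the random autofluorescence
#'   baseline (<= 5).
#' @param baseline_coeff_sd Numeric vector of length `baseline_order + 1`:
#'   SDs (raw counts) of the zero-mean Gaussian coefficients on a Legendre-style
#'   basis over the scaled wavenumber axis.
#' @param baseline_offset Constant raw-count offset added to every baseline
#'   (keeps raw detector counts positive, as autofluorescence does).
#' @param pixel_noise_sd SD (raw counts) of the additive per-point Gaussian
#'   noise.
#' @param pfa_mean,pfa_sd Mean (> 0) and SD of the log-normal per-cell raw
#'   amplitude of the 1040 cm^-1 PFA band.
#' @param pfa_fwhm FWHM of the PFA band in cm^-1.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_name, peaks, baseline_order = 3,
                          baseline_coeff_sd = rep(20, baseline_order + 1),
                          baseline_offset = 100,
                          pixel_noise_sd = 1.5,
                          pfa_mean = 100, pfa_sd = 5, pfa_fwhm = 12) {
  if (baseline_order > 5) stop("baseline_order must be <= 5", call. = FALSE)
  if (length(baseline_coeff_sd) != baseline_order + 1) {
    stop("baseline_coeff_sd must have length baseline_order + 1", call. = FALSE)
  }
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0", call. = FALSE)
  if (pfa_mean <= 0) stop("pfa_mean must be > 0", call. = FALSE)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(class_name = class_name, peaks = peaks,
                 baseline_order = baseline_order,
                 baseline_coeff_sd = baseline_coeff_sd,
                 baseline_offset = baseline_offset,
                 pixel_noise_sd = pixel_noise_sd,
                 pfa_mean = pfa_mean, pfa_sd = pfa_sd, pfa_fwhm = pfa_fwhm,
                 amplitude_scale = NULL),
            class = "class_profile")
}

# mean of a unit-height peak shape over the closed band [center-h, center+h]
# on an integer-spaced reference axis
band_shape_mean <- function(peak, band_center, half_width = 2) {
  wn <- seq(band_center - half_width, band_center + half_width, by = 1)
  mean(peak_shape(peak, wn))
}

#' Default generative profiles for HPaSC, iCAF and myCAF
#'
#' Encodes the subtype contrasts reported for induced pancreatic CAFs:
#' iCAF carries the strongest DNA band at 481 cm^-1 and the strongest
#' CH-stretch (lipid) bands at 2811/2896/2910/2950 cm^-1; myCAF is highest at
#' the guanine band (680 cm^-1) and elevated over HPaSC at 481, 830, 992 and
#' 1175 cm^-1; HPaSC is highest at the amide-I bands (1638, 1700 cm^-1); and
#' iCAF has the largest between-cell variability in the 700-800 and
#' 1200-1400 cm^-1 windows. No biological peak lies in the Raman-silent
#' region (1800-2800 cm^-1).
#'
#' The CH-stretch amplitudes are calibrated analytically so that, after
#' default preprocessing (baseline removal, smoothing, PFA normalization),
#' the expected band mean at 2896 +/- 2 cm^-1 equals 4.082 (HPaSC),
#' 5.042 (iCAF) and 3.659 (myCAF): the target is divided among the 2896 peak
#' and the shoulder contributions of its broad neighbours using the closed
#' form of the Gaussian line shape.
#'
#' @param fwhm_fingerprint FWHM (cm^-1) of fingerprint-region peaks.
#' @param fwhm_ch FWHM (cm^-1) of high-wavenumber CH-stretch peaks.
#' @return List of three [class_profile()] objects (HPaSC, iCAF, myCAF).
#' @export
default_profiles <- function(fwhm_fingerprint = 12, fwhm_ch = 40) {
  classes <- c("HPaSC", "iCAF", "myCAF")

  # fingerprint-region amplitudes (post-normalization units) per class,
  # ordered HPaSC / iCAF / myCAF
  fp <- list(
    #        center   HPaSC iCAF myCAF
    `481`  = c(1.2, 2.2, 1.7),   # DNA: iCAF strongest, myCAF > HPaSC
    `680`  = c(1.1, 1.2, 1.8),   # guanine: myCAF strongest
    `717`  = c(1.0, 1.1, 1.0),   # choline / phospholipid head
    `776`  = c(0.9, 1.0, 0.9),   # phosphatidylinositol
    `830`  = c(0.8, 1.0, 1.3),   # nucleic-acid stretch: myCAF > HPaSC
    `992`  = c(0.9, 1.0, 1.4),   # benzene ring: myCAF > HPaSC
    `1004` = c(1.5, 1.5, 1.5),   # phenylalanine (shared)
    `1175` = c(0.7, 0.9, 1.1),   # cytosine/guanine: myCAF > HPaSC
    `1180` = c(0.8, 0.8, 0.8),   # CH3/CH2 twist, lipid/collagen
    `1300` = c(1.0, 1.6, 1.1),   # fatty acid CH deformation
    `1370` = c(0.8, 1.0, 0.9),   # dATP
    `1423` = c(0.7, 0.9, 0.8),   # NH in-plane deformation
    `1506` = c(0.6, 0.8, 0.7),   # cytosine
    `1638` = c(2.4, 1.6, 1.7),   # amide I: HPaSC strongest
    `1690` = c(1.3, 1.0, 1.0),   # C=O stretch amide I
    `1700` = c(1.8, 1.1, 1.2)    # amide I: HPaSC strongest
  )
  # iCAF heterogeneity windows (DNA ring breathing / amide III / lipid)
  icaf_wide_sd <- c(717, 776, 1300, 1370)

  # CH-stretch region: iCAF strongest at every band
  ch_other <- list(
    `2811` = c(1.4, 2.0, 1.2),
    `2910` = c(2.8, 3.5, 2.5),
    `2950` = c(2.4, 3.0, 2.2)
  )
  band_target_2896 <- c(HPaSC = 4.082, iCAF = 5.042, myCAF = 3.659)
  # CH-band amplitude spread per class, sized so the reported per-class
  # percent SDs at 2896 cm^-1 (16.35 / 11.41 / 12.96 %) are reproduced by
  # the combined cell-level (40% of variance) and pixel-level (60%,
  # intracellular heterogeneity) log-normal multipliers; the 2896 band
  # averages two nearly equal-weight peaks, hence the 1/sqrt(2) factor
  ch_total_sd <- c(HPaSC = 0.1635, iCAF = 0.1141, myCAF = 0.1296) * sqrt(2)
  ch_cell_sd <- ch_total_sd * sqrt(0.4)
  ch_pixel_sd <- ch_total_sd * sqrt(0.6)

  profiles <- vector("list", 3L)
  for (i in seq_along(classes)) {
    cls <- classes[i]
    peaks <- list()
    for (cen in names(fp)) {
      center <- as.numeric(cen)
      sd_i <- if (cls == "iCAF" && center %in% icaf_wide_sd) 0.25 else 0.08
      peaks[[length(peaks) + 1L]] <-
        peak_spec(center, fwhm_fingerprint, fp[[cen]][i], sd_i,
                  within_cell_sd = 0.10)
    }
    ch_peaks <- list()
    for (cen in names(ch_other)) {
      ch_peaks[[length(ch_peaks) + 1L]] <-
        peak_spec(as.numeric(cen), fwhm_ch, ch_other[[cen]][i],
                  ch_cell_sd[[cls]], within_cell_sd = ch_pixel_sd[[cls]])
    }
    # solve the 2896 amplitude so the expected normalized band mean hits the
    # class target after subtracting the neighbours' shoulder contributions
    shoulder <- sum(vapply(ch_peaks, function(p) {
      p$mean_amplitude * band_shape_mean(p, 2896)
    }, numeric(1)))
    p2896 <- peak_spec(2896, fwhm_ch, 1, ch_cell_sd[[cls]],
                       within_cell_sd = ch_pixel_sd[[cls]])
    self <- band_shape_mean(p2896, 2896)
    amp2896 <- (band_target_2896[[cls]] - shoulder) / self
    if (amp2896 <= 0) stop("2896 calibration produced a non-positive amplitude")
    p2896$mean_amplitude <- amp2896
    peaks <- c(peaks, ch_peaks, list(p2896),
               list(peak_spec(3400, fwhm_ch, 1.5, 0.08,
                              within_cell_sd = 0.10)))  # OH stretch
    profiles[[i]] <- class_profile(cls, peaks)
  }
  names(profiles) <- classes
  profiles
}

#' Simulation configuration
#'
#' @param grid Wavenumber grid; defaults to [default_grid()].
#' @param cells_per_class Named integer vector of cell counts, one per
#'   profile; defaults to the acquisition design of 8 HPaSC, 10 iCAF and
#'   12 myCAF cells.
#' @param pixels_per_cell Number of map pixels (spectra) per cell (>= 1);
#'   default 100, the minimum map size per cell.
#' @param seed Integer seed; a fixed seed fully determines the dataset.
#' @param profiles List of [class_profile()] objects; defaults to
#'   [default_profiles()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid = default_grid(),
                       cells_per_class = c(HPaSC = 8, iCAF = 10, myCAF = 12),
                       pixels_per_cell = 100,
                       seed = 1L,
                       profiles = default_profiles()) {
  grid <- validate_grid(grid)
  if (length(profiles) == 0L) {
    stop("config error: profiles must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "class_profile")))
  cls <- vapply(profiles, `[[`, character(1), "class_name")
  if (is.null(names(cells_per_class))) {
    if (length(cells_per_class) == 1L) {
      cells_per_class <- stats::setNames(rep(cells_per_class, length(cls)), cls)
    } else names(cells_per_class) <- cls
  }
  if (!setequal(names(cells_per_class), cls)) {
    stop("cells_per_class names must match profile class names", call. = FALSE)
  }
  if (any(cells_per_class < 1)) stop("cells_per_class must be >= 1", call. = FALSE)
  if (pixels_per_cell < 1) stop("pixels_per_cell must be >= 1", call. = FALSE)
  structure(list(grid = grid,
                 cells_per_class = cells_per_class[cls],
                 pixels_per_cell = as.integer(pixels_per_cell),
                 seed = as.integer(seed), profiles = profiles,
                 class_order = cls),
            class = "sim_config")
}

# lognormal with mean 1 and sd s
rlnorm_mean1 <- function(n, s) {
  if (s == 0) return(rep(1, n))
  s2 <- log(1 + s^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# evaluate a Legendre-flavoured polynomial basis on [-1, 1]
poly_basis <- function(grid, order) {
  u <- 2 * (grid - grid[1]) / (grid[length(grid)] - grid[1]) - 1
  outer(u, 0:order, `^`)
}

#' Simulate the Raman map of one cell
#'
#' Draws one log-normal amplitude multiplier per peak for the cell (mean 1,
#' SD = the peak's `between_cell_sd`) and one PFA internal-standard amplitude,
#' then generates `n_pixels` spectra: peak sum times the cell multipliers and
#' per-pixel log-normal multipliers (`within_cell_sd`, intracellular
#' heterogeneity), plus a random per-pixel polynomial autofluorescence
#' baseline, plus additive Gaussian pixel noise. Pixels are laid on an approximately square
#' 0-based grid at unit (1 um) pitch.
#'
#' Uses the current R random number stream; seed the stream (or call through
#' [simulate_dataset()]) for reproducibility.
#'
#' @param profile A [class_profile()].
#' @param n_pixels Number of map pixels (>= 1).
#' @param grid Wavenumber grid.
#' @param cell_id Identifier stamped on every spectrum.
#' @return List of [raman_spectrum()] objects, length `n_pixels`.
#' @export
simulate_cell <- function(profile, n_pixels, grid = default_grid(),
                          cell_id = "cell_1") {
  if (n_pixels < 1) stop("n_pixels must be >= 1", call. = FALSE)
  mat <- simulate_cell_matrix(profile, n_pixels, grid)
  px <- square_pixels(n_pixels)
  lapply(seq_len(n_pixels), function(j) {
    raman_spectrum(grid, mat[j, ], cell_id = cell_id,
                   class_label = profile$class_name,
                   pixel = c(px$x[j], px$y[j]))
  })
}

square_pixels <- function(n) {
  side <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  list(x = idx %% side, y = idx %/% side)
}

# matrix core shared by simulate_cell and simulate_dataset
simulate_cell_matrix <- function(profile, n_pixels, grid) {
  peaks <- profile$peaks
  scale <- profile$amplitude_scale
  if (is.null(scale)) {
    # expected raw PFA band mean at 1040 +/- 2: converts post-normalization
    # amplitudes into raw detector counts
    pfa_ref <- peak_spec(1040, profile$pfa_fwhm, 1, silent_ok = TRUE)
    scale <- profile$pfa_mean * band_shape_mean(pfa_ref, 1040)
  }
  shapes <- t(vapply(peaks, peak_shape, numeric(length(grid)), grid = grid))
  amps <- vapply(peaks, `[[`, numeric(1), "mean_amplitude") * scale
  cell_mult <- vapply(peaks, function(p) rlnorm_mean1(1L, p$between_cell_sd),
                      numeric(1))
  pfa_amp <- rlnorm_mean1(1L, profile$pfa_sd / profile$pfa_mean) * profile$pfa_mean
  pfa <- pfa_amp * peak_shape(peak_spec(1040, profile$pfa_fwhm, 1,
                                        silent_ok = TRUE), grid)
  # pixel-level multipliers: intracellular heterogeneity per peak
  within_sd <- vapply(peaks, `[[`, numeric(1), "within_cell_sd")
  pixel_mult <- vapply(seq_along(peaks), function(k) {
    rlnorm_mean1(n_pixels, within_sd[k])
  }, numeric(n_pixels))
  if (n_pixels == 1L) pixel_mult <- matrix(pixel_mult, nrow = 1L)
  signal <- sweep(pixel_mult, 2L, amps * cell_mult, `*`) %*% shapes
  base_sd <- profile$baseline_coeff_sd
  B <- poly_basis(grid, profile$baseline_order)
  coef <- matrix(stats::rnorm(n_pixels * length(base_sd), 0, base_sd),
                 nrow = length(base_sd), byrow = FALSE)
  baselines <- t(B %*% coef) + profile$baseline_offset
  noise <- if (profile$pixel_noise_sd > 0) {
    matrix(stats::rnorm(n_pixels * length(grid), 0, profile$pixel_noise_sd),
           nrow = n_pixels)
  } else 0
  signal + sweep(baselines + noise, 2L, pfa, `+`)
}

#' Simulate a full multi-class Raman map dataset
#'
#' Generates `cells_per_class` cells for every class profile, each imaged at
#' `pixels_per_cell` map pixels, and stacks the spectra into a
#' [spectral_dataset()]. With the default configuration (8/10/12 cells x 100
#' pixels) this yields 3000 spectra whose post-normalization statistics in
#' the 2896 cm^-1 band match the calibrated subtype targets.
#'
#' Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `spectral_dataset`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  grid <- config$grid
  blocks <- list(); labels <- character(); cells <- character()
  pxs <- list()
  px1 <- square_pixels(config$pixels_per_cell)
  for (profile in config$profiles) {
    cls <- profile$class_name
    for (ci in seq_len(config$cells_per_class[[cls]])) {
      cid <- sprintf("%s_c%02d", cls, ci)
      blocks[[length(blocks) + 1L]] <-
        simulate_cell_matrix(profile, config$pixels_per_cell, grid)
      labels <- c(labels, rep(cls, config$pixels_per_cell))
      cells <- c(cells, rep(cid, config$pixels_per_cell))
      pxs[[length(pxs) + 1L]] <- px1
    }
  }
  mat <- do.call(rbind, blocks)
  rownames(mat) <- sprintf("spec_%04d", seq_len(nrow(mat)))
  spectral_dataset(grid, mat, labels, cells,
                   class_order = config$class_order,
                   pixels = data.frame(x = unlist(lapply(pxs, `[[`, "x")),
                                       y = unlist(lapply(pxs, `[[`, "y"))))
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys: `grid` (`lo`, `hi`, `step`), `cells_per_class` (named
#' map), `pixels_per_cell`, `seed`. Profiles always come from
#' [default_profiles()]; per-peak overrides belong in code, not config.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid)) seq(y$grid$lo, y$grid$hi, by = y$grid$step)
          else default_grid()
  args <- list(grid = grid)
  if (!is.null(y$cells_per_class)) args$cells_per_class <- unlist(y$cells_per_class)
  if (!is.null(y$pixels_per_cell)) args$pixels_per_cell <- y$pixels_per_cell
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(sim_config, args)
}
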
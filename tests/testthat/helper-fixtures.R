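# Shared fixtures, all generated in code.

# small grid containing the PFA band, for preprocessing tests
pp_grid <- function() seq(900, 1200, by = 1)

# reduced simulation: coarse grid covering the key bands, few cells/pixels
small_sim_config <- function(seed = 1L, cells = c(HPaSC = 2, iCAF = 2, myCAF = 2),
                             pixels = 10L) {
  sim_config(grid = seq(300, 3000, by = 1), cells_per_class = cells,
             pixels_per_cell = pixels, seed = seed)
}

# a profile with every stochastic component switched off
quiet_profile <- function(class_name = "A",
                          peaks = list(peak_spec(500, 12, 2),
                                       peak_spec(1100, 12, 1))) {
  peaks <- lapply(peaks, function(p) { p$between_cell_sd <- 0; p })
  class_profile(class_name, peaks, baseline_order = 0,
                baseline_coeff_sd = 0, baseline_offset = 0,
                pixel_noise_sd = 0, pfa_sd = 0)
}

# deterministic expected spectrum for a quiet profile (peak sum + PFA band),
# computed directly from the generative equations
quiet_expected <- function(profile, grid) {
  scale <- profile$pfa_mean *
    cafspec:::band_shape_mean(peak_spec(1040, profile$pfa_fwhm, 1), 1040)
  sig <- rep(0, length(grid))
  for (p in profile$peaks) {
    sig <- sig + p$mean_amplitude * scale * cafspec:::peak_shape(p, grid)
  }
  sig + profile$pfa_mean *
    cafspec:::peak_shape(peak_spec(1040, profile$pfa_fwhm, 1), grid)
}

# tiny labelled dataset with hand-set intensities
toy_dataset <- function(n_per_class = 4, grid = seq(400, 500, by = 10),
                        classes = c("a", "b")) {
  n <- n_per_class * length(classes)
  set.seed(11)
  mat <- matrix(abs(rnorm(n * length(grid), 10, 1)), nrow = n)
  labels <- rep(classes, each = n_per_class)
  cells <- paste0(labels, "_cell", rep(seq_len(n_per_class), length(classes)))
  spectral_dataset(grid, mat, labels, cells, class_order = classes)
}
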
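grid <- pp_grid()

poly_on <- function(grid, coefs) {
  u <- (grid - mean(grid)) / (max(grid) - min(grid))
  drop(outer(u, seq_along(coefs) - 1, `^`) %*% coefs)
}

gauss <- function(grid, center, fwhm, amp) {
  amp * exp(-4 * log(2) * ((grid - center) / fwhm)^2)
}

test_that("a pure polynomial is its own baseline", {
  y <- poly_on(grid, c(50, 10, -20, 8))
  sp <- raman_spectrum(grid, y)
  cfg <- preprocess_config(baseline_order = 3)
  bl <- fit_baseline(sp, cfg)
  expect_lt(max(abs(bl$fitted_values - y)), 1e-6)
  corrected <- correct_baseline(sp, cfg)
  expect_lt(max(abs(corrected$intensities)), 1e-6)
})

test_that("a constant spectrum with order 0 fits that constant", {
  sp <- raman_spectrum(grid, rep(7.5, length(grid)))
  bl <- fit_baseline(sp, preprocess_config(baseline_order = 0))
  expect_lt(max(abs(bl$fitted_values - 7.5)), 1e-9)
})

test_that("baseline under noise-free peaks matches the masked-polyfit oracle", {
  true_bl <- poly_on(grid, c(80, 15, -10))
  peak_amp <- 200
  peaks <- gauss(grid, 960, 12, peak_amp) + gauss(grid, 1040, 12, peak_amp) +
    gauss(grid, 1130, 12, peak_amp)
  sp <- raman_spectrum(grid, true_bl + peaks)
  cfg <- preprocess_config(baseline_order = 2)
  bl <- fit_baseline(sp, cfg)
  expect_lt(max(abs(bl$fitted_values - true_bl)), 0.01 * peak_amp)

  # independent oracle: ordinary polyfit restricted to peak-free channels
  mask <- peaks < 1e-3
  u <- (grid - mean(grid)) / (max(grid) - min(grid))
  fit <- lm((true_bl + peaks)[mask] ~ poly(u[mask], 2, raw = TRUE))
  oracle <- cbind(1, poly(u, 2, raw = TRUE)) %*% coef(fit)
  expect_lt(max(abs(bl$fitted_values - oracle)), 0.01 * peak_amp)

  # peak heights above the baseline survive correction within 1%
  corrected <- correct_baseline(sp, cfg)
  for (cen in c(960, 1040, 1130)) {
    i <- which(grid == cen)
    expect_lt(abs(corrected$intensities[i] - peaks[i]), 0.01 * peak_amp)
  }
})

test_that("baseline correction is nearly idempotent on peak fixtures", {
  true_bl <- poly_on(grid, c(60, -12, 9))
  peaks <- gauss(grid, 1000, 12, 150) + gauss(grid, 1100, 12, 120)
  cfg <- preprocess_config(baseline_order = 2)
  once <- correct_baseline(raman_spectrum(grid, true_bl + peaks), cfg)
  twice <- correct_baseline(once, cfg)
  expect_lt(max(abs(twice$intensities - once$intensities)), 0.01 * 150)
})

test_that("degenerate grids are rejected", {
  sp <- raman_spectrum(c(400, 410, 420), c(1, 2, 3))
  expect_error(fit_baseline(sp, preprocess_config(baseline_order = 5)),
               "fit error")
})

test_that("iterative clipped fit beats one unmasked polyfit on random fixtures", {
  set.seed(202)
  cfg <- preprocess_config(baseline_order = 3)
  u <- (grid - mean(grid)) / (max(grid) - min(grid))
  basis_raw <- cbind(1, poly(u, 3, raw = TRUE))
  wins <- 0L
  for (r in 1:100) {
    true_bl <- poly_on(grid, rnorm(4, 0, c(50, 20, 20, 10)))
    centers <- sample(seq(930, 1170, by = 10), 3)
    y <- true_bl
    for (cen in centers) y <- y + gauss(grid, cen, 12, runif(1, 80, 250))
    modpoly <- fit_baseline(raman_spectrum(grid, y), cfg)$fitted_values
    plain <- drop(basis_raw %*% qr.solve(basis_raw, y))
    rmse <- function(est) sqrt(mean((est - true_bl)^2))
    wins <- wins + (rmse(modpoly) < rmse(plain))
  }
  expect_gte(wins, 95L)
})

test_that("Savitzky-Golay reproduces low-degree polynomials everywhere", {
  y <- poly_on(grid, c(5, 3, -2, 1))   # degree 3 = sg_polyorder
  out <- smooth_spectrum(raman_spectrum(grid, y), preprocess_config())
  expect_lt(max(abs(out$intensities - y)), 1e-9)
})

test_that("Savitzky-Golay noise attenuation matches its convolution weights", {
  n <- 5000
  g <- seq(300, 300 + n - 1, by = 1)
  set.seed(33)
  w <- unclass(signal::sgolay(p = 3, n = 11))[6, ]   # central projection row
  expected_var <- sum(w^2)
  vars <- replicate(8, {
    out <- smooth_spectrum(raman_spectrum(g, rnorm(n)), preprocess_config())
    var(out$intensities[6:(n - 5)])
  })
  expect_equal(mean(vars), expected_var, tolerance = 0.04)
})

test_that("smoothing rejects invalid windows", {
  sp <- raman_spectrum(grid, rnorm(length(grid)))
  expect_error(preprocess_config(sg_window = 10), "odd")
  cfg <- preprocess_config()
  cfg$sg_window <- 10L
  expect_error(smooth_spectrum(sp, cfg), "odd")
  cfg2 <- preprocess_config(sg_window = 501)
  sp_short <- raman_spectrum(seq(400, 500, by = 1), rnorm(101))
  expect_error(smooth_spectrum(sp_short, cfg2), "exceeds grid length")
})

test_that("normalization scales the PFA band mean to exactly one", {
  y <- rep(2, length(grid))
  out <- normalize_pfa(raman_spectrum(grid, y), preprocess_config())
  expect_equal(out$intensities, y / 2)
  band <- grid >= 1038 & grid <= 1042
  expect_equal(mean(out$intensities[band]), 1, tolerance = 1e-15)

  # idempotent and scale-invariant
  again <- normalize_pfa(out, preprocess_config())
  expect_lt(max(abs(again$intensities - out$intensities)), 1e-12)
  scaled <- normalize_pfa(raman_spectrum(grid, 37.5 * y), preprocess_config())
  expect_lt(max(abs(scaled$intensities - out$intensities)), 1e-12)
})

test_that("normalization fails on non-positive or absent bands", {
  y <- rep(1, length(grid))
  y[grid >= 1030 & grid <= 1050] <- 0
  expect_error(normalize_pfa(raman_spectrum(grid, y), preprocess_config()),
               "normalization error")
  sp <- raman_spectrum(seq(2000, 2100, by = 1), rep(1, 101))
  expect_error(normalize_pfa(sp, preprocess_config()), "range error")
})

test_that("dataset preprocessing normalizes every row and keeps metadata", {
  d <- simulate_dataset(small_sim_config(seed = 8L))
  p <- preprocess_dataset(d)
  band <- d$grid >= 1038 & d$grid <= 1042
  bm <- rowMeans(p$intensities[, band])
  expect_lt(max(abs(bm - 1)), 1e-12)
  expect_identical(p$labels, d$labels)
  expect_identical(p$cell_ids, d$cell_ids)
})

test_that("batched preprocessing equals the per-spectrum operations", {
  d <- simulate_dataset(small_sim_config(seed = 9L,
                                         cells = c(HPaSC = 1, iCAF = 1,
                                                   myCAF = 1), pixels = 3L))
  cfg <- preprocess_config()
  p <- preprocess_dataset(d, cfg)
  for (i in c(1L, 5L, 9L)) {
    sp <- get_spectrum(d, i)
    manual <- normalize_pfa(smooth_spectrum(correct_baseline(sp, cfg), cfg),
                            cfg)
    expect_lt(max(abs(p$intensities[i, ] - manual$intensities)), 1e-9)
  }
})

test_that("empty datasets pass through preprocessing untouched", {
  d <- toy_dataset()
  empty <- subset_rows(d, integer(0))
  out <- preprocess_dataset(empty)
  expect_equal(n_spectra(out), 0L)
})

test_that("preprocessing commutes with row permutation", {
  d <- simulate_dataset(small_sim_config(seed = 10L,
                                         cells = c(HPaSC = 1, iCAF = 1,
                                                   myCAF = 1), pixels = 4L))
  perm <- sample(n_spectra(d))
  p1 <- preprocess_dataset(subset_rows(d, perm))
  p2 <- subset_rows(preprocess_dataset(d), perm)
  expect_lt(max(abs(p1$intensities - p2$intensities)), 1e-9)
  expect_identical(p1$cell_ids, p2$cell_ids)
})

test_that("noise estimation recovers the injected white-noise scale", {
  set.seed(44)
  base <- poly_on(grid, c(100, 20, -15))
  y <- base + gauss(grid, 1040, 12, 300) + rnorm(length(grid), 0, 2.5)
  expect_equal(estimate_noise_sd(y), 2.5, tolerance = 0.25)
  expect_equal(estimate_noise_sd(base), 0, tolerance = 1e-8)
})
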
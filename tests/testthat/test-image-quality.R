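# Measurement procedures: averaging/subtraction, the two SNR definitions,
# bar-target contrast, the MTF resolution limit, and dynamic range.

test_that("average_subtract is exact on constant shifts and checks shapes", {
  base <- matrix(runif(400, 50, 150), 20)
  a <- noisy_stack(base, 5)
  expect_true(all(average_subtract(a, a) == 0))
  b <- a + 13.5
  expect_equal(average_subtract(b, a), matrix(13.5, 20, 20))
  expect_error(average_subtract(a, noisy_stack(matrix(0, 10, 10), 5)),
               "different frame shapes")
})

test_that("residual noise after 10-frame averaging follows variance algebra", {
  cam <- ideal_camera(read_noise_e = 0, offset = 0)
  m <- 400 # photoelectrons per pixel
  s1 <- expose(matrix(m, 90, 90), cam, exposure_settings(1, 10, seed = 21))
  s2 <- expose(matrix(m, 90, 90), cam, exposure_settings(1, 10, seed = 22))
  resid <- average_subtract(s1, s2)
  expect_equal(sd(resid), sqrt(2 * m / 10), tolerance = 0.05)
})

test_that("Lorentzian SNR recovers injected peak-to-noise ratios", {
  set.seed(31)
  npx <- 200
  xs <- seq_len(npx)
  spot <- 500 * 8^2 / ((xs - 97.3)^2 + 8^2) # peak 500, gamma 8 px
  base <- matrix(100, 60, npx)
  on <- array(0, c(60, npx, 10))
  off <- array(0, c(60, npx, 10))
  for (i in 1:10) {
    on[, , i] <- base + matrix(rep(spot, each = 60), 60) +
      matrix(rnorm(60 * npx, 0, 20), 60)
    off[, , i] <- base + matrix(rnorm(60 * npx, 0, 20), 60)
  }
  sub <- average_subtract(on, off)
  res <- snr_lorentzian(sub, off, line = 30)
  expect_equal(res$snr, 25, tolerance = 0.05)       # injected 500/20
  expect_equal(res$fit$center, 97.3, tolerance = 0.02)
  expect_equal(res$fit$width, 8, tolerance = 0.1)
  # doubling the injected peak doubles the SNR
  on2 <- on + array(rep(matrix(rep(spot, each = 60), 60), 10),
                    c(60, npx, 10))
  res2 <- snr_lorentzian(average_subtract(on2, off), off, line = 30)
  expect_equal(res2$snr / res$snr, 2, tolerance = 0.02)
})

test_that("a flat profile fits to near-zero amplitude", {
  set.seed(32)
  off <- array(100 + rnorm(40 * 120 * 8, 0, 10), c(40, 120, 8))
  on <- array(100 + rnorm(40 * 120 * 8, 0, 10), c(40, 120, 8))
  res <- snr_lorentzian(average_subtract(on, off), off, line = 20)
  expect_lt(abs(res$snr), 1.5)
})

test_that("max-gray SNR matches a constructed spike and is scale invariant", {
  set.seed(33)
  off <- array(rnorm(50 * 50 * 10, 100, 5), c(50, 50, 10))
  on <- off
  on[25, 25, ] <- on[25, 25, ] + 50
  s <- snr_max(on, off)
  expect_equal(s$snr, 10, tolerance = 0.1)
  s3 <- snr_max(on * 3, off * 3)
  expect_equal(s3$snr, s$snr, tolerance = 1e-9)
  null <- snr_max(off, off)
  expect_lt(abs(null$signal), 1e-9)
})

test_that("zero background noise is an error, not an SNR", {
  cam <- ideal_camera(read_noise_e = 0, offset = 100)
  on <- expose(matrix(10, 20, 20), cam, exposure_settings(1, 5, seed = 1))
  off <- expose(matrix(0, 20, 20), cam, exposure_settings(1, 5, seed = 2))
  expect_error(snr_max(on, off), "noiseless")
})

test_that("bar contrast equals the closed form on an ideal profile", {
  img <- aligned_bar_image(amp = 200, base = 100)
  res <- mtf_contrast(colMeans(img), 5)
  expect_true(res$found)
  expect_equal(res$contrast, (300 - 100) / (300 + 100))
  flat <- mtf_contrast(rep(100, 80), 5)
  expect_false(flat$found)
  expect_equal(flat$contrast, 0)
})

test_that("bar contrast is invariant under positive rescaling", {
  img <- aligned_bar_image(amp = 150, base = 80, period_px = 12)
  p <- colMeans(img)
  c1 <- mtf_contrast(p, 5)$contrast
  c2 <- mtf_contrast(3.7 * p, 5)$contrast
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("noiseless low-frequency area-sampled contrast matches supersampling", {
  cfg <- config_with_pixel(500)
  f <- 100 # period 20 px
  sc <- make_resolution_target(f, cfg, contrast_amplitude = 100,
                               baseline = 10, phase_um = 0.13,
                               psf_sigma_um = 0)[[1]]
  prof <- colMeans(sc$flux)
  meas <- mtf_contrast(prof, 5, min_sep = 10)
  # supersampled oracle of the same pattern
  x0 <- sc$provenance$pattern_start_um
  period_um <- 1000 / f
  oracle_prof <- vapply(seq_along(prof), function(j) {
    xs <- ((j - 1) + (seq_len(100) - 0.5) / 100) * 0.5 - x0
    inbar <- xs >= 0 & xs < 5 * period_um & (xs %% period_um) < period_um / 2
    10 + 100 * mean(inbar)
  }, numeric(1))
  oracle <- mtf_contrast(oracle_prof, 5, min_sep = 10)
  expect_equal(meas$contrast, oracle$contrast, tolerance = 0.01)
  expect_gte(meas$contrast / ((120 - 10) / (120 + 10)), 0.95)
})

test_that("the cubic x-intercept recovers a linear MTF's root", {
  # images whose measured contrasts sit exactly on MTF(f) = 1 - f/1200
  base <- 100
  a0 <- 300 # reference amplitude -> C(0) = 0.6
  freqs <- c(200, 400, 600, 800, 1000)
  mk <- function(c_target) {
    a <- 2 * base * c_target / (1 - c_target)
    aligned_bar_image(amp = a, base = base, period_px = 10)
  }
  c0 <- a0 / (a0 + 2 * base)
  targets <- lapply(freqs, function(f) mk(c0 * (1 - f / 1200)))
  names(targets) <- freqs
  ref <- aligned_bar_image(amp = a0, base = base, period_px = 10)
  fit <- mtf_curve(targets, ref, frequencies = freqs, c0_fraction = 0.02)
  expect_equal(fit$c0, 0.6, tolerance = 1e-6)
  expect_equal(fit$mtf$mtf, 1 - freqs / 1200, tolerance = 1e-6)
  expect_equal(fit$resolution_limit, 1200, tolerance = 0.01)
})

test_that("an MTF stuck at unity has no resolution limit", {
  img <- aligned_bar_image(amp = 300, base = 100, period_px = 10)
  targets <- list(`100` = img, `200` = img, `300` = img, `400` = img)
  expect_error(mtf_curve(targets, img, c0_fraction = 0.02), "undetermined")
  fit <- mtf_curve(targets, img, c0_fraction = 0.02, require_limit = FALSE)
  expect_true(is.na(fit$resolution_limit))
  expect_true(all(fit$mtf$mtf > 0.95))
})

test_that("fewer than four frequencies cannot anchor a cubic", {
  img <- aligned_bar_image(amp = 300, base = 100)
  expect_error(mtf_curve(list(`100` = img, `200` = img, `300` = img), img),
               "at least 4")
})

test_that("dynamic range is max over clean background mean", {
  img <- matrix(1000, 40, 40)
  set.seed(34)
  img <- img + matrix(rnorm(1600, 0, 1), 40)
  img[10, 10] <- 4500
  roi <- list(rows = 30:39, cols = 30:39)
  dr <- dynamic_range(img, roi)
  expect_equal(as.numeric(dr), 4.5, tolerance = 0.01)
  expect_equal(as.numeric(dynamic_range(img * 2.5, roi)), as.numeric(dr),
               tolerance = 1e-12)
  # constant image: ratio 1
  expect_equal(as.numeric(dynamic_range(matrix(7, 10, 10),
                                        list(rows = 5:9, cols = 5:9))), 1)
  expect_error(dynamic_range(img, list(rows = 5:15, cols = 5:15)),
               "maximum pixel")
  expect_error(dynamic_range(img - 2000, roi), "not positive")
})

test_that("denoised inputs are flagged as not photon calibrated", {
  img <- matrix(100, 20, 20)
  img[3, 3] <- 900
  attr(img, "denoised") <- TRUE
  dr <- dynamic_range(img, list(rows = 12:18, cols = 12:18))
  expect_false(attr(dr, "photon_calibrated"))
})
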
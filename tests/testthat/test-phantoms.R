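# Phantom generators: area-sampled bar targets, analytic spots, cell/EV
# scenes and Brownian time-lapse emitters.

cfg500 <- config_with_pixel(500) # 500 nm grid

test_that("pixel-aligned bars at period 2 px alternate exactly", {
  # period 1 um on a 500 nm grid = 1000 pl/mm, bars aligned to pixels
  sc <- make_resolution_target(1000, cfg500, contrast_amplitude = 80,
                               baseline = 20, psf_sigma_um = 0,
                               margin_um = 2)[[1]]
  row <- sc$flux[1, ]
  x0 <- sc$provenance$pattern_start_um
  first <- round(x0 / 0.5) + 1
  pat <- row[first:(first + 9)]
  expect_equal(pat, rep(c(100, 20), 5))
})

test_that("bar scenes are bounded by baseline and baseline + amplitude", {
  for (f in c(137, 432, 990, 1801)) {
    sc <- make_resolution_target(f, cfg500, contrast_amplitude = 55,
                                 baseline = 7, phase_um = 0.21,
                                 psf_sigma_um = 0)[[1]]
    expect_gte(min(sc$flux), 7)
    expect_lte(max(sc$flux), 62 + 1e-9)
  }
})

test_that("area sampling matches a 100x supersampled oracle", {
  # bar width 1.5 px (period 3 px = 666.7 pl/mm on the 500 nm grid)
  f <- 1000 / 1.5
  sc <- make_resolution_target(f, cfg500, contrast_amplitude = 100,
                               baseline = 0, psf_sigma_um = 0,
                               margin_um = 2)[[1]]
  row <- sc$flux[1, ]
  # supersampled oracle: mean of the continuous square wave over each pixel
  period_um <- 1000 / f
  x0 <- sc$provenance$pattern_start_um
  oracle <- vapply(seq_along(row), function(j) {
    xs <- ((j - 1) + (seq_len(100) - 0.5) / 100) * 0.5 - x0
    inbar <- xs >= 0 & xs < 5 * period_um & (xs %% period_um) < period_um / 2
    100 * mean(inbar)
  }, numeric(1))
  expect_equal(row, oracle, tolerance = 1e-2)
  # the boundary pixel covering half a bar sits at exactly amplitude/2
  expect_true(any(abs(row - 50) < 1e-9))
})

test_that("frequencies beyond grid representability are rejected", {
  expect_error(make_resolution_target(2001, cfg500), "not representable")
})

test_that("Lorentzian and Gaussian spots hit their defining values", {
  # centre snapped to a pixel centre so r = 0 is realised on the grid
  ctr <- c(31.75, 31.75) # (64 - 0.5) * 0.5 um
  sc <- make_spot(cfg500, "lorentzian", peak = 400, width_um = 2,
                  baseline = 50, center_um = ctr, size_px = 128)
  expect_equal(max(sc$flux), 450)
  # at r = gamma (4 px along x) the Lorentzian is at half peak
  expect_equal(sc$flux[64, 64 + 4], 50 + 200)
  g <- make_spot(cfg500, "gaussian", peak = 400, width_um = 2,
                 baseline = 0, center_um = ctr, size_px = 128)
  expect_equal(max(g$flux), 400)
  expect_equal(g$flux[64, 64 + 4], 400 * exp(-0.5))
})

test_that("Lorentzian spot integral over a disk matches the closed form", {
  ctr <- c(31.75, 31.75)
  gam <- 3
  sc <- make_spot(cfg500, "lorentzian", peak = 100, width_um = gam,
                  baseline = 0, center_um = ctr, size_px = 128)
  xs <- (seq_len(128) - 0.5) * 0.5
  r2 <- outer((xs - ctr[2])^2, (xs - ctr[1])^2, "+")
  R <- 25
  num <- sum(sc$flux[r2 <= R^2]) * 0.5^2
  closed <- pi * 100 * gam^2 * log(1 + R^2 / gam^2)
  expect_equal(num, closed, tolerance = 0.01)
})

test_that("cell scenes span the configured dynamic range", {
  empty <- make_cell_scene(cfg500, n_cells = 0,
                           ev_trails = list(n_trails = 0, spacing_um = 4),
                           seed = 1)
  expect_true(all(empty$flux == 0))
  sc <- make_cell_scene(cfg500, n_cells = 1, intracellular_flux = 500,
                        puncta_flux = 250, ev_flux = 5, n_puncta = 3,
                        seed = 42, size_px = 192)
  # peak = cell body + one snapped punctum (separation keeps overlaps tiny)
  expect_equal(max(sc$flux), 750, tolerance = 1e-3)
  expect_equal(sc$provenance$contrast_ratio, 150)
  expect_equal(max(sc$flux) / 5, sc$provenance$contrast_ratio,
               tolerance = 1e-3)
  # reproducible from the seed
  sc2 <- make_cell_scene(cfg500, n_cells = 1, intracellular_flux = 500,
                         puncta_flux = 250, ev_flux = 5, n_puncta = 3,
                         seed = 42, size_px = 192)
  expect_identical(sc$flux, sc2$flux)
})

test_that("Brownian generator obeys its step statistics", {
  # D = 0, no drift: frozen positions
  tl0 <- make_brownian_timelapse(cfg500, n_particles = 3, d_um2_s = 0,
                                 drift_um_s = c(0, 0), n_frames = 5,
                                 seed = 1)
  sp <- split(tl0$truth, tl0$truth$particle)
  for (s in sp) {
    expect_equal(var(s$x_um), 0)
    expect_equal(var(s$y_um), 0)
  }
  # pure drift at 1.3 um/s, dt = 2 s: every step is 2.6 um
  tld <- make_brownian_timelapse(cfg500, n_particles = 1, d_um2_s = 0,
                                 drift_um_s = c(1.3, 0), interval_s = 2,
                                 n_frames = 6, seed = 2)
  s <- tld$truth[order(tld$truth$frame), ]
  expect_equal(diff(s$x_um), rep(2.6, 5))
  expect_equal(diff(s$y_um), rep(0, 5))
  # Brownian mean 2D step = sqrt(pi * D * dt) (Rayleigh mean)
  tlb <- make_brownian_timelapse(cfg500, n_particles = 40, d_um2_s = 0.25,
                                 interval_s = 2, n_frames = 25, seed = 3,
                                 size_px = 256)
  steps <- unlist(lapply(split(tlb$truth, tlb$truth$particle), function(s) {
    s <- s[order(s$frame), ]
    sqrt(diff(s$x_um)^2 + diff(s$y_um)^2)
  }))
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - sqrt(pi * 0.25 * 2)), 3 * se)
})

test_that("timelapse generation is a pure function of parameters and seed", {
  a <- make_brownian_timelapse(cfg500, n_particles = 2, seed = 7)
  b <- make_brownian_timelapse(cfg500, n_particles = 2, seed = 7)
  expect_identical(a$truth, b$truth)
  expect_identical(a$frames[[3]]$flux, b$frames[[3]]$flux)
})
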
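# Optical-train design calculus: magnification, pixel size, brightness,
# flux, resolution, sensor and field-of-view quantities.

qis_cam <- camera_library("qis")
emccd_cam <- camera_library("emccd")

test_that("focal lengths resolve from nominal magnification and stay consistent", {
  obj <- lens_spec("objective", magnification = 40, na = 1.4)
  expect_equal(focal_length(obj), 4.5)
  expect_equal(focal_length(lens_spec("relay", focal_length_mm = 45)), 45)
  expect_error(lens_spec("objective", magnification = 40,
                         focal_length_mm = 5, na = 1.4), "inconsistent")
  expect_error(lens_spec("objective", magnification = 40), "numerical aperture")
  expect_error(lens_spec("relay"), "magnification")
})

test_that("effective magnification follows the two-lens and relay formulas", {
  obj40 <- lens_spec("objective", magnification = 40, na = 1.4)
  tube20 <- lens_spec("tube_objective", magnification = 20, na = 0.45)
  # telescopic train: 40x objective, 20x tube objective, 45/35 relay
  tele <- microscope_config(qis_cam, objective = obj40, tube = tube20,
                            relay = c(45, 35))
  expect_equal(effective_magnification(tele), 2 * 45 / 35, tolerance = 1e-12)
  expect_equal(round_printed(effective_magnification(tele), 2), 2.57)
  expect_equal(round_printed(effective_magnification(tele), 1), 2.6)
  # same two objectives, no relay
  plain <- microscope_config(qis_cam, objective = obj40, tube = tube20)
  expect_equal(effective_magnification(plain), 2.0)
  # identical focal lengths -> unit magnification
  unit <- microscope_config(qis_cam, objective = obj40,
                            tube = lens_spec("tube_objective",
                                             magnification = 40, na = 1.4))
  expect_equal(effective_magnification(unit), 1.0)
  # a relay with f1 = f2 changes nothing
  sym <- microscope_config(qis_cam, objective = obj40, tube = tube20,
                           relay = c(40, 40))
  expect_equal(effective_magnification(sym), effective_magnification(plain))
})

test_that("effective pixel sizes reproduce the benchmark configurations", {
  expect_equal(effective_pixel_size(
    microscope_config(emccd_cam, m_eff = 20, na = 1.45)), 800)
  expect_equal(round(effective_pixel_size(microscope_preset("qiscope_2.6x"))),
               423)
  expect_equal(round_printed(effective_pixel_size(
    microscope_preset("qiscope_6.5x")), 1), 169.2)
  # strictly decreasing in M_eff at fixed pitch
  ms <- c(2, 4, 8, 16, 32)
  px <- vapply(ms, function(m) effective_pixel_size(
    microscope_config(qis_cam, m_eff = m, na = 1.4)), numeric(1))
  expect_true(all(diff(px) < 0))
})

test_that("brightness ratio follows NA^2 / M_eff^2", {
  a <- microscope_config(emccd_cam, m_eff = 20, na = 1.45)
  b <- microscope_preset("qiscope_2.6x")
  expect_equal(brightness_ratio(a, a), 1.0)
  # doubling magnification at fixed NA quarters brightness
  b1 <- microscope_config(qis_cam, m_eff = 2.6, na = 1.4)
  b2 <- microscope_config(qis_cam, m_eff = 5.2, na = 1.4)
  expect_equal(brightness_ratio(b1, b2), 4.0)
  # direct evaluation with the benchmark NA and M_eff values
  expect_equal(brightness_ratio(a, b), (1.45^2 / 20^2) / (1.4^2 / 2.6^2),
               tolerance = 1e-12)
  expect_equal(brightness_ratio(a, b), 0.0181287, tolerance = 1e-4)
})

test_that("photon flux per pixel ratio multiplies brightness by pixel area", {
  lv <- microscope_preset("lv200_emccd_20x")
  qs <- microscope_preset("qiscope_2.6x")
  expect_equal(photon_flux_per_pixel_ratio(lv, lv), 1.0)
  expect_equal(round_printed(photon_flux_per_pixel_ratio(lv, qs), 1), 3.8)
  # halved pitch at identical optics -> quarter flux per pixel
  half_cam <- camera_spec("half", pitch_um = qis_cam$pitch_um / 2,
                          pixels_x = 512, pixels_y = 512, qe = 0.87,
                          read_noise_e = 0.19)
  a <- microscope_config(qis_cam, m_eff = 2.6, na = 1.4)
  b <- microscope_config(half_cam, m_eff = 2.6, na = 1.4)
  expect_equal(photon_flux_per_pixel_ratio(b, a), 0.25)
  # identity: flux ratio = brightness ratio x (d_a/d_b)^2, over a grid
  for (m in c(2, 8, 20)) for (na in c(0.9, 1.4)) {
    x <- microscope_config(emccd_cam, m_eff = m, na = na)
    expect_equal(photon_flux_per_pixel_ratio(x, qs),
                 brightness_ratio(x, qs) *
                   (emccd_cam$pitch_um / qis_cam$pitch_um)^2)
  }
})

test_that("resolution ratio equals the inverse ratio of effective pixel sizes", {
  lv <- microscope_preset("lv200_emccd_20x")
  qs <- microscope_preset("qiscope_2.6x")
  expect_equal(round_printed(resolution_ratio(qs, lv), 2), 1.89)
  expect_equal(resolution_ratio(qs, qs), 1.0)
  expect_equal(resolution_ratio(qs, lv),
               effective_pixel_size(lv) / effective_pixel_size(qs))
  # cross-check from the printed effective pixel sizes
  expect_equal(round_printed(800 / 423, 2), 1.89)
  # reciprocity over arbitrary pairs
  for (m in c(3, 10, 25)) {
    x <- microscope_config(emccd_cam, m_eff = m, na = 1.2)
    expect_equal(resolution_ratio(x, qs) * resolution_ratio(qs, x), 1.0)
  }
})

test_that("sensor metrics match the stated chip dimensions", {
  em <- sensor_metrics(emccd_cam)
  expect_equal(em$side_x_mm, 8.192)
  expect_equal(round_printed(em$area_mm2, 2), 67.11)
  sc <- sensor_metrics(camera_library("scmos"))
  expect_equal(round_printed(sc$area_mm2, 2), 224.28)
  # manufacturer-stated area override is honoured
  expect_equal(sensor_metrics(qis_cam)$area_mm2, 20.25)
  tiny <- camera_spec("tiny", pitch_um = 1, pixels_x = 1, pixels_y = 1,
                      qe = 0.5, read_noise_e = 1)
  expect_equal(sensor_metrics(tiny)$area_mm2, 1e-6)
})

test_that("field of view scales with sensor and inverse magnification", {
  lv <- microscope_config(emccd_cam, m_eff = 20, na = 1.45)
  fov <- field_of_view(lv)
  expect_equal(fov$side_x_um, 409.6)
  expect_equal(fov$diagonal_um, 409.6 * sqrt(2), tolerance = 1e-9)
  lv2 <- microscope_config(emccd_cam, m_eff = 40, na = 1.45)
  fov2 <- field_of_view(lv2)
  expect_equal(fov2$side_x_um, fov$side_x_um / 2)
  expect_equal(fov2$diagonal_um, fov$diagonal_um / 2)
})

test_that("Nyquist limit is 1 / (2 x effective pixel)", {
  expect_equal(nyquist_limit(config_with_pixel(500)), 1000)
  expect_equal(nyquist_limit(config_with_pixel(800)), 625)
  expect_equal(round(nyquist_limit(microscope_preset("qiscope_2.6x"))), 1182)
})

test_that("spec sheets round-trip through YAML", {
  cams <- camera_library()
  expect_setequal(names(cams), c("scmos", "emccd", "qis"))
  expect_true(cams$qis$photon_number_resolving)
  expect_equal(cams$emccd$em_gain, 300)
  cfgs <- microscope_preset()
  expect_true(all(c("lv200_emccd_20x", "qiscope_2.6x", "qiscope_6.5x",
                    "scmos_8x", "emccd_8x", "qis_8x") %in% names(cfgs)))
  # 8x benchmark effective pixels: 812.5 / 2000 / 137.5 nm
  expect_equal(effective_pixel_size(cfgs$scmos_8x), 812.5)
  expect_equal(effective_pixel_size(cfgs$emccd_8x), 2000)
  expect_equal(effective_pixel_size(cfgs$qis_8x), 137.5)
  expect_error(microscope_preset("nope"), "unknown")
})
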
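# Reproducible experiment runners tying the design calculus, phantom
# generators, simulator and measurement procedures together. Every run
# carries a manifest (parameters, seed, package version) sufficient to
# regenerate its outputs bit-for-bit on the deterministic paths.

run_manifest <- function(params, seed = NULL) {
  list(parameters = params, seed = seed,
       package = "qisbench",
       version = as.character(utils::packageVersion("qisbench")),
       r_version = R.version.string)
}

#' Design report comparing two microscope configurations
#'
#' Emits every optical-train design quantity for the pair: effective
#' magnifications and pixel sizes, sensor metrics, fields of view, Nyquist
#' limits, and the brightness, photon-flux-per-pixel and resolution
#' ratios, at full precision alongside the rounding convention an
#' instrument paper would print (one decimal for flux/brightness, two for
#' the resolution ratio).
#'
#' @param config_a,config_b [microscope_config()] objects (a vs b).
#' @return an object of class `design_report`.
#' @export
#' @examples
#' rep <- run_design_report(microscope_preset("lv200_emccd_20x"),
#'                          microscope_preset("qiscope_2.6x"))
#' rep$ratios$photon_flux_per_pixel_printed # 3.8
run_design_report <- function(config_a, config_b) {
  per_config <- function(cfg) {
    list(name = if (is.null(cfg$name)) cfg$camera$name else cfg$name,
         m_eff = effective_magnification(cfg),
         effective_pixel_nm = effective_pixel_size(cfg),
         nyquist_pl_mm = nyquist_limit(cfg),
         sensor = sensor_metrics(cfg$camera),
         fov_um = field_of_view(cfg))
  }
  a <- per_config(config_a)
  b <- per_config(config_b)
  ratios <- list(
    brightness = brightness_ratio(config_a, config_b),
    photon_flux_per_pixel = photon_flux_per_pixel_ratio(config_a, config_b),
    resolution = resolution_ratio(config_a, config_b),
    sensor_area = a$sensor$area_mm2 / b$sensor$area_mm2,
    fov_side = a$fov_um$side_x_um / b$fov_um$side_x_um,
    effective_pixel = a$effective_pixel_nm / b$effective_pixel_nm
  )
  ratios$photon_flux_per_pixel_printed <-
    round_printed(ratios$photon_flux_per_pixel, 1)
  ratios$brightness_printed <- round_printed(ratios$brightness, 1)
  ratios$resolution_printed <- round_printed(ratios$resolution, 2)
  structure(
    list(a = a, b = b, ratios = ratios,
         manifest = run_manifest(list(a = a$name, b = b$name))),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s vs %s\n", x$a$name, x$b$name))
  fmt <- function(cfg) {
    sprintf("  %s: M_eff %.4g, pixel %.4g nm, Nyquist %.4g pl/mm, FOV %.4g um, sensor %.4g mm2\n",
            cfg$name, cfg$m_eff, cfg$effective_pixel_nm, cfg$nyquist_pl_mm,
            cfg$fov_um$side_x_um, cfg$sensor$area_mm2)
  }
  cat(fmt(x$a)); cat(fmt(x$b))
  r <- x$ratios
  cat(sprintf("  photon flux/pixel (a/b): %.6g (printed %.4g)\n",
              r$photon_flux_per_pixel, r$photon_flux_per_pixel_printed))
  cat(sprintf("  brightness (a/b):        %.6g (printed %.4g)\n",
              r$brightness, r$brightness_printed))
  cat(sprintf("  resolution (a/b):        %.6g (printed %.4g)\n",
              r$resolution, r$resolution_printed))
  cat(sprintf("  sensor area / FOV side (a/b): %.4g / %.4g\n",
              r$sensor_area, r$fov_side))
  invisible(x)
}

#' Simulated camera benchmark at equalised photon flux per pixel
#'
#' Emulates the benchmarking protocol: for each camera an illumination
#' spot is imaged with the source on (`n_frames` frames) and off
#' (`n_frames` frames) at the *same* photons per pixel — the neutral-
#' density-filter normalisation of the physical experiment implemented as
#' exact flux scaling. Reports, per camera, the measured maximum-gray and
#' Lorentzian-fit SNRs, the per-pixel Monte-Carlo SNR at the peak photon
#' level, and the closed-form [analytic_snr()] prediction.
#'
#' The default 0.5 photons/pixel puts the comparison in the photon-starved
#' regime bioluminescence actually occupies, where read noise and the EM
#' excess-noise factor — not quantum efficiency — separate the detector
#' classes.
#'
#' @param cameras named list of [camera_spec()]s (default the bundled
#'   library).
#' @param photons_per_pixel peak photons per pixel per exposure after
#'   equalisation.
#' @param exposure_s integration time per frame.
#' @param n_frames frames per on/off stack (default 10).
#' @param seed RNG seed; per-camera sub-seeds are derived from it.
#' @param size_px simulated field size.
#' @param mc_pixels pixels for the Monte-Carlo per-pixel SNR.
#' @return an object of class `benchmark_sim`: `table` (one row per
#'   camera), per-camera `results`, and a `manifest`.
#' @export
run_benchmark_sim <- function(cameras = camera_library(),
                              photons_per_pixel = 0.5, exposure_s = 2,
                              n_frames = 10L, seed = 1L, size_px = 96L,
                              mc_pixels = 2e4) {
  stopifnot(length(cameras) >= 1)
  grid_pitch_um <- 0.8 # sample-plane grid of the shared spot scene
  rows <- lapply(seq_along(cameras), function(i) {
    cam <- cameras[[i]]
    sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
    peak_flux <- photons_per_pixel / exposure_s
    xs <- (seq_len(size_px) - 0.5) * grid_pitch_um
    ctr <- size_px * grid_pitch_um / 2
    r2 <- outer((xs - ctr)^2, (xs - ctr)^2, "+")
    gam <- size_px * grid_pitch_um / 8
    flux <- peak_flux * gam^2 / (r2 + gam^2)
    on <- expose(flux, cam,
                 exposure_settings(exposure_s, n_frames, seed = sub_seed))
    off <- expose(matrix(0, size_px, size_px), cam,
                  exposure_settings(exposure_s, n_frames,
                                    seed = sub_seed + 1L))
    sub <- average_subtract(on, off)
    s_max <- snr_max(on, off)
    s_lor <- tryCatch(snr_lorentzian(sub, off), error = function(e) NULL)
    mc <- monte_carlo_snr(cam, photons_per_pixel, exposure_s,
                          n_pixels = mc_pixels, seed = sub_seed + 2L)
    list(row = data.frame(camera = names(cameras)[i],
                          photons_per_pixel = photons_per_pixel,
                          snr_max = s_max$snr,
                          snr_lorentzian = if (is.null(s_lor)) NA_real_
                          else s_lor$snr,
                          mc_pixel_snr = mc$snr,
                          analytic_snr = analytic_snr(cam, photons_per_pixel,
                                                      exposure_s)),
         snr_max = s_max, snr_lorentzian = s_lor, mc = mc)
  })
  names(rows) <- names(cameras)
  structure(
    list(table = do.call(rbind, lapply(rows, `[[`, "row")),
         results = rows,
         manifest = run_manifest(
           list(cameras = names(cameras),
                photons_per_pixel = photons_per_pixel,
                exposure_s = exposure_s, n_frames = n_frames,
                size_px = size_px, mc_pixels = mc_pixels), seed)),
    class = "benchmark_sim"
  )
}

#' @export
print.benchmark_sim <- function(x, ...) {
  cat("<benchmark_sim> equalised photon flux per pixel:",
      x$table$photons_per_pixel[1], "photons/px\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Simulated bar-target MTF experiment
#'
#' Runs the full resolution-measurement protocol on a simulated
#' pixel-sampling-limited system: generate five-bar targets across a
#' frequency series (sub-pixel phase offset so bars are not grid-aligned),
#' expose each with the configuration's camera (`n_frames` frames,
#' averaged), measure bar contrast, normalise by the zero-frequency
#' contrast of a coarse reference target, and fit the cubic whose
#' x-intercept is the resolution limit. For a pixel-limited system the
#' recovered limit brackets the Nyquist frequency of the effective pixel.
#'
#' @param config a [microscope_config()].
#' @param frequencies spatial frequencies (pl/mm); default 16 steps from
#'   100 up to ~35% past Nyquist.
#' @param contrast_amplitude,baseline bar and background flux
#'   (photons/pixel/s).
#' @param exposure_s,n_frames acquisition settings per frequency.
#' @param seed RNG seed.
#' @return list with the `mtf_fit` (`fit`), the Nyquist limit, their
#'   ratio, and a manifest.
#' @export
run_mtf_experiment <- function(config, frequencies = NULL,
                               contrast_amplitude = 200, baseline = 10,
                               exposure_s = 2, n_frames = 10L, seed = 1L) {
  nyq <- nyquist_limit(config)
  if (is.null(frequencies)) {
    frequencies <- round(seq(100, 1.35 * nyq, length.out = 16L))
  }
  pitch_um <- effective_pixel_size(config) / 1000
  phase_um <- 0.3 * pitch_um # sub-pixel offset: bars not grid-aligned
  scenes <- make_resolution_target(frequencies, config,
                                   contrast_amplitude = contrast_amplitude,
                                   baseline = baseline, phase_um = phase_um)
  ref <- make_resolution_target(min(frequencies) / 2, config,
                                contrast_amplitude = contrast_amplitude,
                                baseline = baseline)[[1]]
  stacks <- lapply(seq_along(scenes), function(i) {
    expose(scenes[[i]], config$camera,
           exposure_settings(exposure_s, n_frames,
                             seed = (seed * 100L + i) %% .Machine$integer.max))
  })
  ref_stack <- expose(ref, config$camera,
                      exposure_settings(exposure_s, n_frames,
                                        seed = (seed * 100L) %% .Machine$integer.max))
  fit <- mtf_curve(stacks, ref_stack, frequencies = frequencies,
                   require_limit = FALSE)
  list(fit = fit, nyquist_pl_mm = nyq,
       limit_over_nyquist = fit$resolution_limit / nyq,
       manifest = run_manifest(
         list(frequencies = frequencies,
              contrast_amplitude = contrast_amplitude, baseline = baseline,
              exposure_s = exposure_s, n_frames = n_frames,
              phase_um = phase_um), seed))
}
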
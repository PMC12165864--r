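#' Exposure settings
#'
#' @param exposure_s integration time per frame, seconds (> 0).
#' @param n_frames number of frames to acquire (>= 1).
#' @param seed integer seed making the acquisition reproducible
#'   bit-for-bit; `NULL` draws from the current RNG stream.
#' @return an object of class `exposure_settings`.
#' @export
exposure_settings <- function(exposure_s = 2, n_frames = 10L, seed = NULL) {
  stopifnot_scalar(exposure_s, "exposure_s", positive = TRUE)
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  structure(list(exposure_s = exposure_s, n_frames = as.integer(n_frames),
                 seed = seed),
            class = "exposure_settings")
}

#' Stochastic electron-multiplication register
#'
#' Draws the amplified output for integer photoelectron counts `n`.
#' The default `"gamma"` model uses the standard continuous approximation:
#' for `n > 0` the output is Gamma(shape `n`, scale `gain`) (zero stays
#' zero). Under Poisson input of mean `lambda` this gives output variance
#' `2 * lambda * gain^2`, i.e. an excess noise factor F^2 of exactly 2.
#' The `"branching"` model simulates the physical register: `stages`
#' serial impact-ionisation stages, each electron duplicating independently
#' with probability `p` chosen so that `(1 + p)^stages = gain`. It is the
#' validation oracle for the gamma approximation (F^2 -> 2 as gain grows).
#'
#' @param n integer vector of input electron counts (>= 0).
#' @param gain mean multiplication factor (> 1).
#' @param method `"gamma"` (default) or `"branching"`.
#' @param stages number of register stages for the branching model
#'   (default 604, a typical frame-transfer EMCCD register length).
#' @return numeric vector of amplified electron counts.
#' @export
em_register <- function(n, gain, method = c("gamma", "branching"),
                        stages = 604L) {
  method <- match.arg(method)
  stopifnot_scalar(gain, "gain", positive = TRUE)
  if (gain <= 1) stop("`gain` must be > 1 for an EM register", call. = FALSE)
  if (any(n < 0)) stop("electron counts must be >= 0", call. = FALSE)
  out <- numeric(length(n))
  pos <- n > 0
  if (!any(pos)) return(out)
  if (method == "gamma") {
    out[pos] <- stats::rgamma(sum(pos), shape = n[pos], scale = gain)
  } else {
    p <- gain^(1 / stages) - 1
    x <- as.numeric(n[pos])
    for (s in seq_len(stages)) {
      x <- x + stats::rbinom(length(x), x, p)
    }
    out[pos] <- x
  }
  out
}

#' Simulate exposure of a photon-flux field
#'
#' Converts a sample-plane photon-rate field into a stack of digital
#' frames through the full detector chain, per frame and pixel:
#' photoelectrons ~ Poisson(flux * QE * t + dark * t); EM amplification
#' (when `em_gain > 1`) via [em_register()], clipped at the register full
#' well; Gaussian read noise (rms `read_noise_e`, post-register electrons);
#' `DN = round(electrons / adc_gain) + offset`, clipped to the ADC range.
#' Photon-number-resolving sensors skip amplification and read noise and
#' report the exact photoelectron count plus offset (ideal counting;
#' an optional `bit_error` probability flips each count by +/-1 electron).
#'
#' @param scene_flux numeric matrix of photon rates at the sensor grid
#'   (photons/pixel/s), or a `qis_scene` from the phantom generators.
#' @param camera a [camera_spec()].
#' @param settings an [exposure_settings()].
#' @param em_method EM-register model passed to [em_register()].
#' @param bit_error probability that a photon-number-resolving readout
#'   miscounts a pixel by one electron (default 0).
#' @return an object of class `frame_stack`: list with `data`
#'   (rows x cols x frames integer array of digital numbers), `saturated`
#'   (logical array, `TRUE` where electrons hit full well or DN hit the
#'   ADC ceiling), `camera`, `exposure_s`, and `effective_pixel_nm`
#'   (carried over from the scene when available).
#' @export
expose <- function(scene_flux, camera, settings = exposure_settings(),
                   em_method = "gamma", bit_error = 0) {
  stopifnot(inherits(camera, "camera_spec"),
            inherits(settings, "exposure_settings"))
  eff_px <- NA_real_
  if (inherits(scene_flux, "qis_scene")) {
    eff_px <- scene_flux$grid_pitch_nm
    scene_flux <- scene_flux$flux
  }
  if (!is.matrix(scene_flux)) scene_flux <- as.matrix(scene_flux)
  if (any(!is.finite(scene_flux)) || any(scene_flux < 0)) {
    stop("photon flux must be finite and >= 0 everywhere", call. = FALSE)
  }
  if (nrow(scene_flux) > camera$pixels_y || ncol(scene_flux) > camera$pixels_x) {
    stop("scene grid exceeds the camera pixel counts", call. = FALSE)
  }
  t <- settings$exposure_s
  mu <- scene_flux * camera$qe * t + camera$dark_e_s * t
  npx <- length(mu)
  dn_max <- 2^camera$bit_depth - 1
  dims <- c(dim(mu), settings$n_frames)
  data <- array(0L, dims)
  sat <- array(FALSE, dims)
  with_seed(settings$seed, {
    for (f in seq_len(settings$n_frames)) {
      ne <- stats::rpois(npx, mu)
      if (camera$photon_number_resolving) {
        e <- pmin(ne, camera$full_well_e)
        if (bit_error > 0) {
          flip <- stats::rbinom(npx, 1L, bit_error) *
            sign(stats::runif(npx) - 0.5)
          e <- pmax(e + flip, 0)
        }
        dn <- e + camera$adc_offset_dn
      } else {
        if (camera$em_gain > 1) {
          e <- em_register(ne, camera$em_gain, method = em_method)
        } else {
          e <- as.numeric(ne)
        }
        e <- pmin(e, camera$full_well_e)
        e_read <- e + stats::rnorm(npx, 0, camera$read_noise_e)
        dn <- round(e_read / camera$adc_gain_e_dn) + camera$adc_offset_dn
      }
      dn_clip <- pmin(pmax(dn, 0), dn_max)
      data[, , f] <- as.integer(dn_clip)
      sat[, , f] <- (e >= camera$full_well_e) | (dn >= dn_max)
    }
  })
  structure(
    list(data = data, saturated = sat, camera = camera,
         camera_name = camera$name, exposure_s = t,
         effective_pixel_nm = eff_px, n_frames = settings$n_frames),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px, %s, %g s/frame\n",
              d[3], d[1], d[2], x$camera_name, x$exposure_s))
  cat(sprintf("  DN range [%d, %d], %.3g%% saturated\n",
              min(x$data), max(x$data), 100 * mean(x$saturated)))
  invisible(x)
}

#' Closed-form per-pixel SNR predictor
#'
#' The analytic oracle for the simulator:
#' \deqn{SNR = \frac{S\,QE}{\sqrt{F^2 (S\,QE + D t) + \sigma_r^2}}}
#' with excess noise factor `F^2 = 2` for an EM camera (the gamma register
#' model has F^2 = 2 exactly) and 1 otherwise, and effective input-referred
#' read noise `sigma_r^2 = (read_noise^2 + adc_gain^2 / 12) / em_gain^2`
#' (the second term is ADC quantisation noise, so the prediction matches
#' the rounded digital output). Photon-number-resolving sensors count
#' ideally, so their `sigma_r` is 0.
#'
#' @param camera a [camera_spec()].
#' @param photons_per_pixel photons incident per pixel over the exposure.
#' @param exposure_s integration time in seconds (enters through dark
#'   current only).
#' @return predicted SNR (dimensionless).
#' @export
analytic_snr <- function(camera, photons_per_pixel, exposure_s = 1) {
  stopifnot(inherits(camera, "camera_spec"))
  if (any(photons_per_pixel < 0)) {
    stop("`photons_per_pixel` must be >= 0", call. = FALSE)
  }
  s <- photons_per_pixel * camera$qe
  f2 <- if (camera$em_gain > 1) 2 else 1
  sigma2 <- if (camera$photon_number_resolving) 0 else {
    # ADC quantisation noise applies when the pre-ADC signal is continuous
    # (read-noise smeared or EM amplified); integer electrons through a
    # unit-gain ADC digitise exactly
    quant <- if (camera$read_noise_e > 0 || camera$em_gain > 1) {
      camera$adc_gain_e_dn^2 / 12
    } else 0
    (camera$read_noise_e^2 + quant) / camera$em_gain^2
  }
  ifelse(s == 0, 0,
         s / sqrt(f2 * (s + camera$dark_e_s * exposure_s) + sigma2))
}

#' Monte-Carlo per-pixel SNR of a simulated camera
#'
#' Simulates a uniform flux field plus a dark reference of the same size,
#' and returns (mean illuminated DN - mean dark DN) / sd(illuminated DN):
#' the dark-subtracted per-pixel SNR, matching what a benchmark measures
#' after background subtraction. Empirical counterpart of
#' [analytic_snr()].
#'
#' @param camera a [camera_spec()].
#' @param photons_per_pixel photons per pixel over the exposure.
#' @param exposure_s integration time, seconds.
#' @param n_pixels number of simulated pixels.
#' @param seed RNG seed.
#' @return list with `snr`, its delta-method standard error `se`,
#'   `mean_dn`, `sd_dn`, `n`.
#' @export
monte_carlo_snr <- function(camera, photons_per_pixel, exposure_s = 1,
                            n_pixels = 1e4, seed = NULL) {
  side <- ceiling(sqrt(n_pixels))
  if (side > min(camera$pixels_x, camera$pixels_y)) {
    side <- min(camera$pixels_x, camera$pixels_y)
  }
  flux <- matrix(photons_per_pixel / exposure_s, side, side)
  st <- expose(flux, camera,
               exposure_settings(exposure_s, n_frames = 1L, seed = seed))
  dark <- expose(matrix(0, side, side), camera,
                 exposure_settings(exposure_s, n_frames = 1L,
                                   seed = if (is.null(seed)) NULL
                                   else seed + 1L))
  dn <- as.numeric(st$data) - mean(dark$data)
  m <- mean(dn)
  s <- stats::sd(dn)
  n <- length(dn)
  snr <- m / s
  # delta-method standard error of mean/sd from sample moments
  mu4 <- mean((dn - m)^4)
  se <- abs(snr) * sqrt(s^2 / (n * m^2) + (mu4 - s^4) / (4 * s^4 * n))
  list(snr = snr, se = se, mean_dn = m, sd_dn = s, n = n)
}

#' Saturation headroom of a detector
#'
#' The maximum input-referred photoelectron count detectable before any
#' clipping — `min(full_well / em_gain, (DN_max - offset) * adc_gain /
#' em_gain)` — divided by the read-noise floor (`read_noise_e`; 1
#' electron, the counting quantum, for an ideal noiseless counter). An EM
#' camera at gain g loses a factor g of headroom, which is why EMCCDs
#' saturate long before photon-counting sensors on the same scene.
#'
#' @param camera a [camera_spec()].
#' @return headroom (dimensionless).
#' @export
saturation_headroom <- function(camera) {
  stopifnot(inherits(camera, "camera_spec"))
  dn_max <- 2^camera$bit_depth - 1
  max_e <- min(camera$full_well_e / camera$em_gain,
               (dn_max - camera$adc_offset_dn) * camera$adc_gain_e_dn /
                 camera$em_gain)
  floor_e <- camera$read_noise_e
  if (floor_e == 0) floor_e <- 1
  max_e / floor_e
}
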
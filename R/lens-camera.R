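#' Lens specification
#'
#' Describes one element of an optical train: an objective, a tube element
#' (either a classic tube lens or a second objective used as tube lens), or
#' one lens of a Keplerian relay pair. Objectives are usually specified by
#' nominal magnification; the focal length then follows from the
#' manufacturer's reference tube length (f = L_ref / M, 180 mm for Olympus
#' objectives). Relay lenses are specified by focal length alone.
#'
#' @param role one of `"objective"`, `"tube_objective"`, `"tube_lens"`,
#'   `"relay"`.
#' @param magnification nominal magnification (dimensionless); may be `NA`
#'   if `focal_length_mm` is given.
#' @param focal_length_mm focal length in mm; may be `NA` if
#'   `magnification` is given (resolved via `reference_tube_length_mm`).
#' @param na numerical aperture; required (> 0) for objectives.
#' @param aperture_mm optional clear-aperture diameter in mm.
#' @param working_distance_mm optional working distance in mm
#'   (informational).
#' @param reference_tube_length_mm tube length used to convert nominal
#'   magnification to focal length (default 180, the Olympus convention).
#' @param name optional label.
#' @return an object of class `lens_spec`.
#' @export
#' @examples
#' obj40 <- lens_spec("objective", magnification = 40, na = 1.4)
#' focal_length(obj40) # 4.5 mm at the 180 mm reference
lens_spec <- function(role = c("objective", "tube_objective", "tube_lens", "relay"),
                      magnification = NA_real_,
                      focal_length_mm = NA_real_,
                      na = NA_real_,
                      aperture_mm = NA_real_,
                      working_distance_mm = NA_real_,
                      reference_tube_length_mm = 180,
                      name = NULL) {
  role <- match.arg(role)
  stopifnot_scalar(reference_tube_length_mm, "reference_tube_length_mm",
                   positive = TRUE)
  if (is.na(magnification) && is.na(focal_length_mm)) {
    stop("a lens needs `magnification` or `focal_length_mm`", call. = FALSE)
  }
  if (!is.na(magnification)) {
    stopifnot_scalar(magnification, "magnification", positive = TRUE)
  }
  if (!is.na(focal_length_mm)) {
    stopifnot_scalar(focal_length_mm, "focal_length_mm", positive = TRUE)
  }
  if (!is.na(magnification) && !is.na(focal_length_mm)) {
    implied <- reference_tube_length_mm / magnification
    if (abs(implied - focal_length_mm) > 1e-9 * focal_length_mm) {
      stop("`magnification` and `focal_length_mm` are inconsistent with the ",
           "reference tube length", call. = FALSE)
    }
  }
  if (role %in% c("objective", "tube_objective")) {
    if (is.na(na) || na <= 0) {
      if (role == "objective") {
        stop("an objective needs a numerical aperture > 0", call. = FALSE)
      }
    }
  }
  if (!is.na(na)) stopifnot_scalar(na, "na", positive = TRUE)
  structure(
    list(role = role,
         magnification = magnification,
         focal_length_mm = focal_length_mm,
         na = na,
         aperture_mm = aperture_mm,
         working_distance_mm = working_distance_mm,
         reference_tube_length_mm = reference_tube_length_mm,
         name = name),
    class = "lens_spec"
  )
}

#' Focal length of a lens element
#'
#' Resolved from the explicit focal length when present, otherwise from the
#' nominal magnification and the manufacturer reference tube length.
#'
#' @param lens a [lens_spec()].
#' @return focal length in mm.
#' @export
focal_length <- function(lens) {
  stopifnot(inherits(lens, "lens_spec"))
  if (!is.na(lens$focal_length_mm)) return(lens$focal_length_mm)
  lens$reference_tube_length_mm / lens$magnification
}

#' @export
print.lens_spec <- function(x, ...) {
  cat(sprintf("<lens_spec> %s%s: f = %.3g mm", x$role,
              if (is.null(x$name)) "" else paste0(" (", x$name, ")"),
              focal_length(x)))
  if (!is.na(x$magnification)) cat(sprintf(", %gx", x$magnification))
  if (!is.na(x$na)) cat(sprintf(", NA %g", x$na))
  cat("\n")
  invisible(x)
}

#' Camera specification
#'
#' A detector spec sheet sufficient to drive both the design calculus
#' (pitch, pixel counts) and the noise simulator (QE, read noise, dark
#' current, EM gain, full well, ADC).
#'
#' @param name detector label.
#' @param pitch_um pixel pitch in micrometres.
#' @param pixels_x,pixels_y pixel counts.
#' @param qe quantum efficiency, fraction in \\[0, 1\\].
#' @param read_noise_e read noise, electrons rms (output-referred; for an
#'   EMCCD this is the raw post-register read noise, so the input-referred
#'   floor is `read_noise_e / em_gain`).
#' @param dark_e_s dark current, electrons/pixel/second.
#' @param em_gain mean electron-multiplication gain (1 = no multiplication;
#'   must be 1 for photon-number-resolving sensors).
#' @param full_well_e full-well capacity in electrons. For an EMCCD this is
#'   the gain-register capacity, the quantity that limits multiplied
#'   signals.
#' @param adc_gain_e_dn ADC conversion, electrons per digital number.
#' @param adc_offset_dn ADC offset in digital numbers.
#' @param bit_depth ADC bit depth (8-32).
#' @param photon_number_resolving logical; `TRUE` for quanta image sensors
#'   whose digital output is the detected photoelectron count.
#' @param sensor_area_mm2 optional manufacturer-stated sensor area override
#'   (mm^2); when present it takes precedence over `pitch x count` in
#'   [sensor_metrics()], which matters when the exact active pixel count is
#'   not public.
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(name, pitch_um, pixels_x, pixels_y, qe,
                        read_noise_e, dark_e_s = 0, em_gain = 1,
                        full_well_e = 1e5, adc_gain_e_dn = 1,
                        adc_offset_dn = 0, bit_depth = 16,
                        photon_number_resolving = FALSE,
                        sensor_area_mm2 = NA_real_) {
  stopifnot_scalar(pitch_um, "pitch_um", positive = TRUE)
  stopifnot_scalar(qe, "qe", positive = TRUE, allow_zero = TRUE)
  if (qe > 1) stop("`qe` must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(read_noise_e, "read_noise_e", positive = TRUE,
                   allow_zero = TRUE)
  stopifnot_scalar(dark_e_s, "dark_e_s", positive = TRUE, allow_zero = TRUE)
  stopifnot_scalar(em_gain, "em_gain", positive = TRUE)
  if (em_gain < 1) stop("`em_gain` must be >= 1", call. = FALSE)
  stopifnot_scalar(full_well_e, "full_well_e", positive = TRUE)
  stopifnot_scalar(adc_gain_e_dn, "adc_gain_e_dn", positive = TRUE)
  if (pixels_x < 1 || pixels_y < 1) {
    stop("pixel counts must be >= 1", call. = FALSE)
  }
  if (bit_depth < 8 || bit_depth > 32) {
    stop("`bit_depth` must lie in [8, 32]", call. = FALSE)
  }
  if (photon_number_resolving && em_gain != 1) {
    stop("photon-number-resolving sensors have no EM register: `em_gain` ",
         "must be 1", call. = FALSE)
  }
  structure(
    list(name = name, pitch_um = pitch_um,
         pixels_x = as.integer(pixels_x), pixels_y = as.integer(pixels_y),
         qe = qe, read_noise_e = read_noise_e, dark_e_s = dark_e_s,
         em_gain = em_gain, full_well_e = full_well_e,
         adc_gain_e_dn = adc_gain_e_dn, adc_offset_dn = adc_offset_dn,
         bit_depth = as.integer(bit_depth),
         photon_number_resolving = isTRUE(photon_number_resolving),
         sensor_area_mm2 = sensor_area_mm2),
    class = "camera_spec"
  )
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf("<camera_spec> %s: %d x %d px at %g um, QE %.2f\n",
              x$name, x$pixels_x, x$pixels_y, x$pitch_um, x$qe))
  cat(sprintf("  read %.3g e- rms, dark %.3g e-/px/s, EM gain %g%s\n",
              x$read_noise_e, x$dark_e_s, x$em_gain,
              if (x$photon_number_resolving) ", photon-number resolving" else ""))
  invisible(x)
}
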
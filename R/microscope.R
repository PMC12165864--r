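#' Microscope configuration (optical train + camera)
#'
#' An optical train is an objective, an optional Keplerian relay pair
#' (objective-side focal length `f1`, camera-side `f2`), a tube element
#' (tube lens or second objective) and a camera. The effective
#' magnification is
#' \deqn{M_{eff} = \frac{f_{tube}}{f_{obj}} \times \frac{f_1}{f_2}}
#' (the relay factor is 1 without a relay). The relay acts on the
#' infinity-space field angles, so its angular magnification `f1/f2`
#' multiplies the two-lens magnification; with `f1 > f2` the relay
#' *demagnifies* the image, squeezing more photons onto each pixel without
#' vignetting the field.
#'
#' Alternatively a configuration may be declared directly from a spec sheet
#' via `m_eff` and `na` (the nominal values an instrument quotes), without
#' a lens train.
#'
#' @param camera a [camera_spec()].
#' @param objective a [lens_spec()] with role `"objective"`; required
#'   unless `m_eff` and `na` are given.
#' @param tube a [lens_spec()] for the tube element.
#' @param relay optional length-2 numeric `c(f1, f2)` in mm, or a list of
#'   two relay [lens_spec()]s (objective-side first).
#' @param m_eff nominal effective magnification (spec-sheet alternative to
#'   a lens train).
#' @param na numerical aperture; taken from the objective when a lens
#'   train is given.
#' @param name optional label.
#' @return an object of class `microscope_config`.
#' @export
#' @examples
#' qis <- camera_spec("qis", pitch_um = 1.1, pixels_x = 4096,
#'                    pixels_y = 4096, qe = 0.87, read_noise_e = 0.19,
#'                    photon_number_resolving = TRUE)
#' cfg <- microscope_config(
#'   camera = qis,
#'   objective = lens_spec("objective", magnification = 40, na = 1.4),
#'   tube = lens_spec("tube_objective", magnification = 20, na = 0.45),
#'   relay = c(45, 35)
#' )
#' effective_magnification(cfg) # 2.571, printed rounded as 2.6
microscope_config <- function(camera, objective = NULL, tube = NULL,
                              relay = NULL, m_eff = NULL, na = NULL,
                              name = NULL) {
  stopifnot(inherits(camera, "camera_spec"))
  if (is.null(objective) && is.null(m_eff)) {
    stop("give either a lens train (`objective` + `tube`) or a nominal ",
         "`m_eff`", call. = FALSE)
  }
  if (!is.null(relay)) {
    if (is.list(relay) && all(vapply(relay, inherits, TRUE, "lens_spec"))) {
      relay <- c(focal_length(relay[[1L]]), focal_length(relay[[2L]]))
    }
    if (!is.numeric(relay) || length(relay) != 2L || any(relay <= 0)) {
      stop("`relay` must be two positive focal lengths c(f1, f2) in mm",
           call. = FALSE)
    }
  }
  if (!is.null(objective)) {
    stopifnot(inherits(objective, "lens_spec"))
    if (is.null(tube)) stop("a lens train needs a `tube` element",
                            call. = FALSE)
    stopifnot(inherits(tube, "lens_spec"))
    if (is.null(na)) na <- objective$na
  }
  if (!is.null(m_eff)) stopifnot_scalar(m_eff, "m_eff", positive = TRUE)
  if (!is.null(na)) stopifnot_scalar(na, "na", positive = TRUE)
  cfg <- structure(
    list(camera = camera, objective = objective, tube = tube,
         relay = relay, m_eff = m_eff, na = na, name = name),
    class = "microscope_config"
  )
  stopifnot_scalar(effective_magnification(cfg), "m_eff", positive = TRUE)
  cfg
}

#' Effective magnification of an optical train
#'
#' Without a relay, `M_eff = f_tube / f_objective`; with a Keplerian relay,
#' `M_eff = (f_tube / f_objective) * (f1 / f2)`. Spec-sheet configurations
#' return their declared nominal value.
#'
#' @param config a [microscope_config()].
#' @return effective magnification (dimensionless).
#' @export
effective_magnification <- function(config) {
  stopifnot(inherits(config, "microscope_config"))
  if (!is.null(config$m_eff)) return(config$m_eff)
  f_obj <- focal_length(config$objective)
  f_tube <- focal_length(config$tube)
  m <- f_tube / f_obj
  if (!is.null(config$relay)) m <- m * config$relay[1L] / config$relay[2L]
  m
}

#' Effective pixel size at the sample plane
#'
#' The sample-plane footprint of one camera pixel: pitch / M_eff.
#'
#' @param config a [microscope_config()].
#' @return effective pixel size in nanometres.
#' @export
#' @examples
#' # 16 um pitch demagnified 20x -> 800 nm sample-plane pixels
effective_pixel_size <- function(config) {
  config$camera$pitch_um * 1000 / effective_magnification(config)
}

config_na <- function(config) {
  na <- config$na
  if (is.null(na) || is.na(na) || na <= 0) {
    stop("configuration has no positive numerical aperture", call. = FALSE)
  }
  na
}

#' Relative image brightness (photons per area)
#'
#' Image-plane brightness scales as `NA^2 / M_eff^2`: photon collection
#' grows with the square of the numerical aperture while demagnification
#' concentrates the same photons onto a smaller image. The proportionality
#' constant cancels in the ratio.
#'
#' @param a,b [microscope_config()] objects.
#' @return brightness of `a` relative to `b` (dimensionless).
#' @export
brightness_ratio <- function(a, b) {
  (config_na(a)^2 / effective_magnification(a)^2) /
    (config_na(b)^2 / effective_magnification(b)^2)
}

#' Relative photon flux per pixel
#'
#' Photon flux per pixel scales as `NA^2 d^2 / M_eff^2` where `d` is the
#' pixel pitch; equivalently brightness times pixel area.
#'
#' @inheritParams brightness_ratio
#' @return photon flux per pixel of `a` relative to `b`.
#' @export
photon_flux_per_pixel_ratio <- function(a, b) {
  brightness_ratio(a, b) * (a$camera$pitch_um / b$camera$pitch_um)^2
}

#' Theoretical spatial-resolution ratio of two sampling-limited microscopes
#'
#' For pixel-sampling-limited systems the resolution limit scales as
#' `M_eff / d`, i.e. inversely with the effective pixel size, so
#' `resolution_ratio(a, b) = (M_a / d_a) / (M_b / d_b)`.
#'
#' @inheritParams brightness_ratio
#' @return resolution of `a` relative to `b` (> 1 means `a` resolves finer
#'   detail).
#' @export
resolution_ratio <- function(a, b) {
  (effective_magnification(a) / a$camera$pitch_um) /
    (effective_magnification(b) / b$camera$pitch_um)
}

#' Physical sensor dimensions
#'
#' Side lengths are pitch times pixel count. When the spec sheet carries a
#' manufacturer-stated `sensor_area_mm2` that value is reported as the
#' area (the stated area is authoritative when the exact active pixel
#' count is not public); otherwise area = side_x * side_y.
#'
#' @param camera a [camera_spec()].
#' @return list with `side_x_mm`, `side_y_mm`, `diagonal_mm`, `area_mm2`.
#' @export
sensor_metrics <- function(camera) {
  stopifnot(inherits(camera, "camera_spec"))
  sx <- camera$pitch_um * camera$pixels_x / 1000
  sy <- camera$pitch_um * camera$pixels_y / 1000
  area <- if (!is.na(camera$sensor_area_mm2)) camera$sensor_area_mm2 else sx * sy
  list(side_x_mm = sx, side_y_mm = sy,
       diagonal_mm = sqrt(sx^2 + sy^2), area_mm2 = area)
}

#' Sensor-limited field of view at the sample plane
#'
#' Sensor side lengths (and diagonal) divided by the effective
#' magnification. Vignetting by internal apertures is not modelled, so
#' this is an upper bound for trains whose relay does not fully clear the
#' field.
#'
#' @param config a [microscope_config()].
#' @return list with `side_x_um`, `side_y_um`, `diagonal_um`.
#' @export
field_of_view <- function(config) {
  m <- effective_magnification(config)
  s <- sensor_metrics(config$camera)
  list(side_x_um = s$side_x_mm * 1000 / m,
       side_y_um = s$side_y_mm * 1000 / m,
       diagonal_um = s$diagonal_mm * 1000 / m)
}

#' Nyquist sampling limit at the sample plane
#'
#' The highest spatial frequency representable by the pixel sampling,
#' `1 / (2 * effective pixel size)`, in line pairs per mm. Contextualises
#' measured bar-target resolution limits.
#'
#' @param config a [microscope_config()].
#' @return Nyquist limit in line pairs per mm.
#' @export
nyquist_limit <- function(config) {
  1 / (2 * effective_pixel_size(config) * 1e-6) # nm -> mm
}

#' @export
print.microscope_config <- function(x, ...) {
  cat(sprintf("<microscope_config>%s camera %s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name, ":"),
              x$camera$name))
  cat(sprintf("  M_eff %.4g, effective pixel %.4g nm, Nyquist %.4g pl/mm\n",
              effective_magnification(x), effective_pixel_size(x),
              nyquist_limit(x)))
  fov <- field_of_view(x)
  cat(sprintf("  FOV %.4g x %.4g um (diag %.4g um)\n",
              fov$side_x_um, fov$side_y_um, fov$diagonal_um))
  invisible(x)
}
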
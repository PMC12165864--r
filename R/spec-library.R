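#' Read camera spec sheets from a YAML file
#'
#' The file maps spec ids to camera fields; units are encoded in the key
#' names (`pitch_um`, `read_noise_e`, `dark_e_s`, ...). See the bundled
#' file `system.file("extdata/specs/cameras.yaml", package = "qisbench")`
#' for the schema.
#'
#' @param path YAML file path.
#' @return named list of [camera_spec()] objects.
#' @export
read_camera_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) do.call(camera_spec, x))
  names(out) <- names(raw)
  out
}

#' Bundled camera spec library
#'
#' Spec sheets for the three detector classes compared throughout the
#' package: a scientific CMOS (`"scmos"`), an electron-multiplying CCD
#' (`"emccd"`, EM gain 300) and a photon-number-resolving quanta image
#' sensor (`"qis"`).
#'
#' @param name optional spec id; omit to get the whole named list.
#' @return a [camera_spec()] or a named list of them.
#' @export
#' @examples
#' camera_library("emccd")
camera_library <- function(name = NULL) {
  specs <- read_camera_specs(
    system.file("extdata", "specs", "cameras.yaml", package = "qisbench",
                mustWork = TRUE))
  if (is.null(name)) return(specs)
  if (!name %in% names(specs)) {
    stop(sprintf("unknown camera spec '%s'; available: %s", name,
                 paste(names(specs), collapse = ", ")), call. = FALSE)
  }
  specs[[name]]
}

#' Read microscope configurations from a YAML file
#'
#' Each entry names a camera spec id (resolved against `cameras`) plus a
#' nominal `m_eff` and `na`.
#'
#' @param path YAML file path.
#' @param cameras named list of [camera_spec()]s used to resolve the
#'   `camera` field of each entry.
#' @return named list of [microscope_config()] objects.
#' @export
read_microscope_configs <- function(path, cameras = camera_library()) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    cam <- if (is.character(x$camera)) cameras[[x$camera]] else x$camera
    if (is.null(cam)) {
      stop(sprintf("microscope '%s' names unknown camera '%s'", nm,
                   x$camera), call. = FALSE)
    }
    microscope_config(camera = cam, m_eff = x$m_eff, na = x$na, name = nm)
  })
  names(out) <- names(raw)
  out
}

#' Bundled microscope configurations
#'
#' The benchmark configurations used throughout the package, declared from
#' their nominal spec-sheet values:
#' * `"scmos_8x"`, `"emccd_8x"`, `"qis_8x"` — the three cameras behind the
#'   same 8x optical train (effective pixels 812.5, 2000 and 137.5 nm);
#' * `"lv200_emccd_20x"` — 100x oil objective (NA 1.45) with a 5x-reducing
#'   tube lens onto the EMCCD (effective pixel 800 nm);
#' * `"qiscope_2.6x"` — the telescopic train: 40x oil objective (NA 1.4),
#'   Keplerian relay, 20x tube objective, onto the QIS (effective pixel
#'   423 nm);
#' * `"qiscope_6.5x"` — higher-resolution telescopic variant (effective
#'   pixel 169.2 nm).
#'
#' @param name optional configuration id; omit for the whole named list.
#' @return a [microscope_config()] or a named list of them.
#' @export
#' @examples
#' effective_pixel_size(microscope_preset("qiscope_2.6x")) # ~423 nm
microscope_preset <- function(name = NULL) {
  cfgs <- read_microscope_configs(
    system.file("extdata", "specs", "microscopes.yaml", package = "qisbench",
                mustWork = TRUE))
  if (is.null(name)) return(cfgs)
  if (!name %in% names(cfgs)) {
    stop(sprintf("unknown microscope preset '%s'; available: %s", name,
                 paste(names(cfgs), collapse = ", ")), call. = FALSE)
  }
  cfgs[[name]]
}
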
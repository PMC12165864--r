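# TIFF and table I/O. Stacks travel as multi-page TIFF (unsigned 16-bit)
# with a JSON metadata sidecar (<path>.json) carrying camera name,
# exposure, grid pitch and scaling, so a round trip regenerates the
# in-memory objects.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as multi-page 16-bit TIFF
#'
#' Digital numbers are stored as uint16; a JSON sidecar records the camera
#' name, exposure and effective pixel size.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  a <- stack$data
  if (max(a) > 65535) stop("digital numbers exceed 16-bit range",
                           call. = FALSE)
  pages <- lapply(seq_len(dim(a)[3]), function(i) a[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = "frame_stack", camera_name = stack$camera_name,
         exposure_s = stack$exposure_s,
         effective_pixel_nm = stack$effective_pixel_nm,
         n_frames = dim(a)[3]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` read when present).
#' @return a `frame_stack` (without the original `camera_spec`).
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) a[, , i] <- pages[[i]]
  meta <- list(camera_name = NA_character_, exposure_s = NA_real_,
               effective_pixel_nm = NA_real_)
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- utils::modifyList(meta, jsonlite::read_json(sp))
  structure(
    list(data = a, saturated = array(FALSE, dim(a)), camera = NULL,
         camera_name = meta$camera_name, exposure_s = meta$exposure_s,
         effective_pixel_nm = meta$effective_pixel_nm,
         n_frames = dim(a)[3]),
    class = "frame_stack"
  )
}

#' Write a scene as 32-bit float TIFF
#'
#' Flux is stored scaled to \\[0, 1\\]; the scale and grid pitch go to the
#' JSON sidecar so [read_scene_tiff()] restores physical units.
#'
#' @param scene a `qis_scene`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "qis_scene"))
  scale <- max(scene$flux, 1e-12)
  tiff::writeTIFF(scene$flux / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(kind = "qis_scene", flux_scale = scale,
         grid_pitch_nm = scene$grid_pitch_nm,
         provenance = scene$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sidecar_path(path))
  new_scene(img * meta$flux_scale, meta$grid_pitch_nm,
            provenance = meta$provenance)
}

#' Write / read particle truth or track tables as CSV
#'
#' Columns: particle_id, frame, t_s, x_um, y_um.
#'
#' @param x a `qis_timelapse` (its truth table), `qis_track`, or
#'   data.frame.
#' @param path CSV path.
#' @return `path` invisibly; `read_track_csv` returns a data.frame.
#' @export
write_track_csv <- function(x, path) {
  df <- if (inherits(x, "qis_timelapse")) {
    data.frame(particle_id = x$truth$particle, frame = x$truth$frame,
               t_s = x$truth$t_s, x_um = x$truth$x_um, y_um = x$truth$y_um)
  } else if (inherits(x, "qis_track")) {
    data.frame(particle_id = 1L, frame = x$points$frame,
               t_s = x$points$t_s, x_um = x$points$x_um,
               y_um = x$points$y_um)
  } else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) utils::read.csv(path)
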
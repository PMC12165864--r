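# Single-particle localisation and linking: intensity-weighted centroids,
# nearest-window frame-to-frame linking (isolated particles need no
# global assignment), mean 2D step speed and Gaussian-fit diameters. Pixel i's physical centre is at (i - 0.5) * pitch, with x
# along columns and y along rows.

roi_indices <- function(center_um, radius_um, pitch_um, nrow_img, ncol_img) {
  ci <- ceiling(center_um[2] / pitch_um)
  cj <- ceiling(center_um[1] / pitch_um)
  half <- ceiling(radius_um / pitch_um)
  list(rows = max(1, ci - half):min(nrow_img, ci + half),
       cols = max(1, cj - half):min(ncol_img, cj + half))
}

#' Locate a single spot by intensity-weighted centroid
#'
#' Subtracts the ROI median as local background, clamps negative weights
#' to zero, and returns the intensity-weighted centroid in micrometres.
#' The ROI counts as spot-free (`found = FALSE`) when its maximum does not
#' exceed the median by `min_mads` robust deviations.
#'
#' @param frame numeric matrix (one image).
#' @param pixel_um pixel size in micrometres.
#' @param roi optional list with `rows`, `cols`; default the whole frame.
#' @param min_mads detection threshold in units of `mad(roi)`.
#' @return list with `found`, `x_um`, `y_um`.
#' @export
locate_spot <- function(frame, pixel_um, roi = NULL, min_mads = 3) {
  if (is.null(roi)) roi <- list(rows = seq_len(nrow(frame)),
                                cols = seq_len(ncol(frame)))
  sub <- frame[roi$rows, roi$cols, drop = FALSE]
  med <- stats::median(sub)
  spread <- stats::mad(sub)
  if (max(sub) <= med + min_mads * spread) {
    return(list(found = FALSE, x_um = NA_real_, y_um = NA_real_))
  }
  w <- pmax(sub - med, 0)
  xs <- (roi$cols - 0.5) * pixel_um
  ys <- (roi$rows - 0.5) * pixel_um
  tot <- sum(w)
  list(found = TRUE,
       x_um = sum(colSums(w) * xs) / tot,
       y_um = sum(rowSums(w) * ys) / tot)
}

timelapse_frames <- function(stack) {
  if (inherits(stack, "qis_timelapse")) {
    return(list(frames = lapply(stack$frames, function(s) s$flux),
                interval_s = stack$interval_s,
                pixel_um = stack$grid_pitch_nm / 1000))
  }
  if (inherits(stack, "frame_stack")) {
    a <- stack$data
    return(list(frames = lapply(seq_len(dim(a)[3]), function(i) a[, , i]),
                interval_s = stack$exposure_s,
                pixel_um = stack$effective_pixel_nm / 1000))
  }
  stop("expected a qis_timelapse or frame_stack", call. = FALSE)
}

#' Track a single particle through a time-lapse
#'
#' Starting from a seed position in frame 1, each subsequent frame is
#' searched within a window of `search_radius_um` around the previous
#' position and the spot re-located by [locate_spot()]. The track
#' terminates at the first frame where no spot is found. The mean 2D
#' "diffusion velocity" is the average Euclidean step length divided by
#' the frame interval (as the measured-image procedure defines it; note
#' this statistic depends on the interval for Brownian motion).
#'
#' @param stack a `qis_timelapse` (noiseless scenes) or `frame_stack`
#'   (simulated/recorded frames; the frame exposure is taken as the
#'   interval).
#' @param start_um length-2 seed position `(x, y)` in micrometres.
#' @param search_radius_um half-width of the search window.
#' @param interval_s frame interval; defaults to the stack's.
#' @param pixel_um pixel size; defaults to the stack's.
#' @param min_mads detection threshold forwarded to [locate_spot()].
#' @return an object of class `qis_track`: `points` (frame, t_s, x_um,
#'   y_um), `mean_velocity_um_s`, `n_steps`.
#' @export
track_particle <- function(stack, start_um, search_radius_um = 4,
                           interval_s = NULL, pixel_um = NULL,
                           min_mads = 3) {
  tl <- timelapse_frames(stack)
  if (is.null(interval_s)) interval_s <- tl$interval_s
  if (is.null(pixel_um)) pixel_um <- tl$pixel_um
  if (is.null(pixel_um) || is.na(pixel_um)) {
    stop("pixel size unknown; pass `pixel_um`", call. = FALSE)
  }
  frames <- tl$frames
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  pos <- start_um
  pts <- list()
  for (f in seq_along(frames)) {
    roi <- roi_indices(pos, search_radius_um, pixel_um, nr, nc)
    loc <- locate_spot(frames[[f]], pixel_um, roi, min_mads = min_mads)
    if (!loc$found) break
    # refine with the window recentred on the first estimate, so the
    # truncated tails are symmetric about the spot rather than about the
    # previous position
    roi2 <- roi_indices(c(loc$x_um, loc$y_um), search_radius_um, pixel_um,
                        nr, nc)
    loc2 <- locate_spot(frames[[f]], pixel_um, roi2, min_mads = min_mads)
    if (loc2$found) loc <- loc2
    pos <- c(loc$x_um, loc$y_um)
    pts[[f]] <- data.frame(frame = f, t_s = (f - 1) * interval_s,
                           x_um = pos[1], y_um = pos[2])
  }
  if (length(pts) < 2) {
    stop("track too short: particle lost before frame 2", call. = FALSE)
  }
  points <- do.call(rbind, pts)
  steps <- sqrt(diff(points$x_um)^2 + diff(points$y_um)^2)
  structure(
    list(points = points, steps_um = steps,
         mean_velocity_um_s = mean(steps) / interval_s,
         n_steps = length(steps), interval_s = interval_s),
    class = "qis_track"
  )
}

#' @export
print.qis_track <- function(x, ...) {
  cat(sprintf("<qis_track> %d positions, %d steps, mean velocity %.4g um/s\n",
              nrow(x$points), x$n_steps, x$mean_velocity_um_s))
  invisible(x)
}

#' @export
plot.qis_track <- function(x, ...) {
  plot(x$points$x_um, x$points$y_um, type = "o", pch = 19,
       xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  invisible(x)
}

#' MSD-based diffusion coefficient (extension to the mean-speed readout)
#'
#' For free 2D Brownian motion the lag-1 mean squared displacement is
#' `4 D dt`, so `D = MSD / (4 dt)`. Unlike the mean step speed, this
#' estimator does not depend on the frame interval.
#'
#' @param track a `qis_track`.
#' @return estimated D in um^2/s.
#' @export
estimate_diffusion <- function(track) {
  stopifnot(inherits(track, "qis_track"))
  mean(track$steps_um^2) / (4 * track$interval_s)
}

#' Particle diameter from a Gaussian line-profile fit
#'
#' Fits `baseline + A * exp(-(x - x0)^2 / (2 sigma^2))` to a 1D profile
#' through the particle (default: the horizontal line through the frame's
#' brightest pixel) and reports the full width at half maximum,
#' `2 sqrt(2 ln 2) * sigma`, in nanometres. Apparent diameters at or below
#' the instrument's resolution limit are censored: the limit is reported
#' with `censored = TRUE`, since the optics, not the particle, set the
#' width.
#'
#' @param frame numeric matrix.
#' @param pixel_nm pixel size in nanometres.
#' @param line optional row index of the profile.
#' @param resolution_limit_nm optional instrument limit for censoring.
#' @return list with `diameter_nm`, `censored`, `sigma_nm`, `fit`
#'   (baseline, amplitude, center_px, sigma_px), `label`.
#' @export
particle_diameter <- function(frame, pixel_nm, line = NULL,
                              resolution_limit_nm = NULL) {
  if (is.null(line)) {
    line <- which(frame == max(frame), arr.ind = TRUE)[1, "row"]
  }
  y <- as.numeric(frame[line, ])
  x <- seq_along(y)
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - x0)^2 / (2 * s^2)),
      start = list(b = b0, a = max(y) - b0, x0 = which.max(y), s = 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Gaussian fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  sigma_nm <- abs(unname(cf["s"])) * pixel_nm
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_nm
  censored <- !is.null(resolution_limit_nm) && fwhm <= resolution_limit_nm
  list(diameter_nm = if (censored) resolution_limit_nm else fwhm,
       censored = censored, sigma_nm = sigma_nm,
       fit = list(baseline = unname(cf["b"]), amplitude = unname(cf["a"]),
                  center_px = unname(cf["x0"]), sigma_px = abs(unname(cf["s"]))),
       label = if (censored) sprintf("<=%g nm", resolution_limit_nm)
       else sprintf("%.0f nm", fwhm))
}
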
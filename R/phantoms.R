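# Synthetic photon-flux scenes. All generators are pure functions of
# (parameters, seed) and return `qis_scene` objects: a non-negative flux
# field (photons/pixel/s at the sensor grid), the grid pitch at the sample
# plane, and a provenance record of every parameter used.

new_scene <- function(flux, grid_pitch_nm, provenance = list()) {
  if (any(!is.finite(flux)) || any(flux < 0)) {
    stop("scene flux must be finite and >= 0", call. = FALSE)
  }
  structure(list(flux = flux, grid_pitch_nm = grid_pitch_nm,
                 provenance = provenance),
            class = "qis_scene")
}

#' @export
print.qis_scene <- function(x, ...) {
  cat(sprintf("<qis_scene> %d x %d px at %.4g nm, flux [%.4g, %.4g] ph/px/s\n",
              nrow(x$flux), ncol(x$flux), x$grid_pitch_nm,
              min(x$flux), max(x$flux)))
  invisible(x)
}

# Cumulative bright measure of a bar pattern: total length of bright bar
# within [pattern start, u]. Bars are `nb` stripes of width P/2 at period P.
bar_cumulative <- function(u, period, nb) {
  u <- pmax(pmin(u, nb * period), 0)
  k <- pmin(floor(u / period), nb - 1)
  k * period / 2 + pmin(u - k * period, period / 2)
}

# Default PSF stand-in width: 0.25 * lambda / NA at lambda = 460 nm (blue
# bioluminescence), in micrometres. Empirical Gaussian, not a diffraction
# model.
default_psf_sigma_um <- function(config, lambda_nm = 460) {
  na <- tryCatch(config_na(config), error = function(e) NA_real_)
  if (is.na(na)) return(0)
  0.25 * lambda_nm / na / 1000
}

#' Five-bar resolution-target scenes
#'
#' For each spatial frequency, a pattern of `bar_count` parallel bright
#' vertical bars (square-wave profile, 50% duty cycle). Each pixel's flux
#' is the exact area average of the continuous pattern over the pixel
#' footprint (analytic integration, not point sampling), so contrast loss
#' near the Nyquist limit reflects physical pixel sampling. An optional
#' Gaussian pre-blur stands in for the optical point-spread function
#' (default width `0.25 * 460 nm / NA`); with blur the pixel average is
#' computed by dense sub-pixel quadrature of the blurred profile.
#'
#' @param frequencies spatial frequencies in line pairs per mm at the
#'   sample plane; each must be below `1 / grid pitch` (twice the Nyquist
#'   limit) to be representable on the grid.
#' @param config a [microscope_config()] fixing the grid pitch.
#' @param bar_count number of bars (default 5).
#' @param contrast_amplitude bar flux above baseline (photons/pixel/s).
#' @param baseline background flux.
#' @param phase_um lateral offset of the first bar edge from the left
#'   margin, in micrometres (tests phase sensitivity near Nyquist).
#' @param height_px image height in pixels.
#' @param margin_um dark margin on each side of the bar set.
#' @param psf_sigma_um Gaussian blur width in micrometres; `NULL` for the
#'   NA-derived default, 0 for none.
#' @return named list mapping frequency to `qis_scene`.
#' @export
make_resolution_target <- function(frequencies, config, bar_count = 5L,
                                   contrast_amplitude = 100, baseline = 10,
                                   phase_um = 0, height_px = 48L,
                                   margin_um = NULL, psf_sigma_um = NULL) {
  pitch_um <- effective_pixel_size(config) / 1000
  if (is.null(psf_sigma_um)) psf_sigma_um <- default_psf_sigma_um(config)
  if (any(frequencies >= 1000 / pitch_um)) {
    stop("frequency at or above 1/(grid pitch) is not representable",
         call. = FALSE)
  }
  if (bar_count < 2) stop("`bar_count` must be >= 2", call. = FALSE)
  out <- lapply(frequencies, function(f) {
    period_um <- 1000 / f
    pat_len <- bar_count * period_um
    marg <- if (is.null(margin_um)) max(2 * period_um, 5 * pitch_um) else margin_um
    width_um <- pat_len + 2 * marg + phase_um
    ncols <- ceiling(width_um / pitch_um)
    edges <- (0:ncols) * pitch_um
    x0 <- marg + phase_um
    if (psf_sigma_um > 0) {
      nsub <- 16L
      xs <- (rep(seq_len(ncols) - 1, each = nsub) +
               (seq_len(nsub) - 0.5) / nsub) * pitch_um
      prof_pts <- blurred_bar_profile(xs - x0, period_um, bar_count,
                                      psf_sigma_um)
      cov <- colMeans(matrix(prof_pts, nrow = nsub))
    } else {
      cum <- bar_cumulative(edges - x0, period_um, bar_count)
      cov <- diff(cum) / pitch_um
    }
    row <- baseline + contrast_amplitude * cov
    flux <- matrix(rep(row, each = height_px), nrow = height_px)
    new_scene(flux, pitch_um * 1000,
              provenance = list(kind = "resolution_target",
                                frequency_pl_mm = f, bar_count = bar_count,
                                contrast_amplitude = contrast_amplitude,
                                baseline = baseline, phase_um = phase_um,
                                psf_sigma_um = psf_sigma_um,
                                pattern_start_um = x0))
  })
  names(out) <- as.character(frequencies)
  out
}

# Gaussian-blurred bar indicator evaluated at positions x (um, relative to
# the pattern start).
blurred_bar_profile <- function(x, period, nb, sigma) {
  v <- numeric(length(x))
  for (k in 0:(nb - 1)) {
    v <- v + stats::pnorm((x - k * period) / sigma) -
      stats::pnorm((x - k * period - period / 2) / sigma)
  }
  v
}

#' Radially symmetric illumination spot
#'
#' Lorentzian (`baseline + peak * gamma^2 / (r^2 + gamma^2)`, `gamma` =
#' `width_um`) or Gaussian (`baseline + peak * exp(-r^2 / (2 width^2))`)
#' profile on the sensor grid — the shape the profile-fit SNR procedure
#' assumes for a focused illumination field.
#'
#' @param config a [microscope_config()] fixing the grid pitch.
#' @param profile `"lorentzian"` or `"gaussian"`.
#' @param peak peak flux above baseline (photons/pixel/s, >= 0).
#' @param width_um half-width gamma (Lorentzian) or sigma (Gaussian), um.
#' @param baseline background flux.
#' @param center_um length-2 spot centre `(x, y)` in um; default field
#'   centre.
#' @param size_px field size in pixels (rows = cols).
#' @return a `qis_scene`.
#' @export
make_spot <- function(config, profile = c("lorentzian", "gaussian"),
                      peak = 100, width_um = 5, baseline = 0,
                      center_um = NULL, size_px = 128L) {
  profile <- match.arg(profile)
  stopifnot_scalar(peak, "peak", positive = TRUE, allow_zero = TRUE)
  stopifnot_scalar(width_um, "width_um", positive = TRUE)
  pitch_um <- effective_pixel_size(config) / 1000
  if (is.null(center_um)) center_um <- rep(size_px * pitch_um / 2, 2)
  xs <- (seq_len(size_px) - 0.5) * pitch_um
  r2 <- outer((xs - center_um[2])^2, (xs - center_um[1])^2, "+")
  flux <- if (profile == "lorentzian") {
    baseline + peak * width_um^2 / (r2 + width_um^2)
  } else {
    baseline + peak * exp(-r2 / (2 * width_um^2))
  }
  new_scene(flux, pitch_um * 1000,
            provenance = list(kind = "spot", profile = profile, peak = peak,
                              width_um = width_um, baseline = baseline,
                              center_um = center_um))
}

# Adds Gaussian emitters of given amplitude/sigma (um) at centers (um) to a
# flux matrix; physical coordinates put pixel i's centre at (i - 0.5) * pitch.
add_gaussian_spots <- function(flux, centers_um, amplitude, sigma_um,
                               pitch_um) {
  n <- nrow(flux); m <- ncol(flux)
  half <- ceiling(5 * sigma_um / pitch_um)
  for (i in seq_len(nrow(centers_um))) {
    cx <- centers_um[i, 1]; cy <- centers_um[i, 2]
    ci <- ceiling(cy / pitch_um); cj <- ceiling(cx / pitch_um)
    ri <- max(1, ci - half):min(n, ci + half)
    rj <- max(1, cj - half):min(m, cj + half)
    if (!length(ri) || !length(rj)) next
    dy <- ((ri - 0.5) * pitch_um - cy)^2
    dx <- ((rj - 0.5) * pitch_um - cx)^2
    flux[ri, rj] <- flux[ri, rj] +
      amplitude * exp(-outer(dy, dx, "+") / (2 * sigma_um^2))
  }
  flux
}

snap_to_pixel_center <- function(xy, pitch_um) {
  (floor(xy / pitch_um) + 0.5) * pitch_um
}

#' Bioluminescent cell scene with extracellular vesicle structure
#'
#' Emulates the structure of a luciferase-expressing cell field: bright
#' elliptical cell bodies with intracellular Gaussian puncta (lysosome- or
#' multivesicular-body-like), plus faint extracellular point emitters
#' arranged along linear trails (migrasome-like) — intensities spanning
#' the detector dynamic range. Placement is reproducible from the seed;
#' punctum and vesicle centres snap to pixel centres so configured peak
#' fluxes are realised exactly on the grid.
#'
#' @param config a [microscope_config()] fixing the grid pitch.
#' @param n_cells number of cell bodies.
#' @param intracellular_flux cell-body flux (photons/pixel/s).
#' @param puncta_flux peak flux of intracellular puncta, added on top of
#'   the cell body.
#' @param ev_flux peak flux of extracellular vesicles (should be far below
#'   `intracellular_flux` to span the dynamic range).
#' @param n_puncta puncta per cell.
#' @param ev_trails list with `n_trails` and `spacing_um` (emitter spacing
#'   along each trail).
#' @param seed RNG seed (placement).
#' @param size_px field size in pixels.
#' @param cell_radius_um mean cell semi-axis, um.
#' @return a `qis_scene`; `provenance$contrast_ratio` records the
#'   configured peak-to-vesicle flux ratio
#'   `(intracellular_flux + puncta_flux) / ev_flux`.
#' @export
make_cell_scene <- function(config, n_cells = 3L, intracellular_flux = 500,
                            puncta_flux = 250, ev_flux = 5,
                            n_puncta = 4L,
                            ev_trails = list(n_trails = 2L, spacing_um = 4),
                            seed = NULL, size_px = 256L,
                            cell_radius_um = 12) {
  for (v in c(intracellular_flux, puncta_flux, ev_flux)) {
    stopifnot_scalar(v, "flux", positive = TRUE, allow_zero = TRUE)
  }
  pitch_um <- effective_pixel_size(config) / 1000
  fw <- size_px * pitch_um
  flux <- matrix(0, size_px, size_px)
  xs <- (seq_len(size_px) - 0.5) * pitch_um
  cells <- NULL
  with_seed(seed, {
    if (n_cells > 0) {
      cells <- cbind(x = stats::runif(n_cells, 0.15 * fw, 0.85 * fw),
                     y = stats::runif(n_cells, 0.15 * fw, 0.85 * fw),
                     a = cell_radius_um * stats::runif(n_cells, 0.8, 1.2),
                     b = cell_radius_um * stats::runif(n_cells, 0.5, 0.9),
                     th = stats::runif(n_cells, 0, pi))
      for (i in seq_len(n_cells)) {
        dx <- outer(rep(1, size_px), xs - cells[i, "x"])
        dy <- outer(xs - cells[i, "y"], rep(1, size_px))
        u <- dx * cos(cells[i, "th"]) + dy * sin(cells[i, "th"])
        v <- -dx * sin(cells[i, "th"]) + dy * cos(cells[i, "th"])
        inside <- (u / cells[i, "a"])^2 + (v / cells[i, "b"])^2 <= 1
        flux[inside] <- intracellular_flux
        # puncta: separated Gaussian peaks inside the body
        placed <- matrix(numeric(0), 0, 2)
        sig <- 1.0 # um
        tries <- 0
        while (nrow(placed) < n_puncta && tries < 200) {
          tries <- tries + 1
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * 0.7
          px <- cells[i, "x"] + rad * cells[i, "a"] * cos(ang)
          py <- cells[i, "y"] + rad * cells[i, "b"] * sin(ang)
          p <- snap_to_pixel_center(c(px, py), pitch_um)
          if (nrow(placed) == 0 ||
              min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 5 * sig) {
            placed <- rbind(placed, p)
          }
        }
        if (nrow(placed) > 0) {
          flux <- add_gaussian_spots(flux, placed, puncta_flux, sig, pitch_um)
        }
      }
    }
    nt <- ev_trails$n_trails
    if (!is.null(nt) && nt > 0) {
      in_cell <- function(p) {
        if (is.null(cells)) return(FALSE)
        any(vapply(seq_len(nrow(cells)), function(i) {
          dx <- p[1] - cells[i, "x"]; dy <- p[2] - cells[i, "y"]
          u <- dx * cos(cells[i, "th"]) + dy * sin(cells[i, "th"])
          v <- -dx * sin(cells[i, "th"]) + dy * cos(cells[i, "th"])
          (u / (cells[i, "a"] + 2))^2 + (v / (cells[i, "b"] + 2))^2 <= 1
        }, TRUE))
      }
      for (tr in seq_len(nt)) {
        p0 <- c(stats::runif(1, 0.05 * fw, 0.95 * fw),
                stats::runif(1, 0.05 * fw, 0.95 * fw))
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.2, 0.5) * fw
        npts <- max(2L, floor(len / ev_trails$spacing_um))
        pts <- t(vapply(seq_len(npts) - 1L, function(k) {
          p0 + k * ev_trails$spacing_um * c(cos(ang), sin(ang))
        }, numeric(2)))
        keep <- pts[, 1] > 0 & pts[, 1] < fw & pts[, 2] > 0 & pts[, 2] < fw
        keep <- keep & !apply(pts, 1, in_cell)
        if (any(keep)) {
          pts <- pts[keep, , drop = FALSE]
          pts <- t(apply(pts, 1, snap_to_pixel_center, pitch_um = pitch_um))
          flux <- add_gaussian_spots(flux, pts, ev_flux, 0.5, pitch_um)
        }
      }
    }
  })
  new_scene(flux, pitch_um * 1000,
            provenance = list(kind = "cell_scene", n_cells = n_cells,
                              intracellular_flux = intracellular_flux,
                              puncta_flux = puncta_flux, ev_flux = ev_flux,
                              ev_trails = ev_trails, seed = seed,
                              contrast_ratio = if (ev_flux > 0)
                                (intracellular_flux + puncta_flux) / ev_flux
                              else NA_real_))
}

#' Brownian point-emitter time-lapse
#'
#' Per particle and axis, positions follow
#' `x[t+1] = x[t] + drift * dt + N(0, 2 * D * dt)`; emitters are rendered
#' as Gaussian spots and the ground-truth trajectory is recorded in
#' micrometres (pixel centres at `(i - 0.5) * pitch`).
#'
#' @param config a [microscope_config()] fixing the grid pitch.
#' @param n_particles number of emitters.
#' @param d_um2_s diffusion coefficient D, um^2/s (>= 0).
#' @param drift_um_s length-2 drift velocity (um/s).
#' @param interval_s frame interval dt, seconds.
#' @param n_frames number of frames (>= 2).
#' @param emitter_flux peak flux per emitter (photons/pixel/s).
#' @param psf_sigma_um rendered spot width, um.
#' @param baseline background flux.
#' @param seed RNG seed.
#' @param size_px field size in pixels.
#' @return an object of class `qis_timelapse`: list of per-frame
#'   `qis_scene`s, the frame interval, and `truth`
#'   (data.frame: particle, frame, t_s, x_um, y_um).
#' @export
make_brownian_timelapse <- function(config, n_particles = 1L, d_um2_s = 0.25,
                                    drift_um_s = c(0, 0), interval_s = 2,
                                    n_frames = 10L, emitter_flux = 200,
                                    psf_sigma_um = 0.8, baseline = 0,
                                    seed = NULL, size_px = 128L) {
  stopifnot_scalar(d_um2_s, "d_um2_s", positive = TRUE, allow_zero = TRUE)
  stopifnot_scalar(interval_s, "interval_s", positive = TRUE)
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  pitch_um <- effective_pixel_size(config) / 1000
  fw <- size_px * pitch_um
  step_sd <- sqrt(2 * d_um2_s * interval_s)
  pos <- NULL
  truth <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  with_seed(seed, {
    pos <- cbind(stats::runif(n_particles, 0.2 * fw, 0.8 * fw),
                 stats::runif(n_particles, 0.2 * fw, 0.8 * fw))
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        pos <- pos + matrix(drift_um_s * interval_s, n_particles, 2,
                            byrow = TRUE) +
          matrix(stats::rnorm(2 * n_particles, 0, step_sd), n_particles, 2)
        # reflect at the field boundary so particles stay in view
        pos <- abs(pos)
        pos <- fw - abs(fw - pos)
      }
      flux <- matrix(baseline, size_px, size_px)
      flux <- add_gaussian_spots(flux, pos, emitter_flux, psf_sigma_um,
                                 pitch_um)
      frames[[f]] <- new_scene(flux, pitch_um * 1000,
                               provenance = list(kind = "brownian_frame",
                                                 frame = f))
      truth[[f]] <- data.frame(particle = seq_len(n_particles), frame = f,
                               t_s = (f - 1) * interval_s,
                               x_um = pos[, 1], y_um = pos[, 2])
    }
  })
  structure(
    list(frames = frames, interval_s = interval_s,
         truth = do.call(rbind, truth), grid_pitch_nm = pitch_um * 1000,
         provenance = list(n_particles = n_particles, d_um2_s = d_um2_s,
                           drift_um_s = drift_um_s, interval_s = interval_s,
                           n_frames = n_frames, emitter_flux = emitter_flux,
                           psf_sigma_um = psf_sigma_um, seed = seed)),
    class = "qis_timelapse"
  )
}

#' @export
print.qis_timelapse <- function(x, ...) {
  cat(sprintf("<qis_timelapse> %d frames at dt = %g s, %d particle(s)\n",
              length(x$frames), x$interval_s,
              max(x$truth$particle)))
  invisible(x)
}
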
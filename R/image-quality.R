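# Measurement procedures for benchmark images: frame averaging with
# background subtraction, the two SNR definitions (Lorentzian profile fit
# and maximum gray value, both against laser-off background noise), the
# bar-target MTF pipeline with a cubic-fit resolution limit, and the
# max/background dynamic-range ratio.

frames_array <- function(x) {
  if (inherits(x, "frame_stack")) return(x$data)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a frame_stack, matrix, or rows x cols x frames array",
       call. = FALSE)
}

#' Pixel-wise frame average
#'
#' @param stack a `frame_stack`, matrix, or 3D array.
#' @return matrix of per-pixel means.
#' @export
frame_average <- function(stack) {
  a <- frames_array(stack)
  rowMeans(a, dims = 2L)
}

#' Average frames and subtract the averaged background
#'
#' Pixel-wise mean over signal frames minus pixel-wise mean over
#' background frames. Negative values are retained — clipping would bias
#' the noise statistics of the difference image.
#'
#' @param signal_stack,background_stack `frame_stack`s (or arrays) of
#'   equal frame shape.
#' @return numeric matrix (digital numbers; may be negative).
#' @export
average_subtract <- function(signal_stack, background_stack) {
  s <- frames_array(signal_stack)
  b <- frames_array(background_stack)
  if (!identical(dim(s)[1:2], dim(b)[1:2])) {
    stop("signal and background stacks have different frame shapes",
         call. = FALSE)
  }
  rowMeans(s, dims = 2L) - rowMeans(b, dims = 2L)
}

#' Background noise: mean of per-frame global standard deviations
#'
#' The noise figure used by both SNR procedures: each background
#' ("laser off") frame contributes its whole-frame standard deviation,
#' and the per-frame values are averaged. An ROI variant is available via
#' `roi` but the whole frame is the default.
#'
#' @param background_stack a `frame_stack` or 3D array.
#' @param roi optional list with integer vectors `rows` and `cols`.
#' @return noise in digital numbers.
#' @export
background_noise <- function(background_stack, roi = NULL) {
  b <- frames_array(background_stack)
  if (!is.null(roi)) b <- b[roi$rows, roi$cols, , drop = FALSE]
  mean(apply(b, 3L, stats::sd))
}

new_snr_fit <- function(signal, noise, method, fit = NULL, profile = NULL,
                        photon_calibrated = TRUE) {
  structure(list(signal = signal, noise = noise, snr = signal / noise,
                 method = method, fit = fit, profile = profile,
                 photon_calibrated = photon_calibrated),
            class = "snr_fit")
}

#' @export
print.snr_fit <- function(x, ...) {
  cat(sprintf("<snr_fit> method %s: signal %.4g DN, noise %.4g DN, SNR %.4g\n",
              x$method, x$signal, x$noise, x$snr))
  if (!is.null(x$fit)) {
    cat(sprintf("  Lorentzian fit: peak %.4g, center %.4g px, width %.4g px, baseline %.4g\n",
                x$fit$peak, x$fit$center, x$fit$width, x$fit$baseline))
  }
  if (!x$photon_calibrated) {
    cat("  note: input was denoised; values are not photon counts\n")
  }
  invisible(x)
}

#' @export
coef.snr_fit <- function(object, ...) {
  c(signal = object$signal, noise = object$noise, snr = object$snr)
}

#' SNR from a Lorentzian profile fit
#'
#' Least-squares fit of `baseline + peak * g^2 / ((x - x0)^2 + g^2)` to
#' the horizontal intensity profile of the background-subtracted average
#' image at a given row. The signal is the fitted peak amplitude above
#' baseline; the noise is [background_noise()] of the off stack; their
#' ratio is the SNR.
#'
#' @param subtracted background-subtracted averaged image
#'   (from [average_subtract()]).
#' @param background_stack the off ("laser off") `frame_stack`.
#' @param line row index of the profile; default the centre row.
#' @return an `snr_fit` with the Lorentzian parameters in `$fit`.
#' @export
snr_lorentzian <- function(subtracted, background_stack, line = NULL) {
  if (!is.matrix(subtracted)) stop("`subtracted` must be a matrix",
                                   call. = FALSE)
  if (is.null(line)) line <- ceiling(nrow(subtracted) / 2)
  if (line < 1 || line > nrow(subtracted)) {
    stop("`line` is outside the image", call. = FALSE)
  }
  y <- as.numeric(subtracted[line, ])
  x <- seq_along(y)
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  a0 <- max(y) - b0
  if (a0 <= 0) a0 <- max(abs(y - b0), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * g^2 / ((x - x0)^2 + g^2),
      start = list(b = b0, a = a0, x0 = which.max(y),
                   g = max(length(y) / 10, 2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Lorentzian fit did not converge: ", conditionMessage(e),
           "\n  profile range [", signif(min(y), 4), ", ",
           signif(max(y), 4), "], n = ", length(y), call. = FALSE)
    })
  cf <- stats::coef(fit)
  noise <- background_noise(background_stack)
  if (noise <= 0) stop("noiseless input: background noise is zero",
                       call. = FALSE)
  new_snr_fit(signal = unname(cf["a"]), noise = noise,
              method = "lorentzian_peak",
              fit = list(peak = unname(cf["a"]), center = unname(cf["x0"]),
                         width = abs(unname(cf["g"])),
                         baseline = unname(cf["b"])),
              profile = y,
              photon_calibrated = !isTRUE(attr(subtracted, "denoised")))
}

#' SNR from the maximum gray value
#'
#' The signal is the maximum of the background-subtracted averaged on
#' image; the noise is [background_noise()] of the off stack.
#'
#' @param on_stack,off_stack `frame_stack`s with the source on and off.
#' @return an `snr_fit` with method `"max_gray"`.
#' @export
snr_max <- function(on_stack, off_stack) {
  subtracted <- average_subtract(on_stack, off_stack)
  noise <- background_noise(off_stack)
  if (noise <= 0) stop("noiseless input: background noise is zero",
                       call. = FALSE)
  new_snr_fit(signal = max(subtracted), noise = noise, method = "max_gray")
}

moving_average3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  s <- y
  s[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  s
}

# Local maxima of a vector with plateau handling: equal-value runs are
# collapsed and a run is a peak when both neighbouring runs are lower; the
# run's centre index is returned. Edge runs are never peaks.
find_local_maxima <- function(s) {
  r <- rle(s)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(v)
  if (k < 3) return(integer(0))
  idx <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1
  floor((starts[idx] + ends[idx]) / 2)
}

#' Bar-target contrast from a profile
#'
#' Identifies `expected_bars` peaks and the `expected_bars - 1`
#' interleaved troughs in a box-averaged bar profile, averages each group
#' and returns `(I_peak - I_trough) / (I_peak + I_trough)`. Extremum
#' *locations* come from a lightly smoothed copy (moving average, window
#' 3) for robust alternation detection; contrast *values* are read from
#' the unsmoothed profile, so smoothing does not bias the contrast. When
#' the required alternating extrema cannot be found the contrast is
#' reported as 0 with `found = FALSE` rather than dropped, so unresolved
#' frequencies still anchor the MTF fit at zero.
#'
#' @param profile numeric vector: the column-wise mean over a box drawn
#'   across the bar set.
#' @param expected_bars number of bright bars (>= 2; default 5).
#' @param min_sep minimum peak separation in samples; defaults to
#'   `length(profile) / (3 * expected_bars)`. Pass the known half-period
#'   when the frequency is known.
#' @param expected_spacing known bar period in samples (optional). When
#'   given, the mean spacing of the detected peaks must match it within
#'   `max(spacing_tol_frac * period, spacing_tol_px)`; aliased moire
#'   fringes beyond the sampling limit mimic bars at the *wrong* spacing,
#'   and this geometric check rejects them (contrast 0, `found = FALSE`),
#'   as an analyst comparing the image against the printed line spacing
#'   would.
#' @param spacing_tol_frac,spacing_tol_px spacing tolerance (fraction of
#'   the period / absolute samples; the absolute floor absorbs pixel
#'   quantisation of peak positions near Nyquist).
#' @return list with `contrast`, `found`, `i_peak`, `i_trough`, and the
#'   peak/trough indices.
#' @export
mtf_contrast <- function(profile, expected_bars = 5L, min_sep = NULL,
                         expected_spacing = NULL, spacing_tol_frac = 0.15,
                         spacing_tol_px = 0.35) {
  if (expected_bars < 2) stop("`expected_bars` must be >= 2", call. = FALSE)
  y <- as.numeric(profile)
  not_found <- list(contrast = 0, found = FALSE, i_peak = NA_real_,
                    i_trough = NA_real_, peaks = integer(0),
                    troughs = integer(0))
  if (length(y) < 2 * expected_bars + 1) return(not_found)
  if (is.null(min_sep)) min_sep <- length(y) / (3 * expected_bars)
  # The moving average is for robust extremum *location* when bars span
  # many pixels; near Nyquist (half-period < 3 samples) a 3-sample window
  # would erase the modulation itself, so the raw profile is used there.
  s <- if (min_sep >= 3) moving_average3(y) else y
  cand <- find_local_maxima(s)
  if (length(cand) < expected_bars) return(not_found)
  # greedy selection by height with a separation constraint
  ord <- cand[order(s[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
    if (length(sel) == expected_bars) break
  }
  if (length(sel) < expected_bars) return(not_found)
  peaks <- sort(sel)
  if (!is.null(expected_spacing)) {
    mean_spacing <- (peaks[length(peaks)] - peaks[1]) / (length(peaks) - 1)
    tol <- max(spacing_tol_frac * expected_spacing, spacing_tol_px)
    if (abs(mean_spacing - expected_spacing) > tol) return(not_found)
  }
  troughs <- integer(expected_bars - 1L)
  for (k in seq_len(expected_bars - 1L)) {
    span <- (peaks[k] + 1):(peaks[k + 1] - 1)
    if (!length(span)) return(not_found)
    troughs[k] <- span[which.min(y[span])]
  }
  # enforce alternation on the unsmoothed profile
  if (any(y[troughs] >= y[peaks[-length(peaks)]]) ||
      any(y[troughs] >= y[peaks[-1]])) {
    return(not_found)
  }
  i_peak <- mean(y[peaks])
  i_trough <- mean(y[troughs])
  total <- i_peak + i_trough
  contrast <- if (total <= 0) 0 else (i_peak - i_trough) / total
  list(contrast = contrast, found = TRUE, i_peak = i_peak,
       i_trough = i_trough, peaks = peaks, troughs = troughs)
}

# Zero-frequency contrast: (Imax - Imin)/(Imax + Imin) with Imax/Imin the
# means of the brightest/darkest `fraction` of pixels in the reference.
zero_frequency_contrast <- function(reference, fraction = 0.05) {
  img <- frame_average(reference)
  v <- sort(as.numeric(img))
  k <- max(1L, round(fraction * length(v)))
  i_min <- mean(v[seq_len(k)])
  i_max <- mean(v[seq.int(length(v) - k + 1L, length(v))])
  (i_max - i_min) / (i_max + i_min)
}

#' MTF curve and cubic-fit resolution limit
#'
#' For each spatial frequency the frames are averaged, a box profile is
#' taken (column means over `roi_rows`), and the bar contrast `C(f)` is
#' measured with [mtf_contrast()]. `C(0)` comes from the brightest and
#' darkest pixel fractions of the zero-frequency reference, and
#' `MTF(f) = C(f) / C(0)`, clipped to \\[0, 1\\]. A least-squares cubic
#' polynomial is fitted to the measured `(f, MTF)` points and its
#' x-intercept gives the spatial resolution limit. A cubic can have
#' spurious low-frequency roots, so the limit is the smallest real root
#' exceeding the highest frequency whose fitted MTF is at least
#' `root_guard` (default 0.2, configurable).
#'
#' @param targets named list (names = frequencies in pl/mm) of
#'   `frame_stack`s or matrices, one per measured frequency; or pass
#'   `frequencies` explicitly.
#' @param zero_reference `frame_stack` or matrix for the zero-frequency
#'   contrast.
#' @param frequencies numeric frequencies; default `as.numeric(names(targets))`.
#' @param expected_bars bars per target (default 5).
#' @param roi_rows rows of the profile box; default all rows.
#' @param pixel_pitch_nm sample-plane pixel size used to set the peak
#'   separation constraint from each frequency's known period; taken from
#'   the first `frame_stack`'s metadata when available.
#' @param c0_fraction pixel fraction for the zero-frequency contrast.
#' @param root_guard fitted-MTF threshold guarding root selection.
#' @param require_limit error when the fitted cubic has no admissible
#'   positive real root (default `TRUE`).
#' @return an object of class `mtf_fit`: `samples` (frequency, contrast,
#'   found), `c0`, `mtf` (frequency, mtf), `fit_coefficients`,
#'   `resolution_limit` (pl/mm).
#' @export
mtf_curve <- function(targets, zero_reference, frequencies = NULL,
                      expected_bars = 5L, roi_rows = NULL,
                      pixel_pitch_nm = NULL, c0_fraction = 0.05,
                      root_guard = 0.2, require_limit = TRUE) {
  if (is.null(frequencies)) frequencies <- as.numeric(names(targets))
  if (length(targets) != length(frequencies) || anyNA(frequencies)) {
    stop("`targets` must map frequencies (names or `frequencies`) to stacks",
         call. = FALSE)
  }
  if (length(frequencies) < 4) {
    stop("the cubic fit needs at least 4 measured frequencies",
         call. = FALSE)
  }
  if (is.null(pixel_pitch_nm) && inherits(targets[[1]], "frame_stack")) {
    pixel_pitch_nm <- targets[[1]]$effective_pixel_nm
  }
  ord <- order(frequencies)
  frequencies <- frequencies[ord]
  targets <- targets[ord]
  res <- lapply(seq_along(targets), function(i) {
    img <- frame_average(targets[[i]])
    rows <- if (is.null(roi_rows)) seq_len(nrow(img)) else roi_rows
    prof <- colMeans(img[rows, , drop = FALSE])
    min_sep <- NULL
    spacing <- NULL
    if (!is.null(pixel_pitch_nm) && is.finite(pixel_pitch_nm)) {
      period_px <- 1e6 / frequencies[i] / pixel_pitch_nm
      min_sep <- max(period_px / 2, 1)
      spacing <- period_px
    }
    mtf_contrast(prof, expected_bars = expected_bars, min_sep = min_sep,
                 expected_spacing = spacing)
  })
  contrast <- vapply(res, `[[`, numeric(1), "contrast")
  found <- vapply(res, `[[`, logical(1), "found")
  c0 <- zero_frequency_contrast(zero_reference, c0_fraction)
  if (c0 <= 0) stop("zero-frequency contrast is not positive", call. = FALSE)
  mtf <- pmin(pmax(contrast / c0, 0), 1)
  # fit on f / fmax so the cubic coefficients are O(1) and negligible
  # higher-order terms can be zapped before root finding (a run of
  # collinear points otherwise leaves polyroot a near-zero leading
  # coefficient and a spurious far root)
  fmax <- max(frequencies)
  x <- frequencies / fmax
  fit <- stats::lm(mtf ~ x + I(x^2) + I(x^3))
  cs <- stats::coef(fit)
  cs[!is.finite(cs)] <- 0
  cs[abs(cs) < 1e-8 * max(abs(cs))] <- 0
  while (length(cs) > 1 && cs[length(cs)] == 0) cs <- cs[-length(cs)]
  cf <- cs / fmax^(seq_along(cs) - 1) # coefficients on the pl/mm scale
  fitted_at <- function(f) {
    drop(outer(f, seq_along(cf) - 1, "^") %*% cf)
  }
  real_roots <- if (length(cs) > 1) {
    roots <- polyroot(cs)
    Re(roots[abs(Im(roots)) < 1e-6 * pmax(abs(roots), 1)]) * fmax
  } else numeric(0)
  guard_ok <- frequencies[fitted_at(frequencies) >= root_guard]
  f_guard <- if (length(guard_ok)) max(guard_ok) else 0
  adm <- sort(real_roots[real_roots > f_guard])
  limit <- if (length(adm)) adm[1] else NA_real_
  if (is.na(limit) && require_limit) {
    stop("resolution limit undetermined: the fitted cubic has no real ",
         "root above ", signif(f_guard, 4), " pl/mm", call. = FALSE)
  }
  structure(
    list(samples = data.frame(frequency = frequencies, contrast = contrast,
                              found = found),
         c0 = c0,
         mtf = data.frame(frequency = frequencies, mtf = mtf),
         fit = fit,
         fit_coefficients = unname(c(cf, rep(0, 4 - length(cf)))),
         resolution_limit = limit, root_guard = root_guard,
         c0_fraction = c0_fraction, pixel_pitch_nm = pixel_pitch_nm),
    class = "mtf_fit"
  )
}

#' @export
print.mtf_fit <- function(x, ...) {
  cat(sprintf("<mtf_fit> %d frequencies, C(0) = %.4g\n",
              nrow(x$mtf), x$c0))
  cat(sprintf("  resolution limit: %s pl/mm\n",
              if (is.na(x$resolution_limit)) "undetermined"
              else sprintf("%.4g", x$resolution_limit)))
  invisible(x)
}

#' @export
coef.mtf_fit <- function(object, ...) object$fit_coefficients

#' @export
plot.mtf_fit <- function(x, ...) {
  plot(x$mtf$frequency, x$mtf$mtf, xlab = "spatial frequency (pl/mm)",
       ylab = "MTF", ylim = c(0, 1.05), pch = 19, ...)
  fs <- seq(0, max(x$mtf$frequency,
                   x$resolution_limit, na.rm = TRUE) * 1.05, length.out = 200)
  cf <- x$fit_coefficients
  graphics::lines(fs, pmax(cf[1] + cf[2] * fs + cf[3] * fs^2 + cf[4] * fs^3, 0))
  if (!is.na(x$resolution_limit)) {
    graphics::abline(v = x$resolution_limit, lty = 2)
  }
  invisible(x)
}

#' Image dynamic range
#'
#' Ratio of the maximum gray value of the image to the mean over a
#' background region (a small patch of extracellular space free of any
#' signal). Quantifies how large a brightness span one exposure captures
#' without saturating.
#'
#' @param image numeric matrix.
#' @param background_roi list with integer vectors `rows` and `cols`.
#' @return dynamic range (dimensionless); carries attribute
#'   `photon_calibrated = FALSE` when the image was denoised.
#' @export
dynamic_range <- function(image, background_roi) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (is.null(background_roi$rows) || is.null(background_roi$cols) ||
      !length(background_roi$rows) || !length(background_roi$cols)) {
    stop("`background_roi` must provide non-empty `rows` and `cols`",
         call. = FALSE)
  }
  bg <- image[background_roi$rows, background_roi$cols, drop = FALSE]
  mx <- which(image == max(image), arr.ind = TRUE)[1, ]
  if (mx["row"] %in% background_roi$rows && mx["col"] %in% background_roi$cols) {
    stop("`background_roi` contains the maximum pixel; choose a region ",
         "free of signal", call. = FALSE)
  }
  m <- mean(bg)
  if (m <= 0) stop("background mean is not positive", call. = FALSE)
  out <- max(image) / m
  attr(out, "photon_calibrated") <- !isTRUE(attr(image, "denoised"))
  out
}
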
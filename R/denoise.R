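# Data preparation for self-supervised denoising. Only the target
# construction and the display transform are implemented; the networks
# themselves plug in through a named-denoiser registry, and a non-learned
# baseline (the window mean) ships so the pipeline runs end to end.

#' Noise2Noise training pairs by adjacent-frame averaging
#'
#' For each frame with a full window, the semi-noisy target is the exact
#' pixel-wise mean of `window` adjacent frames centred on it. Frames
#' within `(window - 1) / 2` of either end are excluded rather than given
#' a shrunken window, keeping the target noise level uniform across
#' pairs. Sums are accumulated in double-precision integers before the
#' single division, so targets equal the brute-force window means
#' bit-for-bit.
#'
#' Averaged targets are flagged `denoised`: their values are no longer
#' detected photon counts.
#'
#' @param stack a `frame_stack` or rows x cols x frames array (>= `window`
#'   frames).
#' @param window odd window length >= 3 (default 7).
#' @return list with `inputs` (array of the retained noisy frames),
#'   `targets` (float array of window means, attribute `denoised`),
#'   `kept_frames` (indices into the original stack), `window`.
#' @export
n2n_targets <- function(stack, window = 7L) {
  a <- frames_array(stack)
  n <- dim(a)[3]
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  if (n < window) {
    stop(sprintf("stack has %d frames but the window needs %d", n, window),
         call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  kept <- seq.int(half + 1L, n - half)
  targets <- array(0, c(dim(a)[1:2], length(kept)))
  for (k in seq_along(kept)) {
    i <- kept[k]
    acc <- a[, , i - half]
    for (j in (i - half + 1L):(i + half)) acc <- acc + a[, , j]
    targets[, , k] <- acc / window
  }
  attr(targets, "denoised") <- TRUE
  list(inputs = a[, , kept, drop = FALSE], targets = targets,
       kept_frames = kept, window = window)
}

#' Gamma display transform
#'
#' Min-max normalises an image to \\[0, 1\\] and raises it to `gamma`.
#' Display-only: the output compresses bright structure so faint
#' extracellular signal is visible alongside saturating cell bodies, and
#' must never feed back into quantitative metrics. A constant image maps
#' to zeros with attribute `degenerate = TRUE`.
#'
#' @param image numeric matrix.
#' @param gamma exponent > 0; values < 1 brighten the dim end.
#' @return matrix in \\[0, 1\\] with attribute `denoised = TRUE` (the
#'   values are display units, not photons).
#' @export
gamma_display <- function(image, gamma = 0.5) {
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    attr(out, "denoised") <- TRUE
    return(out)
  }
  out <- ((image - rng[1]) / (rng[2] - rng[1]))^gamma
  attr(out, "denoised") <- TRUE
  out
}

denoiser_registry <- new.env(parent = emptyenv())

#' Register / retrieve pluggable denoisers
#'
#' A denoiser is any function mapping a rows x cols x frames array to an
#' array of the same shape (or a matrix for single frames). The learned
#' networks used in practice register here; the built-in
#' `"window_mean"` baseline (the 7-frame running mean itself) keeps the
#' pipeline runnable without training. Denoiser output is flagged
#' `denoised`.
#'
#' @param name denoiser id.
#' @param fn the denoising function (for `register_denoiser`).
#' @return `get_denoiser` returns the wrapped function;
#'   `list_denoisers` the registered names.
#' @export
register_denoiser <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = denoiser_registry)
  invisible(name)
}

#' @rdname register_denoiser
#' @export
get_denoiser <- function(name) {
  if (!exists(name, envir = denoiser_registry, inherits = FALSE)) {
    stop(sprintf("no denoiser '%s' registered; see list_denoisers()", name),
         call. = FALSE)
  }
  fn <- get(name, envir = denoiser_registry)
  function(x, ...) {
    out <- fn(frames_array(x), ...)
    attr(out, "denoised") <- TRUE
    out
  }
}

#' @rdname register_denoiser
#' @export
list_denoisers <- function() ls(denoiser_registry)

# built-in baseline: running window mean (edge frames passed through)
register_denoiser("window_mean", function(a, window = 7L) {
  n <- dim(a)[3]
  if (n < window) return(a)
  out <- a * 1.0
  res <- n2n_targets(a, window)
  out[, , res$kept_frames] <- res$targets
  out
})
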
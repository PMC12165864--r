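#' Round to printed precision (half away from zero)
#'
#' Design ratios are reported both at full precision and rounded the way
#' instrument papers print them: ties go away from zero, so 2.575 at one
#' decimal is 2.6, not the banker's 2.57 -> 2.6 / 2.58 behaviour of
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 1).
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @export
#' @examples
#' round_printed(1.890909, 2) # 1.89
#' round_printed(3.835, 1)    # 3.8
round_printed <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && !allow_zero && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (positive && allow_zero && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
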
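#' Round half away from zero
#'
#' Deterministic rounding used throughout the package so that generated
#' images are bit-exact across platforms (base `round()` rounds half to
#' even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Clamp intensities to the 8-bit range
#'
#' @param x numeric vector or matrix.
#' @param lo,hi range bounds.
#' @return `x` with values forced into `[lo, hi]`.
#' @keywords internal
clamp <- function(x, lo = 0, hi = 255) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Quantize a numeric matrix to integer 8-bit intensities.
quantize8 <- function(x) {
  x <- clamp(round_half_away(x))
  storage.mode(x) <- "integer"
  x
}

#' Validate a grayscale image matrix
#'
#' A grayscale image is a numeric matrix whose entries are integers in
#' `[0, 255]`. Multi-channel arrays are rejected rather than converted:
#' the agent model is defined on 256 scalar states.
#'
#' @param image object to check.
#' @param arg name used in error messages.
#' @return the image, invisibly, with integer storage.
#' @keywords internal
as_gray_image <- function(image, arg = "image") {
  if (length(dim(image)) == 3L) {
    stop(sprintf("`%s` has %d channels; only single-channel images are supported",
                 arg, dim(image)[3L]), call. = FALSE)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(image)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (any(image < 0) || any(image > 255)) {
    stop(sprintf("`%s` has intensities outside [0, 255]", arg), call. = FALSE)
  }
  if (any(image != floor(image))) {
    stop(sprintf("`%s` has non-integer intensities", arg), call. = FALSE)
  }
  storage.mode(image) <- "integer"
  image
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards. `seed = NULL`
# uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
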
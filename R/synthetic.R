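#' Built-in region layouts for synthetic test images
#'
#' Ground-truth region maps used by the synthetic-image generator. Three
#' geometries are provided: a vertical half-plane split (two regions),
#' equal vertical bands (any number of regions), and a concentric square
#' (an inner square covering half the image side length inside a
#' background region).
#'
#' @param height,width image dimensions in pixels.
#' @param regions number of vertical bands for `layout_bands()`.
#' @return integer matrix of region ids `1..R` with `height` rows.
#' @examples
#' table(layout_bands(8, 9, 3))
#' @export
layout_split <- function(height, width) {
  layout_bands(height, width, 2L)
}

#' @rdname layout_split
#' @export
layout_bands <- function(height, width, regions = 3L) {
  stopifnot(height >= 1, width >= regions, regions >= 1)
  # split columns as evenly as possible, left band gets remainders
  sizes <- diff(floor(seq(0, width, length.out = regions + 1)))
  matrix(rep(seq_len(regions), times = sizes), nrow = height, ncol = width,
         byrow = TRUE)
}

#' @rdname layout_split
#' @export
layout_concentric <- function(height, width) {
  stopifnot(height >= 2, width >= 2)
  m <- matrix(1L, height, width)
  ri <- seq.int(floor(height / 4) + 1L, floor(height / 4) + ceiling(height / 2))
  ci <- seq.int(floor(width / 4) + 1L, floor(width / 4) + ceiling(width / 2))
  m[ri, ci] <- 2L
  m
}

#' Specification of a synthetic test image
#'
#' Bundles everything needed to reproduce one synthetic image: a region
#' layout, per-region Gaussian intensity parameters, optional
#' salt-and-pepper noise (given either as an absolute pixel count or as
#' a density `d`, with `Np = M * N * d`), optional additive Gaussian
#' noise, and the RNG seed. The same spec and seed always regenerate a
#' bit-identical image.
#'
#' @param height,width image dimensions (ignored when `region_map` is
#'   supplied).
#' @param region_means,region_stds per-region Gaussian mean and standard
#'   deviation of pixel intensity; equal length, one entry per region.
#' @param layout one of `"split"`, `"bands"`, `"concentric"`; used to
#'   build the region map when `region_map` is `NULL`. `"bands"` makes
#'   `length(region_means)` equal vertical bands.
#' @param region_map optional explicit integer matrix of region ids
#'   `1..R`.
#' @param sp_count,sp_density impulse-noise amount, mutually exclusive:
#'   an exact number of corrupted pixels, or a density in `[0, 1]`.
#' @param gaussian_sigma standard deviation of additive Gaussian noise
#'   (0 disables).
#' @param seed integer RNG seed.
#' @return an object of class `"synth_spec"`.
#' @examples
#' sp <- synth_spec(40, 40, region_means = c(50, 200),
#'                  region_stds = c(20, 20), sp_density = 0.1, seed = 7)
#' im <- synth_image(sp)
#' dim(im$image)
#' @export
synth_spec <- function(height = 100L, width = 100L,
                       region_means = c(50, 200),
                       region_stds = c(20, 20),
                       layout = c("split", "bands", "concentric"),
                       region_map = NULL,
                       sp_count = NULL, sp_density = NULL,
                       gaussian_sigma = 0, seed = NULL) {
  if (length(region_means) != length(region_stds)) {
    stop("`region_means` and `region_stds` must have the same length",
         call. = FALSE)
  }
  if (any(region_stds < 0)) stop("`region_stds` must be >= 0", call. = FALSE)
  if (!is.null(sp_count) && !is.null(sp_density)) {
    stop("give either `sp_count` or `sp_density`, not both", call. = FALSE)
  }
  r <- length(region_means)
  if (is.null(region_map)) {
    if (height < 1 || width < 1) stop("non-positive image dimensions", call. = FALSE)
    layout <- match.arg(layout)
    region_map <- switch(layout,
      split = layout_split(height, width),
      bands = layout_bands(height, width, r),
      concentric = layout_concentric(height, width))
  } else {
    storage.mode(region_map) <- "integer"
    height <- nrow(region_map)
    width <- ncol(region_map)
  }
  ids <- sort(unique(as.vector(region_map)))
  if (!identical(ids, seq_len(r))) {
    stop(sprintf("region_map must cover ids 1..%d exactly", r), call. = FALSE)
  }
  structure(list(height = height, width = width, region_map = region_map,
                 region_means = region_means, region_stds = region_stds,
                 sp_count = sp_count, sp_density = sp_density,
                 gaussian_sigma = gaussian_sigma, seed = seed),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("synthetic image spec: %d x %d, %d region(s)\n",
              x$height, x$width, length(x$region_means)))
  cat("  means:", paste(x$region_means, collapse = ", "),
      " stds:", paste(x$region_stds, collapse = ", "), "\n")
  if (!is.null(x$sp_count)) cat("  salt-and-pepper count:", x$sp_count, "\n")
  if (!is.null(x$sp_density)) cat("  salt-and-pepper density:", x$sp_density, "\n")
  if (x$gaussian_sigma > 0) cat("  gaussian sigma:", x$gaussian_sigma, "\n")
  invisible(x)
}

#' Generate the noise-free piecewise-Gaussian image of a spec
#'
#' Every pixel in region `r` is an independent draw from
#' `Normal(region_means[r], region_stds[r])`, rounded half away from
#' zero and clamped to `[0, 255]`. The ground-truth label image is the
#' spec's region map.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed; defaults to the spec's.
#' @return list with elements `image` (grayscale matrix) and `labels`
#'   (region-id matrix).
#' @export
generate_region_image <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    img <- matrix(0, spec$height, spec$width)
    for (r in seq_along(spec$region_means)) {
      idx <- spec$region_map == r
      img[idx] <- rnorm(sum(idx), spec$region_means[r], spec$region_stds[r])
    }
    list(image = quantize8(img), labels = spec$region_map)
  })
}

#' Add salt-and-pepper impulse noise
#'
#' Corrupts exactly `Np` distinct pixel positions, chosen uniformly
#' without replacement, setting `ceiling(Np/2)` of them to 0 (pepper)
#' and the rest to 255 (salt). `Np` is either `count` or
#' `M * N * density` rounded to the nearest integer.
#'
#' @param image grayscale matrix.
#' @param count exact number of corrupted pixels.
#' @param density fraction `d` of corrupted pixels, `Np = M * N * d`.
#' @param seed integer RNG seed (`NULL` uses the current stream).
#' @return the corrupted image.
#' @examples
#' im <- matrix(128L, 20, 20)
#' noisy <- add_salt_pepper(im, density = 0.1, seed = 1)
#' sum(noisy != im)   # 40 pixels
#' @export
add_salt_pepper <- function(image, count = NULL, density = NULL, seed = NULL) {
  image <- as_gray_image(image)
  if (is.null(count) == is.null(density)) {
    stop("give exactly one of `count` or `density`", call. = FALSE)
  }
  n_pix <- length(image)
  if (!is.null(density)) {
    if (density < 0 || density > 1) stop("`density` must be in [0, 1]", call. = FALSE)
    count <- as.integer(round_half_away(n_pix * density))
  }
  if (count < 0 || count > n_pix) {
    stop("impulse count must be between 0 and the pixel count", call. = FALSE)
  }
  if (count == 0L) return(image)
  with_seed(seed, {
    pos <- sample.int(n_pix, count)
    n_pepper <- ceiling(count / 2)
    image[pos[seq_len(n_pepper)]] <- 0L
    if (count > n_pepper) image[pos[(n_pepper + 1L):count]] <- 255L
    image
  })
}

#' Add additive Gaussian noise
#'
#' Perturbs every pixel independently with `Normal(0, sigma)` noise,
#' then rounds half away from zero and clamps to `[0, 255]`. The
#' default `sigma = 1` matches the additive-noise model used in the
#' package's noise-robustness experiments.
#'
#' @param image grayscale matrix.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer RNG seed (`NULL` uses the current stream).
#' @return the perturbed image.
#' @export
add_gaussian_noise <- function(image, sigma = 1, seed = NULL) {
  image <- as_gray_image(image)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  with_seed(seed, {
    quantize8(image + matrix(rnorm(length(image), 0, sigma),
                             nrow(image), ncol(image)))
  })
}

#' Materialize a synthetic spec into clean and noisy images
#'
#' Runs [generate_region_image()] and then applies whatever noise the
#' spec asks for. Sub-seeds for the three stochastic stages are derived
#' deterministically from the spec seed so the clean image does not
#' change when noise settings do.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed; defaults to the spec's.
#' @return list with `image` (noisy), `clean`, `labels`, and `spec`.
#' @export
synth_image <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  seeds <- derive_seeds(seed, 3L)
  base <- generate_region_image(spec, seed = seeds[[1L]])
  img <- base$image
  if (!is.null(spec$sp_count) || !is.null(spec$sp_density)) {
    img <- add_salt_pepper(img, count = spec$sp_count,
                           density = spec$sp_density, seed = seeds[[2L]])
  }
  if (spec$gaussian_sigma > 0) {
    img <- add_gaussian_noise(img, spec$gaussian_sigma, seed = seeds[[3L]])
  }
  list(image = img, clean = base$image, labels = base$labels, spec = spec)
}

# Derive n reproducible 31-bit sub-seeds from one seed (NULL stays NULL:
# every stage then draws from the current stream).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}
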
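#' Root-mean-square error between two images
#'
#' @param ref,test grayscale matrices of identical shape.
#' @return RMSE in intensity units, `>= 0`.
#' @export
rmse <- function(ref, test) {
  ref <- as_gray_image(ref, "ref"); test <- as_gray_image(test, "test")
  check_same_shape(ref, test)
  sqrt(mean((as.numeric(ref) - as.numeric(test))^2))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 * log10(255 / RMSE)` decibels for 8-bit images; `Inf`
#' when the images are identical (RMSE = 0).
#'
#' @inheritParams rmse
#' @return PSNR in dB (possibly `Inf`).
#' @examples
#' psnr(matrix(0L, 4, 4), matrix(255L, 4, 4))   # 0 dB
#' @export
psnr <- function(ref, test) {
  e <- rmse(ref, test)
  if (e == 0) return(Inf)
  20 * log10(255 / e)
}

#' Global structural similarity index
#'
#' Single-window SSIM computed from whole-image statistics. Both images
#' are rescaled to `[0, 1]` and the luminance and contrast/structure
#' factors are combined as
#' `(2 mu_x mu_y + C1)(2 s + C2) / ((mu_x^2 + mu_y^2 + C1)(sd_x^2 + sd_y^2 + C2))`,
#' where `s` is the cross-covariance (`form = "covariance"`, default;
#' gives exactly 1 on identical images) or the product of the two
#' standard deviations (`form = "product"`). Sample statistics use the
#' `n - 1` denominator. `C1 = C2 = 0.065` are stabilizers on the unit
#' intensity scale.
#'
#' @inheritParams rmse
#' @param C1,C2 stabilizing constants.
#' @param form second-factor numerator: cross-covariance or product of
#'   standard deviations.
#' @return the SSIM value (at most 1 in covariance form).
#' @export
ssim <- function(ref, test, C1 = 0.065, C2 = 0.065,
                 form = c("covariance", "product")) {
  ref <- as_gray_image(ref, "ref"); test <- as_gray_image(test, "test")
  check_same_shape(ref, test)
  form <- match.arg(form)
  x <- as.numeric(ref) / 255
  y <- as.numeric(test) / 255
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  s <- if (form == "covariance") stats::cov(x, y) else sqrt(vx) * sqrt(vy)
  ((2 * mx * my + C1) * (2 * s + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Scharr 3x3 gradient magnitude, same-size output with replicated
# borders; /16 normalization keeps G on the 8-bit intensity scale.
scharr_gradient <- function(image) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- conv2_same(image, kx)
  gy <- conv2_same(image, t(kx))
  sqrt(gx^2 + gy^2)
}

# 2-D correlation with a 3x3 kernel, replicate-padded borders.
conv2_same <- function(image, k) {
  m <- nrow(image); n <- ncol(image)
  pad <- rbind(image[1, , drop = FALSE], image, image[m, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, n, drop = FALSE])
  out <- matrix(0, m, n)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + k[di + 1, dj + 1] * pad[(1:m) + di, (1:n) + dj]
  }
  out
}

# Log-Gabor filter bank in the frequency domain (FFT ordering).
# Returns a list of norient elements, each a list of nscale complex
# response arrays obtained by inverse FFT.
log_gabor_responses <- function(image, nscale, norient, min_wavelength,
                                mult, sigma_onf) {
  m <- nrow(image); n <- ncol(image)
  fy <- ifelse(seq_len(m) - 1 <= m / 2, seq_len(m) - 1, seq_len(m) - 1 - m) / m
  fx <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n) / n
  radius <- sqrt(outer(fy^2, fx^2, `+`))
  radius[1, 1] <- 1  # avoid log(0) at DC; the filter is zeroed there below
  theta <- atan2(outer(-fy, rep(1, n)), outer(rep(1, m), fx))
  lowpass <- 1 / (1 + (radius / 0.45)^(2 * 15))
  F <- stats::fft(image)
  sigma_theta <- (pi / norient) / 1.2
  lapply(seq_len(norient), function(o) {
    angl <- (o - 1) * pi / norient
    # angular distance wrapped to [-pi, pi]
    dtheta <- abs(atan2(sin(theta - angl), cos(theta - angl)))
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))
    lapply(seq_len(nscale), function(s) {
      wavelength <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wavelength
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lowpass
      lg[1, 1] <- 0
      stats::fft(F * lg * spread, inverse = TRUE) / (m * n)
    })
  })
}

#' Phase congruency map
#'
#' Contrast-invariant feature-salience measure
#' `PC(w) = E(w) / (eps + sum_n A_n(w))`: the magnitude of the summed
#' even/odd log-Gabor responses over scales (then summed over
#' orientations), normalized by the total response amplitude. Values
#' lie in `[0, 1]`; high values mark step edges and lines regardless of
#' their contrast.
#'
#' @param image grayscale matrix, at least 16 x 16.
#' @param nscale,norient filter-bank size (scales x orientations).
#' @param min_wavelength wavelength in pixels of the finest scale.
#' @param mult wavelength multiplier between scales.
#' @param sigma_onf radial bandwidth parameter of the log-Gabor.
#' @param eps stabilizer preventing division by zero in featureless
#'   patches.
#' @return matrix of PC values in `[0, 1]`.
#' @export
phase_congruency <- function(image, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55, eps = 1e-4) {
  image <- as_gray_image(image)
  if (nrow(image) < 16L || ncol(image) < 16L) {
    stop("image must be at least 16 x 16 for the filter bank", call. = FALSE)
  }
  resp <- log_gabor_responses(matrix(as.numeric(image), nrow(image)),
                              nscale, norient, min_wavelength, mult, sigma_onf)
  energy <- 0; amplitude <- 0
  for (o in resp) {
    sumE <- 0; sumO <- 0
    for (r in o) {
      e <- Re(r); od <- Im(r)
      sumE <- sumE + e; sumO <- sumO + od
      amplitude <- amplitude + sqrt(e^2 + od^2)
    }
    energy <- energy + sqrt(sumE^2 + sumO^2)
  }
  energy / (eps + amplitude)
}

#' Feature similarity index
#'
#' Combines a phase-congruency similarity `S_PC` and a gradient
#' similarity `S_G` per pixel,
#' `S_L(w) = S_PC(w) * S_G(w)` with
#' `S_PC = (2 PC1 PC2 + T1) / (PC1^2 + PC2^2 + T1)` and
#' `S_G = (2 G1 G2 + T2) / (G1^2 + G2^2 + T2)`,
#' and averages `S_L` weighted by `PCm = max(PC1, PC2)`, so the score
#' is dominated by the most salient features of either image. Gradients
#' use Scharr kernels on the 8-bit scale; `T1 = 0.85` and `T2 = 160`
#' are the customary stabilizers for that scale. The result lies in
#' `[0, 1]` and equals 1 for identical images.
#'
#' @inheritParams rmse
#' @param T1,T2 stabilizing constants for `S_PC` and `S_G`.
#' @param ... filter-bank settings passed to [phase_congruency()].
#' @return FSIM value in `[0, 1]`.
#' @export
fsim <- function(ref, test, T1 = 0.85, T2 = 160, ...) {
  ref <- as_gray_image(ref, "ref"); test <- as_gray_image(test, "test")
  check_same_shape(ref, test)
  pc1 <- phase_congruency(ref, ...)
  pc2 <- phase_congruency(test, ...)
  g1 <- scharr_gradient(matrix(as.numeric(ref), nrow(ref)))
  g2 <- scharr_gradient(matrix(as.numeric(test), nrow(test)))
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Full-reference quality report for one image pair
#'
#' @inheritParams rmse
#' @return one-row `data.frame` with columns `psnr`, `rmse`, `ssim`,
#'   `fsim`.
#' @export
quality_report <- function(ref, test) {
  data.frame(psnr = psnr(ref, test), rmse = rmse(ref, test),
             ssim = ssim(ref, test), fsim = fsim(ref, test))
}
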
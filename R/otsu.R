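#' Multilevel Otsu thresholding baseline
#'
#' Splits the 256-bin intensity histogram into `levels` classes by the
#' thresholds that maximize the between-class variance (equivalently,
#' minimize the summed within-class weighted variance). The optimum is
#' found exactly by dynamic programming over the histogram, so the
#' result does not depend on pixel order — only on the histogram.
#'
#' @param image grayscale matrix.
#' @param levels number of classes, `>= 2`.
#' @return integer label matrix (`1..levels`) with attributes
#'   `"thresholds"` (upper intensity bound of each class but the last)
#'   and `"class_means"` (mean intensity of each class, for rendering).
#' @examples
#' im <- cbind(matrix(50L, 8, 4), matrix(200L, 8, 4))
#' attr(otsu_baseline(im, 2), "thresholds")
#' @export
otsu_baseline <- function(image, levels = 2L) {
  image <- as_gray_image(image)
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  h <- intensity_hist(image)
  occupied <- which(h > 0L)
  if (length(occupied) < levels) {
    stop(sprintf("histogram has %d distinct intensities; cannot form %d classes",
                 length(occupied), levels), call. = FALSE)
  }
  # within-class weighted sum of squares for any intensity interval
  # [a, b], from cumulative moments
  c0 <- cumsum(h)
  c1 <- cumsum(h * (0:255))
  c2 <- cumsum(h * (0:255)^2)
  seg_cost <- function(a, b) {  # a, b in 0..255, a <= b
    w <- c0[b + 1] - if (a > 0) c0[a] else 0
    if (w == 0) return(0)
    s1 <- c1[b + 1] - if (a > 0) c1[a] else 0
    s2 <- c2[b + 1] - if (a > 0) c2[a] else 0
    s2 - s1^2 / w
  }
  # dp[l, b+1]: minimal cost of covering 0..b with l classes
  dp <- matrix(Inf, levels, 256)
  cut <- matrix(NA_integer_, levels, 256)
  for (b in 0:255) dp[1, b + 1] <- seg_cost(0, b)
  for (l in 2:levels) {
    for (b in (l - 1):255) {
      cands <- (l - 1):b  # first intensity of class l
      costs <- vapply(cands, function(a) dp[l - 1, a] + seg_cost(a, b), 0)
      best <- which.min(costs)
      dp[l, b + 1] <- costs[best]
      cut[l, b + 1] <- cands[best]
    }
  }
  # recover class boundaries
  starts <- integer(levels)
  b <- 255L
  for (l in levels:2) {
    starts[l] <- cut[l, b + 1]
    b <- starts[l] - 1L
  }
  starts[1] <- 0L
  thresholds <- starts[-1] - 1L  # upper bound of classes 1..levels-1
  lut <- findInterval(0:255, starts)
  labels <- matrix(lut[as.vector(image) + 1L], nrow(image), ncol(image))
  storage.mode(labels) <- "integer"
  means <- vapply(seq_len(levels), function(l) {
    sel <- lut == l & h > 0
    if (!any(sel)) return(NA_real_)
    sum(h[sel] * (0:255)[sel]) / sum(h[sel])
  }, 0)
  attr(labels, "thresholds") <- thresholds
  attr(labels, "class_means") <- means
  labels
}
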
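#' Segment a grayscale image with the two-phase hybrid method
#'
#' Phase 1 homogenizes regions with the agent-based model
#' ([run_abm()]); phase 2 clusters the homogenized intensities with the
#' firefly search plus K-means refinement ([firefly_cluster()]) and
#' labels every pixel with its nearest centroid. Setting
#' `abm$iter1 = 0` skips homogenization, giving the plain-clustering
#' ablation. The result is fully deterministic under a fixed `seed`.
#'
#' @param image grayscale matrix.
#' @param k number of clusters.
#' @param abm an [abm_config()].
#' @param firefly a [firefly_config()]; its `seed` is overridden by
#'   `seed` when that is given.
#' @param seed integer seed for the stochastic clustering phase.
#' @return list of class `"abmff_segmentation"` with elements `labels`
#'   (integer matrix `1..k`), `solution` (the `"cluster_solution"`),
#'   `homogenized` (the phase-1 image), `rendered` (labels replaced by
#'   centroid intensities), and `k`.
#' @examples
#' im <- cbind(matrix(50L, 16, 8), matrix(200L, 16, 8))
#' seg <- segment(im, k = 2, abm = abm_config(iter1 = 5), seed = 1)
#' seg$solution$centroids
#' @export
segment <- function(image, k, abm = abm_config(),
                    firefly = firefly_config(), seed = NULL) {
  image <- as_gray_image(image)
  if (!is.null(seed)) firefly$seed <- seed
  ih <- run_abm(image, abm)
  sol <- firefly_cluster(ih, k, firefly)
  labels <- assign_labels(ih, sol)
  structure(list(labels = labels, solution = sol, homogenized = ih,
                 rendered = render_segmentation(labels, sol), k = k),
            class = "abmff_segmentation")
}

#' @export
print.abmff_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d x %d image, k = %d\n",
              nrow(x$labels), ncol(x$labels), x$k))
  print(x$solution)
  invisible(x)
}

#' Pixel accuracy under the best label permutation
#'
#' Cluster indices are arbitrary, so accuracy is the largest fraction
#' of agreeing pixels over all one-to-one matchings between predicted
#' and true labels (found by exhaustive search over permutations of the
#' smaller label set; intended for the small `k` used in experiments).
#'
#' @param pred,truth integer label matrices of identical shape.
#' @return accuracy in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  check_same_shape(pred, truth)
  pl <- sort(unique(as.vector(pred)))
  tl <- sort(unique(as.vector(truth)))
  if (max(length(pl), length(tl)) > 8L) {
    stop("permutation matching supports at most 8 labels", call. = FALSE)
  }
  conf <- table(factor(as.vector(pred), levels = pl),
                factor(as.vector(truth), levels = tl))
  # pad to square so permutations are one-to-one
  n <- max(dim(conf))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  perms <- all_permutations(n)
  best <- max(vapply(perms, function(p) sum(sq[cbind(seq_len(n), p)]), 0))
  best / length(pred)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Run one synthetic segmentation experiment
#'
#' Generates the spec's image (clean reference plus noisy input), runs
#' each requested method on the noisy input, and scores every result
#' with PSNR/SSIM/FSIM of its centroid-rendered segmentation against
#' the clean reference, plus pixel accuracy against the ground-truth
#' region map.
#'
#' Methods: `"abmff"` is the full two-phase pipeline; `"cluster"` is
#' the ablation without the agent-based phase (`iter1 = 0`); `"otsu"`
#' is multilevel Otsu thresholding rendered with its class means.
#'
#' @param spec a [synth_spec()].
#' @param k number of clusters (defaults to the spec's region count).
#' @param methods subset of `c("abmff", "cluster", "otsu")`.
#' @param abm,firefly stage configurations for the pipeline methods.
#' @param seed integer seed for image generation and clustering.
#' @return `data.frame` with one row per method: `method`, `psnr`,
#'   `rmse`, `ssim`, `fsim`, `accuracy`.
#' @export
run_experiment <- function(spec, k = length(spec$region_means),
                           methods = c("abmff", "cluster", "otsu"),
                           abm = abm_config(), firefly = firefly_config(),
                           seed = spec$seed) {
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- derive_seeds(seed, 2L)
  syn <- synth_image(spec, seed = seeds[[1L]])
  rows <- lapply(methods, function(m) {
    if (m == "otsu") {
      labels <- otsu_baseline(syn$image, levels = k)
      rendered <- render_segmentation(labels, attr(labels, "class_means"))
    } else {
      cfg <- abm
      if (m == "cluster") cfg$iter1 <- 0L
      seg <- segment(syn$image, k, abm = cfg, firefly = firefly,
                     seed = seeds[[2L]])
      labels <- seg$labels
      rendered <- seg$rendered
    }
    cbind(data.frame(method = m), quality_report(syn$clean, rendered),
          data.frame(accuracy = pixel_accuracy(labels, syn$labels)))
  })
  do.call(rbind, rows)
}
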
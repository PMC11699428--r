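#' Intensity histogram of a grayscale image
#'
#' 256 counts, `counts[v + 1]` = number of pixels with intensity `v`.
#' Because the clustering operates on intensity alone, every objective
#' evaluation can be done exactly on the histogram instead of per
#' pixel.
#'
#' @param image grayscale matrix.
#' @return integer vector of length 256.
#' @export
intensity_hist <- function(image) {
  image <- as_gray_image(image)
  tabulate(as.vector(image) + 1L, nbins = 256L)
}

# Nearest-centroid index for each value; ties go to the lowest
# centroid index.
nearest_centroid <- function(values, centroids) {
  d <- outer(values, centroids, function(a, b) (a - b)^2)
  max.col(-d, ties.method = "first")
}

#' Regularized clustering objective
#'
#' The fitness minimized by the firefly search:
#' `J(C) = sum_i sum_{x in C_i} (x - mu_i)^2
#'         - alpha * sum_{i < j} (mu_i - mu_j)^2`,
#' i.e. within-cluster squared distance under nearest-centroid
#' assignment, minus `alpha` times the summed squared separations of
#' all centroid pairs. The first term rewards tight clusters; the
#' subtracted term rewards well-separated centroids; `alpha` balances
#' the two (nominal value 0.6). Evaluated exactly on the 256-bin
#' histogram; ties in assignment go to the lowest centroid index.
#'
#' @param hist intensity histogram ([intensity_hist()]).
#' @param centroids numeric vector of `k` centroid intensities.
#' @param alpha_reg separation weight `alpha >= 0`.
#' @return the scalar objective `J`.
#' @examples
#' h <- tabulate(c(0, 0, 10, 10) + 1, nbins = 256)
#' clustering_objective(h, c(0, 10), alpha_reg = 0.6)  # -60
#' @export
clustering_objective <- function(hist, centroids, alpha_reg = 0.6) {
  stopifnot(length(hist) == 256L, all(hist >= 0), length(centroids) >= 1,
            all(is.finite(centroids)), alpha_reg >= 0)
  if (sum(hist) == 0) stop("empty histogram", call. = FALSE)
  present <- which(hist > 0L)
  values <- present - 1
  counts <- hist[present]
  assign <- nearest_centroid(values, centroids)
  intra <- sum(counts * (values - centroids[assign])^2)
  sep <- 0
  k <- length(centroids)
  if (k > 1L) {
    sep <- sum(stats::dist(matrix(centroids, ncol = 1))^2)
  }
  intra - alpha_reg * sep
}

#' Configuration of the firefly search and K-means refinement
#'
#' Each firefly is a candidate set of `k` centroids; its brightness is
#' the negative of the clustering objective. Every iteration, each
#' firefly moves toward every brighter firefly with attractiveness
#' `beta0 * exp(-gamma * r^2)` (where `r` is the Euclidean distance
#' between the sorted centroid vectors, removing label-permutation
#' ambiguity) plus a uniform random perturbation of amplitude
#' `step_scale * 255` that decays geometrically by `step_decay` per
#' iteration. `gamma` defaults to `1 / 255^2` so attraction is
#' expressed on the normalized intensity scale.
#'
#' @param swarm_size number of fireflies, `>= 2`.
#' @param iter2 number of search iterations, `>= 1`.
#' @param alpha_reg separation weight of [clustering_objective()].
#' @param beta0 attractiveness at distance zero.
#' @param gamma light-absorption coefficient.
#' @param step_scale initial random-walk amplitude (fraction of the
#'   intensity range).
#' @param step_decay per-iteration geometric decay of `step_scale`.
#' @param kmeans_max_iter,kmeans_tol stopping rule of the K-means
#'   refinement (`tol` is the largest centroid displacement, in
#'   intensity units, considered converged).
#' @param seed integer RNG seed (`NULL` uses the current stream).
#' @return an object of class `"firefly_config"`.
#' @export
firefly_config <- function(swarm_size = 20L, iter2 = 100L, alpha_reg = 0.6,
                           beta0 = 1, gamma = 1 / 255^2, step_scale = 0.2,
                           step_decay = 0.97, kmeans_max_iter = 300L,
                           kmeans_tol = 1e-4, seed = NULL) {
  if (swarm_size < 2) stop("`swarm_size` must be >= 2", call. = FALSE)
  if (iter2 < 1) stop("`iter2` must be >= 1", call. = FALSE)
  if (alpha_reg < 0) stop("`alpha_reg` must be >= 0", call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size),
                 iter2 = as.integer(iter2), alpha_reg = alpha_reg,
                 beta0 = beta0, gamma = gamma, step_scale = step_scale,
                 step_decay = step_decay,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_tol = kmeans_tol, seed = seed),
            class = "firefly_config")
}

new_cluster_solution <- function(centroids, objective, alpha_reg,
                                 source = "firefly") {
  ord <- order(centroids)
  structure(list(centroids = as.numeric(centroids[ord]),
                 objective = objective, k = length(centroids),
                 alpha_reg = alpha_reg, source = source),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster solution (k = %d, via %s)\n", x$k, x$source))
  cat("  centroids:", paste(sprintf("%.2f", x$centroids), collapse = ", "), "\n")
  cat(sprintf("  objective J = %.4f (alpha = %g)\n", x$objective, x$alpha_reg))
  invisible(x)
}

#' Firefly metaheuristic search for intensity centroids
#'
#' Initializes `swarm_size` centroid sets uniformly at random in
#' `[0, 255]` and iterates the attraction dynamics described in
#' [firefly_config()], clipping centroids to `[0, 255]` after every
#' move. The brightest (lowest-`J`) solution ever visited is returned;
#' its per-iteration trace is attached as attribute `"best_trace"` and
#' is non-increasing by construction.
#'
#' @param hist intensity histogram ([intensity_hist()]).
#' @param k number of clusters; at most the number of distinct
#'   intensities present.
#' @param config a [firefly_config()].
#' @return a `"cluster_solution"` (centroids sorted ascending).
#' @export
firefly_search <- function(hist, k, config = firefly_config()) {
  stopifnot(length(hist) == 256L, k >= 1)
  n_distinct <- sum(hist > 0L)
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the %d distinct intensities present",
                 k, n_distinct), call. = FALSE)
  }
  with_seed(config$seed, {
    pos <- matrix(stats::runif(config$swarm_size * k, 0, 255),
                  nrow = config$swarm_size)
    J <- apply(pos, 1L, clustering_objective, hist = hist,
               alpha_reg = config$alpha_reg)
    best_i <- which.min(J)
    best <- list(centroids = pos[best_i, ], J = J[best_i])
    trace <- numeric(config$iter2)
    step <- config$step_scale
    for (t in seq_len(config$iter2)) {
      J_snapshot <- J
      pos_snapshot <- pos
      for (i in seq_len(config$swarm_size)) {
        xi <- pos[i, ]
        for (j in seq_len(config$swarm_size)) {
          if (J_snapshot[j] >= J_snapshot[i]) next
          r2 <- sum((sort(pos_snapshot[j, ]) - sort(xi))^2)
          beta <- config$beta0 * exp(-config$gamma * r2)
          xi <- xi + beta * (pos_snapshot[j, ] - xi) +
            step * (stats::runif(k) - 0.5) * 255
        }
        xi <- clamp(xi)
        pos[i, ] <- xi
        J[i] <- clustering_objective(hist, xi, config$alpha_reg)
        if (J[i] < best$J) best <- list(centroids = xi, J = J[i])
      }
      trace[t] <- best$J
      step <- step * config$step_decay
    }
    out <- new_cluster_solution(best$centroids, best$J, config$alpha_reg,
                                source = "firefly")
    attr(out, "best_trace") <- trace
    out
  })
}

#' K-means refinement of a centroid set
#'
#' Standard weighted K-means on the intensity histogram: alternate
#' nearest-centroid assignment and centroid-mean update until the
#' largest centroid displacement falls below `tol` or `max_iter` is
#' reached. The within-cluster sum of squares `JK` is recorded after
#' every update (attribute `"jk_trace"`) and is non-increasing. A
#' centroid that loses all its values is re-seeded at the occupied
#' intensity farthest from its nearest surviving centroid.
#'
#' @param hist intensity histogram.
#' @param centroids initial centroids (typically the firefly optimum).
#' @param max_iter,tol stopping rule.
#' @param alpha_reg separation weight used to fill in the returned
#'   solution's `objective`.
#' @return a `"cluster_solution"` with attribute `"jk_trace"`.
#' @export
kmeans_refine <- function(hist, centroids, max_iter = 300L, tol = 1e-4,
                          alpha_reg = 0.6) {
  stopifnot(length(hist) == 256L, length(centroids) >= 1)
  present <- which(hist > 0L)
  values <- present - 1
  counts <- hist[present]
  mu <- as.numeric(centroids)
  k <- length(mu)
  jk <- numeric(0)
  for (it in seq_len(max_iter)) {
    assign <- nearest_centroid(values, mu)
    new_mu <- mu
    for (c in seq_len(k)) {
      sel <- assign == c
      if (any(sel)) {
        new_mu[c] <- sum(counts[sel] * values[sel]) / sum(counts[sel])
      } else {
        # empty cluster: restart at the occupied value farthest from
        # its nearest non-empty centroid
        occupied <- mu[sort(unique(assign))]
        d_near <- vapply(values, function(v) min((v - occupied)^2), 0)
        new_mu[c] <- values[which.max(d_near)]
      }
    }
    jk <- c(jk, sum(counts * (values - new_mu[nearest_centroid(values, new_mu)])^2))
    moved <- max(abs(new_mu - mu))
    mu <- new_mu
    if (moved < tol) break
  }
  out <- new_cluster_solution(mu, clustering_objective(hist, mu, alpha_reg),
                              alpha_reg, source = "kmeans")
  attr(out, "jk_trace") <- jk
  out
}

#' Full clustering stage: firefly search plus K-means refinement
#'
#' Runs [firefly_search()], refines its optimum with [kmeans_refine()],
#' and returns whichever of the two candidates has the lower
#' regularized objective `J`. (K-means minimizes the pure
#' within-cluster sum of squares, which on small or widely spread data
#' can trade away the separation reward; keeping the better-`J`
#' candidate makes the stage a strict improvement over the search
#' alone.)
#'
#' @param x grayscale matrix or a 256-bin intensity histogram.
#' @param k number of clusters.
#' @param config a [firefly_config()].
#' @return a `"cluster_solution"`.
#' @export
firefly_cluster <- function(x, k, config = firefly_config()) {
  hist <- if (is.matrix(x)) intensity_hist(x) else as.integer(x)
  if (length(hist) != 256L) stop("`x` must be an image matrix or a 256-bin histogram",
                                 call. = FALSE)
  ff <- firefly_search(hist, k, config)
  km <- kmeans_refine(hist, ff$centroids, config$kmeans_max_iter,
                      config$kmeans_tol, config$alpha_reg)
  if (km$objective <= ff$objective) km else ff
}

#' Label every pixel with its nearest centroid
#'
#' Labels are `1..k` in ascending-centroid order (label 1 is the
#' darkest cluster); midpoint ties go to the lower label.
#'
#' @param image grayscale matrix.
#' @param solution a `"cluster_solution"` or a bare centroid vector.
#' @return integer label matrix, same shape as `image`.
#' @export
assign_labels <- function(image, solution) {
  image <- as_gray_image(image)
  centroids <- if (inherits(solution, "cluster_solution")) solution$centroids
               else sort(as.numeric(solution))
  lut <- nearest_centroid(0:255, centroids)
  labels <- matrix(lut[as.vector(image) + 1L], nrow(image), ncol(image))
  storage.mode(labels) <- "integer"
  labels
}

#' Render a segmentation as a grayscale image
#'
#' Replaces every label by its (rounded) centroid intensity, producing
#' an image with at most `k` distinct gray levels that can be compared
#' to the original with full-reference quality metrics.
#'
#' @param labels integer label matrix (`1..k`).
#' @param solution a `"cluster_solution"` or a centroid vector, ordered
#'   to match the labels.
#' @return grayscale matrix.
#' @export
render_segmentation <- function(labels, solution) {
  centroids <- if (inherits(solution, "cluster_solution")) solution$centroids
               else as.numeric(solution)
  stopifnot(all(labels >= 1L), all(labels <= length(centroids)))
  out <- matrix(centroids[as.vector(labels)], nrow(labels), ncol(labels))
  quantize8(out)
}
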
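# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles are deliberately naive transcriptions kept
# separate from the package implementation.

rand_gray <- function(m, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(sample(0:255, m * n, replace = TRUE), m, n)
  storage.mode(x) <- "integer"
  x
}

# Literal transcription of the consensus rules: S = sign(sum of signs
# of neighbor differences); S = +1 -> +delta, S = -1 -> -delta,
# S = 0 -> unchanged; clamp to [0, 255]. Plain nested loops in the
# configured scan order.
sweep_oracle <- function(grid, delta = 1L, neighborhood = "moore",
                         scan_order = "right-to-left",
                         update = "synchronous") {
  m <- nrow(grid); n <- ncol(grid)
  out <- grid
  src_of <- function() if (update == "sequential") out else grid
  cols <- if (scan_order == "right-to-left") n:1 else 1:n
  for (i in 1:m) {
    for (j in cols) {
      src <- src_of()
      e0 <- src[i, j]
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (neighborhood == "von-neumann" && di != 0 && dj != 0) next
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > m || nj < 1 || nj > n) next
        acc <- acc + sign(src[ni, nj] - e0)
      }
      s <- sign(acc)
      out[i, j] <- as.integer(min(255, max(0, e0 + s * delta)))
    }
  }
  out
}

# Pooled within-region standard deviation given ground-truth labels.
pooled_region_sd <- function(image, labels) {
  devs <- unlist(lapply(sort(unique(as.vector(labels))), function(r) {
    v <- image[labels == r]
    v - mean(v)
  }))
  sqrt(mean(devs^2))
}

# Exhaustive-search oracle for the regularized objective with k = 2
# over integer centroid pairs.
exhaustive_j2 <- function(hist, alpha = 0.6) {
  vals <- which(hist > 0) - 1
  cnt <- hist[hist > 0]
  best <- Inf
  best_mu <- NULL
  for (m1 in 0:254) {
    d1 <- (vals - m1)^2
    for (m2 in (m1 + 1):255) {
      J <- sum(cnt * pmin(d1, (vals - m2)^2)) - alpha * (m1 - m2)^2
      if (J < best) {
        best <- J
        best_mu <- c(m1, m2)
      }
    }
  }
  list(J = best, centroids = best_mu)
}

# Naive per-pixel evaluation of the regularized objective.
objective_per_pixel <- function(image, centroids, alpha = 0.6) {
  intra <- 0
  for (v in as.vector(image)) {
    d <- (v - centroids)^2
    intra <- intra + min(d)
  }
  sep <- 0
  k <- length(centroids)
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    sep <- sep + (centroids[i] - centroids[j])^2
  }
  intra - alpha * sep
}

# Exhaustive multilevel-threshold oracle: minimal within-class weighted
# sum of squares over all contiguous splits of the occupied bins.
otsu_oracle_cost <- function(hist, levels) {
  vals <- which(hist > 0) - 1
  cnt <- hist[hist > 0]
  n <- length(vals)
  wss <- function(idx) {
    w <- cnt[idx]; v <- vals[idx]
    sum(w * v^2) - sum(w * v)^2 / sum(w)
  }
  best <- Inf
  splits <- utils::combn(n - 1, levels - 1)
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, c], n)
    cost <- sum(vapply(seq_len(levels), function(l) {
      wss((bounds[l] + 1):bounds[l + 1])
    }, 0))
    best <- min(best, cost)
  }
  best
}

# Within-class cost actually attained by a label assignment.
labels_wss <- function(image, labels) {
  sum(unlist(lapply(sort(unique(as.vector(labels))), function(l) {
    v <- as.numeric(image[labels == l])
    (v - mean(v))^2
  })))
}

# Sweeps until an impulse pixel reaches or crosses the surrounding
# region value (cap to keep runaway cases finite).
impulse_removal_time <- function(height, delta, region = 200L, size = 9L,
                                 cap = 400L) {
  im <- matrix(as.integer(region), size, size)
  c0 <- ceiling(size / 2)
  im[c0, c0] <- as.integer(region - height)
  cfg <- abm_config(iter1 = 1L, delta = delta)
  cur <- im
  for (t in seq_len(cap)) {
    cur <- abm_step(cur, cfg)
    if (cur[c0, c0] >= region) return(t)
  }
  NA_integer_
}
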
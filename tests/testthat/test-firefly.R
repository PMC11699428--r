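test_that("objective matches hand evaluations", {
  h <- tabulate(c(0, 0, 10, 10) + 1, nbins = 256)
  expect_equal(clustering_objective(h, c(0, 10), 0.6), -60)

  # k = 1: plain sum of squares, no separation term
  h2 <- tabulate(c(4, 8) + 1, nbins = 256)
  expect_equal(clustering_objective(h2, 6, 0.6), 8)

  h3 <- tabulate(c(1, 2, 9, 10) + 1, nbins = 256)
  expect_equal(clustering_objective(h3, c(1.5, 9.5), 0), 1.0)

  expect_error(clustering_objective(integer(256), c(1, 2)), "empty")
})

test_that("histogram objective equals naive per-pixel evaluation", {
  set.seed(77)
  for (rep in 1:10) {
    img <- rand_gray(6, 5)
    k <- sample(2:4, 1)
    cen <- runif(k, 0, 255)
    expect_equal(clustering_objective(intensity_hist(img), cen, 0.6),
                 objective_per_pixel(img, cen, 0.6))
  }
})

test_that("objective is invariant under centroid permutation", {
  set.seed(3)
  img <- rand_gray(8, 8)
  h <- intensity_hist(img)
  cen <- c(30, 120, 210)
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(clustering_objective(h, cen[p], 0.6),
                 clustering_objective(h, cen, 0.6))
  }
})

test_that("firefly search finds well-separated delta masses", {
  h <- integer(256); h[51] <- 500L; h[201] <- 500L
  sol <- firefly_cluster(h, 2, firefly_config(seed = 1))
  expect_lt(max(abs(sol$centroids - c(50, 200))), 1.0)
})

test_that("firefly search is deterministic under a fixed seed", {
  h <- intensity_hist(rand_gray(10, 10, seed = 4))
  a <- firefly_search(h, 3, firefly_config(seed = 9, iter2 = 30))
  b <- firefly_search(h, 3, firefly_config(seed = 9, iter2 = 30))
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$objective, b$objective)
})

test_that("best-so-far objective never increases across iterations", {
  h <- intensity_hist(rand_gray(12, 12, seed = 6))
  sol <- firefly_search(h, 3, firefly_config(seed = 2, iter2 = 40))
  expect_true(all(diff(attr(sol, "best_trace")) <= 0))
})

test_that("k exceeding the distinct intensity count is rejected", {
  h <- integer(256); h[c(10, 20)] <- 5L
  expect_error(firefly_search(h, 3, firefly_config(seed = 1)), "distinct")
})

test_that("k-means refinement reaches the analytic fixed point", {
  h <- tabulate(c(0, 1, 9, 10) + 1, nbins = 256)
  sol <- kmeans_refine(h, c(0, 10))
  expect_equal(sol$centroids, c(0.5, 9.5))

  # exact cluster means are a fixed point
  h2 <- integer(256); h2[c(21, 41)] <- 10L; h2[c(201, 221)] <- 10L
  sol2 <- kmeans_refine(h2, c(30, 210))
  expect_equal(sol2$centroids, c(30, 210))

  # k = 1 converges to the histogram mean
  sol3 <- kmeans_refine(h, 3)
  expect_equal(sol3$centroids, 5)
})

test_that("k-means within-cluster criterion is non-increasing", {
  set.seed(13)
  for (rep in 1:5) {
    h <- intensity_hist(rand_gray(10, 10))
    sol <- kmeans_refine(h, runif(3, 0, 255))
    jk <- attr(sol, "jk_trace")
    expect_true(all(diff(jk) <= 1e-9))
  }
})

test_that("empty clusters are re-seeded rather than dropped", {
  h <- integer(256); h[c(11, 21, 231)] <- 10L
  # centroid at 255 captures nothing on the first assignment
  sol <- kmeans_refine(h, c(15, 100, 255))
  expect_length(sol$centroids, 3L)
  expect_true(all(diff(attr(sol, "jk_trace")) <= 1e-9))
})

test_that("label assignment uses nearest centroid with low-index ties", {
  im <- matrix(c(40L, 210L, 125L, 126L), 2, 2)
  lab <- assign_labels(im, c(50, 200))
  expect_identical(lab, matrix(c(1L, 2L, 1L, 2L), 2, 2))

  # constant image gets a single label
  expect_true(all(assign_labels(matrix(7L, 4, 4), c(50, 200)) == 1L))
})

test_that("rendering replaces labels by centroid intensities", {
  lab <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  r <- render_segmentation(lab, c(49.6, 200.2))
  expect_identical(r, matrix(c(50L, 200L, 200L, 50L), 2, 2))
})
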
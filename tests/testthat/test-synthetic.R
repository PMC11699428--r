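test_that("zero-variance regions produce exactly their means", {
  sp <- synth_spec(10, 10, region_means = c(50, 200), region_stds = c(0, 0),
                   seed = 1)
  g <- generate_region_image(sp)
  expect_true(all(g$image[, 1:5] == 50L))
  expect_true(all(g$image[, 6:10] == 200L))
  expect_identical(g$labels, sp$region_map)
})

test_that("region draws match their Gaussian parameters", {
  sp <- synth_spec(100, 100, region_means = c(50, 200),
                   region_stds = c(20, 20), seed = 42)
  g <- generate_region_image(sp)
  for (r in 1:2) {
    v <- g$image[g$labels == r]
    n <- length(v)
    expect_lt(abs(mean(v) - sp$region_means[r]), 3 * 20 / sqrt(n))
    expect_gte(sd(v), 15)
    expect_lte(sd(v), 25)
  }
})

test_that("synthetic generation is deterministic and clamped", {
  sp <- synth_spec(30, 30, region_means = c(5, 250),
                   region_stds = c(30, 30), sp_density = 0.1,
                   gaussian_sigma = 2, seed = 7)
  a <- synth_image(sp)
  b <- synth_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$clean, b$clean)
  expect_gte(min(a$image), 0)
  expect_lte(max(a$image), 255)
})

test_that("spec validation rejects malformed inputs", {
  expect_error(synth_spec(region_means = c(50, 200), region_stds = 20),
               "same length")
  expect_error(synth_spec(region_means = 50, region_stds = -1), ">= 0")
  expect_error(synth_spec(10, 10, region_means = c(1, 2),
                          region_stds = c(0, 0), sp_count = 5,
                          sp_density = 0.1), "not both")
  expect_error(synth_spec(0, 10), "non-positive")
})

test_that("salt-and-pepper corrupts exactly Np pixels, split evenly", {
  im <- matrix(128L, 100, 100)
  noisy <- add_salt_pepper(im, density = 0.1, seed = 3)
  expect_identical(sum(noisy != im), 1000L)

  noisy2 <- add_salt_pepper(im, count = 2000, seed = 5)
  expect_identical(sum(noisy2 == 0L), 1000L)
  expect_identical(sum(noisy2 == 255L), 1000L)
  expect_identical(sum(noisy2 != 128L), 2000L)

  # odd count: extra impulse goes to pepper
  noisy3 <- add_salt_pepper(im, count = 7, seed = 2)
  expect_identical(sum(noisy3 == 0L), 4L)
  expect_identical(sum(noisy3 == 255L), 3L)

  expect_identical(add_salt_pepper(im, density = 0), im)
  expect_error(add_salt_pepper(im, count = 1e5), "pixel count")
})

test_that("gaussian noise perturbs mildly and deterministically", {
  im <- matrix(128L, 100, 100)
  expect_identical(add_gaussian_noise(im, 0), im)
  a <- add_gaussian_noise(im, 1, seed = 11)
  b <- add_gaussian_noise(im, 1, seed = 11)
  expect_identical(a, b)
  expect_lt(abs(mean(a) - 128), 0.1)
  expect_error(add_gaussian_noise(im, -1), ">= 0")
})

test_that("layouts cover their region ids with expected geometry", {
  expect_identical(sort(unique(as.vector(layout_bands(8, 9, 3)))), 1:3)
  expect_equal(as.vector(table(layout_bands(8, 9, 3))), c(24, 24, 24))
  sq <- layout_concentric(8, 8)
  expect_identical(sort(unique(as.vector(sq))), 1:2)
  expect_true(all(sq[3:6, 3:6] == 2L))
  expect_true(all(sq[1, ] == 1L))
})
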
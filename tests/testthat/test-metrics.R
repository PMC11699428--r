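test_that("rmse matches closed forms", {
  a <- matrix(100L, 4, 4)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(matrix(0L, 4, 4), matrix(255L, 4, 4)), 255)
  b <- a; b[1:8] <- 102L   # half the pixels differ by 2
  expect_equal(rmse(a, b), sqrt(2))
  expect_error(rmse(a, matrix(0L, 3, 3)), "dimensions")
})

test_that("psnr matches closed forms with an infinite self-similarity", {
  expect_equal(psnr(matrix(0L, 4, 4), matrix(255L, 4, 4)), 0)
  # one pixel of four differing by 51 gives RMSE 25.5, hence 20 dB
  d <- matrix(0L, 2, 2); e <- d; e[1, 1] <- 51L
  expect_equal(rmse(d, e), 25.5)
  expect_equal(psnr(d, e), 20)
  a <- matrix(128L, 3, 3)
  expect_identical(psnr(a, a), Inf)
})

test_that("global ssim is 1 on identical images and symmetric", {
  im <- rand_gray(12, 12, seed = 21)
  expect_equal(ssim(im, im), 1, tolerance = 1e-12)
  other <- rand_gray(12, 12, seed = 22)
  expect_equal(ssim(im, other), ssim(other, im))
})

test_that("ssim on constant images matches direct substitution", {
  a <- matrix(51L, 10, 10)   # 0.2 after rescaling
  b <- matrix(204L, 10, 10)  # 0.8
  hand <- (2 * 0.2 * 0.8 + 0.065) * (0 + 0.065) /
    ((0.2^2 + 0.8^2 + 0.065) * (0 + 0 + 0.065))
  expect_equal(ssim(a, b), hand)
})

test_that("ssim product form differs from covariance form off-diagonal", {
  set.seed(31)
  im <- rand_gray(16, 16)
  noisy <- add_gaussian_noise(im, 20, seed = 1)
  expect_false(isTRUE(all.equal(ssim(im, noisy, form = "product"),
                                ssim(im, noisy, form = "covariance"))))
  # product form does not self-certify: < 1 on identical non-constant
  # images is expected only for the covariance form to equal 1
  expect_equal(ssim(im, im, form = "covariance"), 1, tolerance = 1e-12)
})

test_that("fsim is 1 on identical images, bounded, and symmetric", {
  sp <- synth_spec(32, 32, region_means = c(60, 190),
                   region_stds = c(10, 10), seed = 8)
  im <- generate_region_image(sp)$image
  expect_equal(fsim(im, im), 1, tolerance = 1e-12)
  other <- add_salt_pepper(im, count = 60, seed = 2)
  v <- fsim(im, other)
  expect_gte(v, 0); expect_lte(v, 1)
  expect_lt(v, 1)
  expect_equal(fsim(other, im), v)
  expect_error(fsim(im[1:8, ], other[1:8, ]), "16 x 16")
})

test_that("metrics degrade monotonically with added impulse noise", {
  sp <- synth_spec(48, 48, region_means = c(50, 200),
                   region_stds = c(10, 10), seed = 14)
  clean <- generate_region_image(sp)$image
  counts <- c(50, 200, 600)
  ps <- vapply(counts, function(np) {
    psnr(clean, add_salt_pepper(clean, count = np, seed = 99))
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("quality_report bundles all four metrics", {
  im <- rand_gray(20, 20, seed = 41)
  qr <- quality_report(im, im)
  expect_named(qr, c("psnr", "rmse", "ssim", "fsim"))
  expect_identical(qr$psnr, Inf)
  expect_equal(qr$ssim, 1, tolerance = 1e-10)
})
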
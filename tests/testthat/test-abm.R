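test_that("neighbor consensus reads the neighborhood majority", {
  im <- matrix(128L, 3, 3)
  expect_identical(neighbor_consensus(im, 2, 2), 0L)

  im2 <- matrix(200L, 3, 3); im2[2, 2] <- 10L
  expect_identical(neighbor_consensus(im2, 2, 2), 1L)

  # evenly split neighborhood: an edge agent stays put
  im3 <- matrix(c(255, 255, 0, 255, 128, 0, 255, 0, 0), 3, 3)
  storage.mode(im3) <- "integer"
  expect_identical(neighbor_consensus(im3, 2, 2), 0L)

  # boundary agents use only in-grid neighbors
  im4 <- matrix(0L, 2, 2); im4[1, 1] <- 10L
  expect_identical(neighbor_consensus(im4, 1, 1), -1L)
  expect_error(neighbor_consensus(im, 0, 1), "out of bounds")
})

test_that("rules move states by exactly delta and clamp", {
  expect_equal(apply_rule(100, 1L, 1), 101)
  expect_equal(apply_rule(100, -1L, 5), 95)
  expect_equal(apply_rule(100, 0L, 5), 100)
  expect_equal(apply_rule(0, -1L, 1), 0)
  expect_equal(apply_rule(254, 1L, 5), 255)
})

test_that("one sweep matches the literal rule transcription", {
  set.seed(101)
  for (rep in 1:5) {
    g <- rand_gray(6, 6)
    for (upd in c("synchronous", "sequential")) {
      for (nb in c("moore", "von-neumann")) {
        for (sc in c("right-to-left", "left-to-right")) {
          cfg <- abm_config(delta = 2L, neighborhood = nb,
                            scan_order = sc, update = upd)
          expect_identical(abm_step(g, cfg),
                           sweep_oracle(g, 2L, nb, sc, upd),
                           info = paste(upd, nb, sc))
        }
      }
    }
  }
})

test_that("uniform grids are fixed points for any delta", {
  for (d in c(1L, 3L, 9L)) {
    im <- matrix(77L, 7, 7)
    expect_identical(abm_step(im, abm_config(delta = d)), im)
  }
})

test_that("sweeps stay bounded and move each pixel by at most delta", {
  set.seed(5)
  g <- rand_gray(12, 12)
  cur <- g
  for (t in 1:20) {
    nxt <- abm_step(cur, abm_config(delta = 4L))
    expect_lte(max(abs(nxt - cur)), 4L)
    expect_gte(min(nxt), 0L)
    expect_lte(max(nxt), 255L)
    cur <- nxt
  }
})

test_that("an isolated impulse climbs delta per sweep toward its region", {
  im <- matrix(200L, 5, 5); im[3, 3] <- 0L
  s1 <- abm_step(im, abm_config(delta = 1L))
  expect_identical(s1[3, 3], 1L)
  expect_lte(max(abs(s1 - im)), 1L)
  # the climb is delta per sweep while the gap exceeds the ring dip
  cur <- im
  for (t in 1:150) cur <- abm_step(cur, abm_config(delta = 1L))
  expect_identical(cur[3, 3], 150L)
})

test_that("run_abm with zero iterations is the identity", {
  g <- rand_gray(8, 8, seed = 2)
  expect_identical(run_abm(g, abm_config(iter1 = 0L)), g)
})

test_that("variance trace records per-sweep homogenization", {
  sp <- synth_spec(40, 40, region_means = c(50, 200),
                   region_stds = c(15, 15), seed = 9)
  im <- generate_region_image(sp)$image
  out <- run_abm(im, abm_config(iter1 = 30L, delta = 1L), trace = TRUE)
  v <- attr(out, "variance")
  expect_length(v, 31L)
  expect_equal(v[1], var(as.numeric(im)))
})

test_that("config validation rejects bad parameters", {
  expect_error(abm_config(iter1 = -1), ">= 0")
  expect_error(abm_config(delta = 0), ">= 1")
  expect_error(abm_config(delta = 1.5), ">= 1")
})
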
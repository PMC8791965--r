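test_that("channel-max heatmap takes the max absolute activation per pixel", {
  f <- array(0, dim = c(2, 2, 2))
  f[, , 1] <- rbind(c(1, -3), c(0, 2))
  f[, , 2] <- rbind(c(2, 1), c(-1, -5))
  h <- channel_max_heatmap(f)
  expect_equal(unclass(h), rbind(c(2, 3), c(1, 5)), ignore_attr = TRUE)
  expect_equal(attr(h, "stage"), "raw")

  f1 <- array(rnorm(16), dim = c(4, 4, 1))
  expect_equal(unclass(channel_max_heatmap(f1)), abs(f1[, , 1]),
               ignore_attr = TRUE)

  # brute-force oracle over a random block
  set.seed(8)
  fr <- array(rnorm(5 * 5 * 8), dim = c(5, 5, 8))
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    best <- -Inf
    for (k in 1:8) best <- max(best, abs(fr[i, j, k]))
    oracle[i, j] <- best
  }
  expect_equal(unclass(channel_max_heatmap(fr)), oracle, ignore_attr = TRUE)

  # permutation invariance in channel order
  perm <- sample(8)
  expect_equal(unclass(channel_max_heatmap(fr[, , perm])),
               unclass(channel_max_heatmap(fr)))

  expect_error(channel_max_heatmap(array(1, dim = c(2, 2))), "array")
  expect_error(channel_max_heatmap(array(Inf, dim = c(2, 2, 1))), "finite")
})

test_that("truncated-ReLU normalization maps heatmaps into [0, 1]", {
  h <- attention_heatmap(rbind(c(0.5, 2), c(0, 4)), "raw")
  n <- normalize_heatmap(h)
  expect_equal(unclass(n), rbind(c(0.125, 0.5), c(0, 1)), ignore_attr = TRUE)
  expect_equal(attr(n, "stage"), "normalized")

  # already scaled with the max at the ceiling: unchanged under q = 100
  m <- matrix(c(0, 0.3, 0.6, 1), 2)
  expect_equal(unclass(normalize_heatmap(attention_heatmap(m, "raw"))), m,
               ignore_attr = TRUE)

  # all-zero maps pass through (degenerate early-training feature maps)
  z <- normalize_heatmap(attention_heatmap(matrix(0, 3, 3), "raw"))
  expect_true(all(unclass(z) == 0))

  # percentile ceiling clamps single-pixel spikes to 1
  sp <- matrix(1, 10, 10); sp[5, 5] <- 1000
  n90 <- normalize_heatmap(attention_heatmap(sp, "raw"), q = 90)
  expect_equal(max(n90), 1)
  expect_gt(sum(unclass(n90) == 1), 1)
})

test_that("bilinear upsampling is bounded and exact on constants", {
  cst <- attention_heatmap(matrix(0.4, 3, 3), "normalized")
  up <- upsample_heatmap(cst, c(12, 12))
  expect_equal(dim(up), c(12L, 12L))
  expect_true(all(abs(unclass(up) - 0.4) < 1e-12))
  expect_equal(attr(up, "stage"), "normalized")

  chk <- attention_heatmap(rbind(c(0, 1), c(1, 0)), "raw")
  u4 <- upsample_heatmap(chk, c(4, 4))
  expect_true(all(u4[2:3, 2:3] > 0 & u4[2:3, 2:3] < 1))

  set.seed(2)
  for (i in 1:20) {
    hm <- attention_heatmap(matrix(runif(49), 7, 7), "raw")
    uu <- upsample_heatmap(hm, c(224, 224))
    expect_lte(max(uu), max(hm) + 1e-6)
    expect_gte(min(uu), min(hm) - 1e-6)
  }

  expect_error(upsample_heatmap(cst, c(2, 2)), ">=")
})

test_that("Gaussian re-weighting decays by the closed form and never amplifies", {
  # on-grid center so the peak and the one-sigma offset land on pixels
  g <- gaussian_weight(225, 225, center = c(112, 112), sigma = 30)
  expect_equal(max(g), 1)
  expect_true(all(g > 0))

  ctr <- attr(g, "center")
  h <- attention_heatmap(matrix(0.8, 225, 225), "normalized")
  w <- gaussian_reweight(h, g)
  expect_equal(w[ctr[1] + 1, ctr[2] + 1], 0.8, tolerance = 1e-9)
  # one sigma from the center along a row: 0.8 * exp(-1/2)
  expect_equal(w[ctr[1] + 1, ctr[2] + 1 + 30], 0.8 * exp(-0.5),
               tolerance = 1e-9)
  expect_true(all(unclass(w) <= unclass(h) + 1e-12))

  flat <- gaussian_weight(225, 225, sigma = 1e6)
  wf <- gaussian_reweight(h, flat)
  expect_equal(unclass(wf), unclass(h), tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(gaussian_weight(8, 8, sigma = 0), "positive")
  expect_error(gaussian_reweight(attention_heatmap(matrix(1, 4, 4), "raw"),
                                 gaussian_weight(4, 4)), "Normalize")
})

test_that("masking multiplies every slice by the heatmap", {
  set.seed(5)
  px <- array(rnorm(6 * 6 * 3), dim = c(6, 6, 3))
  sl <- plane_slab(px)
  hm <- attention_heatmap(matrix(runif(36), 6, 6), "gaussian_weighted")

  ones <- attention_heatmap(matrix(1, 6, 6), "gaussian_weighted")
  expect_equal(apply_mask(sl, ones)$pixels, px)
  zeros <- attention_heatmap(matrix(0, 6, 6), "gaussian_weighted")
  expect_true(all(apply_mask(sl, zeros)$pixels == 0))

  out <- apply_mask(sl, hm)$pixels
  oracle <- array(0, dim = dim(px))
  for (i in 1:6) for (j in 1:6) for (s in 1:3) {
    oracle[i, j, s] <- px[i, j, s] * hm[i, j]
  }
  expect_equal(out, oracle)

  expect_error(apply_mask(sl, attention_heatmap(matrix(1, 4, 4),
                                                "gaussian_weighted")),
               "match")
})

test_that("normalized heatmaps stay in [0, 1] under fuzzing", {
  set.seed(99)
  for (i in 1:200) {
    d <- sample(2:12, 2)
    raw <- matrix(rnorm(prod(d), sd = 10^runif(1, -3, 3)), d[1], d[2])
    n <- normalize_heatmap(attention_heatmap(abs(raw), "raw"),
                           q = sample(c(80, 95, 100), 1))
    expect_gte(min(n), 0)
    expect_lte(max(n), 1)
  }
})
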
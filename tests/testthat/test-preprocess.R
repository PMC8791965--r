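# stack whose slice s has constant value s, for index bookkeeping
indexed_stack <- function(L, size = 8) {
  array(rep(seq_len(L), each = size^2), dim = c(size, size, L))
}

test_that("select_slices centers a contiguous window on the middle slice", {
  # 23-slice stack (a typical clinical stack length), 3 slices -> 0-based
  # indices 10, 11, 12
  sl <- select_slices(indexed_stack(23), 3)
  expect_equal(unique(as.vector(sl$pixels[, , 1])), 11)
  expect_equal(unique(as.vector(sl$pixels[, , 3])), 13)
  expect_equal(sl$n_slices, 3L)

  expect_equal(unique(as.vector(select_slices(indexed_stack(7), 1)$pixels)), 4)

  # even-length stack: lower-middle convention, 0-based middle = 3
  sl8 <- select_slices(indexed_stack(8), 3)
  expect_equal(as.vector(apply(sl8$pixels, 3, mean)), c(3, 4, 5))

  # ascending, contiguous
  sl5 <- select_slices(indexed_stack(11), 5)
  expect_equal(as.vector(apply(sl5$pixels, 3, mean)), 4:8)

  expect_error(select_slices(indexed_stack(2), 3, subject_id = "abc"), "abc")
  expect_error(select_slices(indexed_stack(9), 4), "1, 3 or 5")
})

test_that("crop handles centering, identity, randomness and padding", {
  x <- array(rnorm(256 * 256 * 3), dim = c(256, 256, 3))
  sl <- plane_slab(x)
  cc <- crop(sl, 224)
  expect_equal(dim(cc$pixels), c(224, 224, 3))
  expect_equal(cc$pixels, x[17:240, 17:240, ])  # offset (16, 16)

  same <- crop(plane_slab(x[1:224, 1:224, ]), 224)
  expect_equal(same$pixels, x[1:224, 1:224, ])

  # random crops: deterministic given seed, one offset shared across slices
  r1 <- crop(sl, 224, mode = "random", seed = 4)
  r2 <- crop(sl, 224, mode = "random", seed = 4)
  expect_identical(r1, r2)
  hit <- which(x[, , 2] == r1$pixels[1, 1, 2], arr.ind = TRUE)
  expect_equal(x[hit[1] + 0:223, hit[2] + 0:223, 1], r1$pixels[, , 1])

  # undersized input: symmetric zero-padding, then crop
  small <- plane_slab(array(1, dim = c(200, 260, 1)))
  pc <- crop(small, 224)
  expect_equal(dim(pc$pixels), c(224, 224, 1))
  expect_equal(sum(pc$pixels[, , 1] == 0), 224 * 224 - 200 * 224)
  expect_true(all(pc$pixels[13:212, , 1] == 1))
})

test_that("normalization uses joint slab moments and is affine-invariant", {
  v <- array(rep(c(0, 2), 32), dim = c(4, 4, 4))
  n <- normalize_sample(plane_slab(v))
  expect_setequal(unique(as.vector(n$pixels)), c(-1, 1))

  set.seed(1)
  x <- plane_slab(array(rexp(4 * 4 * 3), dim = c(4, 4, 3)))
  nx <- normalize_sample(x)
  expect_lt(abs(mean(nx$pixels)), 1e-6)
  pop_sd <- sqrt(mean((nx$pixels - mean(nx$pixels))^2))
  expect_lt(abs(pop_sd - 1), 1e-6)

  # idempotence and invariance to positive affine maps
  expect_equal(normalize_sample(nx)$pixels, nx$pixels, tolerance = 1e-6)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    y <- x; y$pixels <- a * x$pixels + b
    expect_equal(normalize_sample(y)$pixels, nx$pixels, tolerance = 1e-6)
  }

  expect_error(normalize_sample(plane_slab(array(3, dim = c(4, 4, 2)))),
               "constant")
})

test_that("dataset splitting follows the floor rule with no leakage", {
  man <- tibble::tibble(subject_id = sprintf("s%03d", 1:741),
                        age_days = runif(741, 133, 273))
  sp <- split_dataset(man, seed = 2)
  expect_equal(as.vector(table(sp$partition)), c(518, 74, 149))
  expect_identical(sp, split_dataset(man, seed = 2))
  expect_false(identical(sp$partition, split_dataset(man, seed = 3)$partition))
  expect_equal(sort(sp$subject_id), sort(man$subject_id))
  expect_equal(anyDuplicated(sp$subject_id), 0L)

  sp10 <- split_dataset(man[1:10, ], seed = 1)
  expect_equal(as.vector(table(sp10$partition)), c(7, 1, 2))

  expect_error(split_dataset(man[0, ]), "Empty")
  expect_error(split_dataset(man, fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("fine-tuning splits reserve floor(fraction * n) for adaptation", {
  man <- function(n) tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                                    age_days = 150 + seq_len(n))
  sp25 <- finetune_split(man(25), seed = 1)
  expect_equal(nrow(sp25$adapt), 5L)
  expect_equal(nrow(sp25$test), 20L)

  sp189 <- finetune_split(man(189), seed = 1)
  expect_equal(nrow(sp189$adapt), 37L)
  expect_equal(nrow(sp189$test), 152L)

  sp10 <- finetune_split(man(10), seed = 1)
  expect_equal(nrow(sp10$adapt), 2L)
  expect_length(intersect(sp10$adapt$subject_id, sp10$test$subject_id), 0L)

  expect_error(finetune_split(man(4)), "At least 5")
})

test_that("prepare_dataset yields normalized model-ready slabs per plane", {
  cfg <- phantom_config()
  manifest <- generate_cohort(cfg, 3, seed = 5)
  d <- prepare_dataset(manifest, n_slices = 3, size = 64)
  expect_named(d, c("subject_id", "age_days", "slab_axial", "slab_coronal",
                    "slab_sagittal"))
  sl <- d$slab_coronal[[2]]
  expect_s3_class(sl, "plane_slab")
  expect_equal(dim(sl$pixels), c(64, 64, 3))
  expect_lt(abs(mean(sl$pixels)), 1e-6)
})
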
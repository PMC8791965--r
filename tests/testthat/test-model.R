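tiny_spec <- function(ch = 3L, size = 32L) {
  backbone_spec("tiny", in_channels = ch, input_size = size)
}

rand_slab <- function(ch = 3L, size = 32L, seed = 1) {
  set.seed(seed)
  plane_slab(array(rnorm(size * size * ch), dim = c(size, size, ch)),
             plane = "axial", subject_id = "t1")
}

test_that("built models honor the input-channel and mode contracts", {
  m <- build_model(tiny_spec(3), "dual", seed = 2)
  expect_equal(dim(m$global$features[[1]]$w)[3], 3L)
  fd <- forward_dual(m, rand_slab(3))
  expect_true(is.finite(fd$prediction$y_global))
  expect_true(is.finite(fd$prediction$y_local))
  expect_s3_class(fd$heatmap, "attention_heatmap")
  expect_equal(attr(fd$heatmap, "stage"), "gaussian_weighted")

  m1 <- build_model(tiny_spec(1), "dual", seed = 2)
  expect_equal(dim(m1$global$features[[1]]$w)[3], 1L)

  g <- build_model(tiny_spec(3), "global_only", seed = 2)
  expect_null(g$local)
  fg <- forward_dual(g, rand_slab(3))
  expect_equal(fg$prediction$y_pred, fg$prediction$y_global)
  expect_true(is.na(fg$prediction$y_local))
  expect_null(fg$heatmap)

  expect_error(forward_dual(m, rand_slab(1)), "expects")
  expect_error(backbone_spec("vgg"), "arg")
  expect_error(backbone_spec("tiny", in_channels = 2), "1, 3 or 5")
  expect_error(backbone_spec("tiny", pretrained = TRUE), "weights file")
})

test_that("fusion is the exact arithmetic mean of the branch outputs", {
  m <- build_model(tiny_spec(3), "dual", seed = 6)
  for (s in 1:3) {
    fd <- forward_dual(m, rand_slab(3, seed = s))
    expect_identical(fd$prediction$y_pred,
                     (fd$prediction$y_global + fd$prediction$y_local) / 2)
  }
})

test_that("all slice-count variants run a full forward/backward pass", {
  for (ch in c(1L, 3L, 5L)) {
    m <- build_model(tiny_spec(ch), "dual", seed = 3)
    x <- fetalage:::slab_batch(list(rand_slab(ch, seed = ch)))
    fwd <- fetalage:::dual_forward(m, x)
    expect_true(is.finite(fwd$y_pred))
    grads <- fetalage:::dual_backward(m, fwd, gy_global = 1, gy_local = 1)
    expect_true(all(vapply(grads, function(g) all(is.finite(g)), logical(1))))
    expect_setequal(names(grads), names(fetalage:::model_params(m)))
  }
})

test_that("residual families build with the reference feature depths", {
  r18 <- build_model(backbone_spec("resnet18", in_channels = 1,
                                   input_size = 64), "global_only", seed = 1)
  expect_equal(r18$global$K, 512L)
  f <- forward_dual(r18, rand_slab(1, 64))
  expect_true(is.finite(f$prediction$y_pred))

  r50 <- build_model(backbone_spec("resnet50", in_channels = 3,
                                   input_size = 64), "global_only", seed = 1)
  expect_equal(r50$global$K, 2048L)
  expect_equal(dim(r50$global$features[[1]]$w), c(7, 7, 3, 64))
})

test_that("pretrained first-layer kernels adapt by averaged replication", {
  set.seed(4)
  w <- array(rnorm(7 * 7 * 3 * 8), dim = c(7, 7, 3, 8))
  for (ch in c(1L, 5L)) {
    a <- adapt_first_conv(w, ch)
    expect_equal(dim(a), c(7, 7, ch, 8))
    # total response to a channel-replicated input is preserved
    expect_equal(apply(a, c(1, 2, 4), sum), apply(w, c(1, 2, 4), sum),
                 tolerance = 1e-12)
  }
  expect_error(adapt_first_conv(array(1, dim = c(3, 3, 2, 4)), 1), "kernel")
})

test_that("multi-plane predictions average the per-plane fused outputs", {
  mm <- build_multiplane_model(tiny_spec(1), seed = 5)
  cfg <- phantom_config(image_size = 64)
  man <- generate_cohort(cfg, 3, seed = 11)
  d <- prepare_dataset(man, n_slices = 1, size = 32)
  pred <- multiplane_predict(mm, d)
  expect_equal(pred$y_pred,
               rowMeans(cbind(pred$y_pred_axial, pred$y_pred_coronal,
                              pred$y_pred_sagittal)))
  expect_equal(pred$y_true, man$age_days)

  # single available plane: the fused output is that plane's output
  d1 <- d[, c("subject_id", "age_days", "slab_coronal")]
  p1 <- multiplane_predict(mm, d1)
  expect_equal(p1$y_pred, p1$y_pred_coronal)

  # identical inputs and identical weights across planes: symmetry
  ms <- build_multiplane_model(tiny_spec(1), seed = 5, share_weights = TRUE)
  d_same <- d
  d_same$slab_coronal <- d_same$slab_axial
  d_same$slab_sagittal <- d_same$slab_axial
  ps <- multiplane_predict(ms, d_same)
  expect_equal(ps$y_pred, ps$y_pred_axial, tolerance = 1e-5)

  expect_error(multiplane_predict(mm, d[, 1:2]), "No plane")
})

test_that("the local-branch loss backpropagates into global weights", {
  set.seed(3)
  x <- array(rnorm(32 * 32 * 1 * 2), dim = c(32, 32, 1, 2))
  t_b <- c(150, 220)
  m <- build_model(tiny_spec(1), "dual", seed = 11)
  fwd <- fetalage:::dual_forward(m, x)
  gy_l <- 2 * (fwd$y_local - t_b) / 2
  grads <- fetalage:::dual_backward(m, fwd, gy_global = c(0, 0),
                                    gy_local = gy_l)
  # nonzero gradient reaches the global stem through the attention mask
  expect_gt(max(abs(grads$g.L1.w)), 0)

  # with the mask stop-gradient, that path is severed
  m2 <- build_model(tiny_spec(1), "dual", seed = 11,
                    gradient_through_mask = FALSE)
  fwd2 <- fetalage:::dual_forward(m2, x)
  grads2 <- fetalage:::dual_backward(m2, fwd2, gy_global = c(0, 0),
                                     gy_local = gy_l)
  expect_equal(max(abs(grads2$g.L1.w)), 0)

  # and the finite-difference check confirms the gradient is exact
  p <- fetalage:::model_params(m)
  loss_fn <- function(mm) {
    f <- fetalage:::dual_forward(mm, x)
    mean((f$y_local - t_b)^2)
  }
  nm <- "g.L4.w"
  idx <- which.max(abs(grads[[nm]]))
  h <- 1e-5
  p1 <- p; p1[[nm]][idx] <- p[[nm]][idx] + h
  p2 <- p; p2[[nm]][idx] <- p[[nm]][idx] - h
  fd <- (loss_fn(fetalage:::set_model_params(m, p1)) -
           loss_fn(fetalage:::set_model_params(m, p2))) / (2 * h)
  expect_equal(grads[[nm]][idx], fd, tolerance = 1e-4)
})
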
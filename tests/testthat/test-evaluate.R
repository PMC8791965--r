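test_that("R-squared matches its definition and a two-pass oracle", {
  y <- c(140, 180, 220, 260)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)

  set.seed(20)
  for (i in 1:100) {
    yt <- rnorm(30, 200, 30)
    yp <- yt + rnorm(30, 0, 10)
    ss_res <- 0; ss_tot <- 0; m <- sum(yt) / 30
    for (k in 1:30) {
      ss_res <- ss_res + (yt[k] - yp[k])^2
      ss_tot <- ss_tot + (yt[k] - m)^2
    }
    expect_equal(r2_score(yt, yp), 1 - ss_res / ss_tot, tolerance = 1e-10)
  }
  # asymmetric in its arguments, unlike concordance
  yt <- c(1, 2, 3, 4); yp <- c(1.1, 2.2, 2.9, 4.4)
  expect_false(isTRUE(all.equal(r2_score(yt, yp), r2_score(yp, yt))))
  expect_error(r2_score(rep(1, 5), 1:5), "constant")
})

test_that("MAE matches a loop oracle", {
  expect_equal(mae_days(c(10, 10, 10), c(11, 8, 13)), 2)
  expect_equal(mae_days(1:5, 1:5), 0)
  set.seed(21)
  for (i in 1:100) {
    yt <- rnorm(25); yp <- rnorm(25)
    acc <- 0
    for (k in 1:25) acc <- acc + abs(yt[k] - yp[k])
    expect_equal(mae_days(yt, yp), acc / 25, tolerance = 1e-12)
  }
})

test_that("Lin's concordance follows the population-moment definition", {
  y <- c(140, 200, 260)
  expect_equal(lin_ccc(y, y)$ccc, 1)

  # hand-evaluated: cov = 2/3, both variances 2/3, mean gap 1 -> 4/7
  cc <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cc$ccc, 4 / 7, tolerance = 1e-12)
  expect_lte(cc$ci_low, cc$ccc)
  expect_gte(cc$ci_high, cc$ccc)

  set.seed(22)
  for (i in 1:100) {
    yt <- rnorm(20, 0, runif(1, 0.5, 3))
    yp <- 0.5 * yt + rnorm(20, runif(1, -1, 1))
    cc <- lin_ccc(yt, yp)$ccc
    # independent recomputation with explicit population moments
    n <- 20
    m1 <- sum(yt) / n; m2 <- sum(yp) / n
    v1 <- sum((yt - m1)^2) / n; v2 <- sum((yp - m2)^2) / n
    cv <- sum((yt - m1) * (yp - m2)) / n
    expect_equal(cc, 2 * cv / (v1 + v2 + (m1 - m2)^2), tolerance = 1e-9)
    # agreement never exceeds correlation in magnitude
    expect_lte(abs(cc), abs(cor(yt, yp)) + 1e-12)
    # symmetric in its arguments
    expect_equal(cc, lin_ccc(yp, yt)$ccc, tolerance = 1e-12)
  }

  # sample-moment variant differs for biased pairs
  expect_false(isTRUE(all.equal(
    lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc,
    lin_ccc(c(1, 2, 3), c(2, 3, 4), moments = "sample")$ccc)))
  expect_error(lin_ccc(rep(1, 5), 1:5), "Constant")
})

test_that("McBride classes follow the printed bins", {
  expect_equal(as.character(mcbride_class(0.970)), "substantial")
  expect_equal(as.character(mcbride_class(0.89)), "poor")
  expect_equal(as.character(mcbride_class(0.995)), "almost_perfect")
  # boundary convention
  expect_equal(as.character(mcbride_class(0.90)), "moderate")
  expect_equal(as.character(mcbride_class(0.95)), "substantial")
  expect_equal(as.character(mcbride_class(0.99)), "substantial")
  expect_equal(as.character(mcbride_class(-1)), "poor")
  expect_error(mcbride_class(1.2), "ccc")
})

test_that("quantile agreement curves collapse to a constant offset", {
  set.seed(23)
  yt <- sort(runif(60, 140, 270))
  qc <- bland_altman_quantiles(yt, yt + 4.5)
  expect_true(all(abs(qc$diff_days - 4.5) < 1e-9))
  expect_setequal(unique(qc$quantile), c(5, 10, 25, 50, 75, 90, 95))
  expect_error(bland_altman_quantiles(yt[1:10], yt[1:10]), "at least 15")
})

test_that("quantile curves are monotone in quantile level", {
  set.seed(24)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    yt <- runif(n, 100, 300)
    yp <- yt + rnorm(n, 0, runif(1, 0.5, 15))
    qc <- bland_altman_quantiles(yt, yp)
    wide <- tidyr::pivot_wider(qc, names_from = "quantile",
                               values_from = "diff_days")
    mat <- as.matrix(wide[, -1])
    expect_true(all(diff(t(mat)) >= -1e-9))
  }
})

test_that("a bias knot flips the sign of the median curve", {
  set.seed(25)
  yt <- sort(runif(120, 140, 280))
  knot <- 210
  b <- 6
  yp <- yt + ifelse(yt < knot, b, -b) + rnorm(120, 0, 0.5)
  qc <- bland_altman_quantiles(yt, yp)
  med <- qc[qc$quantile == 50, ]
  expect_gt(med$diff_days[which.min(med$age_days)], 0)
  expect_lt(med$diff_days[which.max(med$age_days)], 0)
})

test_that("evaluation reports expose tidy, glance and plots", {
  set.seed(26)
  yt <- runif(40, 140, 270)
  pred <- tibble::tibble(y_true = yt, y_pred = yt)
  ev <- evaluate_predictions(pred)
  expect_equal(ev$r2, 1)
  expect_equal(ev$mae, 0)
  expect_equal(ev$ccc, 1)
  expect_equal(as.character(ev$mcbride), "almost_perfect")

  g <- glance(ev)
  expect_equal(nrow(g), 1L)
  expect_equal(g$mcbride, "almost_perfect")
  td <- tidy(ev)
  expect_true(all(c("metric", "value") %in% names(td)))

  noisy <- tibble::tibble(y_true = yt, y_pred = yt + rnorm(40, 0, 5))
  ev2 <- evaluate_predictions(noisy)
  expect_s3_class(autoplot(ev2), "ggplot")
  expect_s3_class(autoplot(ev2, "bland_altman"), "ggplot")
  expect_s3_class(autoplot(ev2$curves), "ggplot")
  expect_output(print(ev2), "Lin's CCC")
})

test_that("localization hits respect the dilation radius", {
  mask <- matrix(FALSE, 20, 20)
  mask[9:12, 9:12] <- TRUE
  h <- matrix(0, 20, 20)
  h[10, 10] <- 1
  expect_true(localization_hit(h, mask))
  h2 <- matrix(0, 20, 20); h2[17, 10] <- 1   # 5 px below the mask edge
  expect_true(localization_hit(h2, mask, dilate_px = 5))
  h3 <- matrix(0, 20, 20); h3[20, 20] <- 1
  expect_false(localization_hit(h3, mask, dilate_px = 5))
})
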
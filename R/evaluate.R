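#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Predicting the mean of
#' the truth scores exactly 0; perfect predictions score 1.
#'
#' @param y_true,y_pred Numeric vectors of equal length, `n >= 2`,
#'   non-constant truth.
#' @return The R-squared value (unitless, at most 1).
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) < 2L || length(y_true) != length(y_pred)) {
    abort("Need equal-length vectors with n >= 2.")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("`y_true` is constant; R-squared is undefined.")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean absolute error in days
#'
#' @param y_true,y_pred Numeric vectors of equal length (days).
#' @return Mean of `|y_true - y_pred|`, in days.
#' @export
mae_days <- function(y_true, y_pred) {
  if (length(y_true) < 1L || length(y_true) != length(y_pred)) {
    abort("Need equal-length non-empty vectors.")
  }
  mean(abs(y_true - y_pred))
}

#' Lin's concordance correlation coefficient with 95% confidence interval
#'
#' `rho_c = 2 cov(y, yhat) / (var(y) + var(yhat) + (mean gap)^2)`, with
#' population (1/n) moments by default, following Lin's original
#' definition; sample (1/(n-1)) moments are available as an option. The
#' confidence interval uses the Fisher z-transform of `rho_c` with Lin's
#' asymptotic variance, back-transformed.
#'
#' @param y_true,y_pred Non-constant numeric vectors, `n >= 3`.
#' @param conf_level Confidence level for the interval.
#' @param moments `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return A tibble with columns `ccc`, `ci_low`, `ci_high`, `n`.
#' @export
lin_ccc <- function(y_true, y_pred, conf_level = 0.95,
                    moments = c("population", "sample")) {
  moments <- match.arg(moments)
  n <- length(y_true)
  if (n < 3L || n != length(y_pred)) {
    abort("Need equal-length vectors with n >= 3.")
  }
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    abort("Constant vectors have no defined concordance.")
  }
  m1 <- mean(y_true); m2 <- mean(y_pred)
  denom_n <- if (moments == "population") n else n - 1L
  s1 <- sum((y_true - m1)^2) / denom_n
  s2 <- sum((y_pred - m2)^2) / denom_n
  s12 <- sum((y_true - m1) * (y_pred - m2)) / denom_n
  ccc <- 2 * s12 / (s1 + s2 + (m1 - m2)^2)

  r <- s12 / sqrt(s1 * s2)
  u <- (m1 - m2) / (s1 * s2)^0.25
  z <- atanh(ccc)
  # Lin's asymptotic variance of z (1989, corrected 2000)
  sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
          2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
          ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(max(sz2, 0))
  tibble::tibble(ccc = ccc,
                 ci_low = tanh(z - half), ci_high = tanh(z + half), n = n)
}

#' McBride strength-of-agreement class for a concordance coefficient
#'
#' Bins: poor `< 0.90`; moderate `[0.90, 0.95)`; substantial
#' `[0.95, 0.99]`; almost perfect `> 0.99`.
#'
#' @param ccc A concordance value in `[-1, 1]`.
#' @return A factor level among poor / moderate / substantial /
#'   almost_perfect.
#' @export
mcbride_class <- function(ccc) {
  assert_number(ccc, "ccc", lower = -1, upper = 1)
  cls <- if (ccc < 0.90) "poor"
         else if (ccc < 0.95) "moderate"
         else if (ccc <= 0.99) "substantial"
         else "almost_perfect"
  factor(cls, levels = c("poor", "moderate", "substantial", "almost_perfect"))
}

gaussian_kernel_smooth <- function(y, sigma) {
  if (sigma <= 0 || length(y) < 2L) return(y)
  idx <- seq_along(y)
  vapply(idx, function(i) {
    w <- exp(-((idx - i)^2) / (2 * sigma^2))
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' Quantile curves for a modified Bland-Altman agreement analysis
#'
#' Pairs are sorted by true age; a sliding window of `window` points
#' (advancing by `max(1, round((1 - overlap) * window))` points — one
#' point at the default 95% overlap) yields the empirical 5/10/25/50/75/
#' 90/95% quantiles of the prediction differences `y_pred - y_true`,
#' located at the window's median true age. Each quantile series is then
#' smoothed with a discrete Gaussian kernel. Because the same linear
#' positive-weight smoother is applied to every level, curves stay
#' monotone across quantile levels at every evaluation point.
#'
#' @param y_true,y_pred Numeric vectors, `n >= window`.
#' @param quantiles Quantile levels of the difference distribution.
#' @param window Window size in points.
#' @param overlap Fractional overlap between consecutive windows.
#' @param smooth_sigma Gaussian smoothing bandwidth in window positions.
#' @return A `ga_quantile_curves` tibble in long form: `age_days`
#'   (window median true age), `quantile` (level), `diff_days` (smoothed
#'   difference quantile).
#' @export
bland_altman_quantiles <- function(y_true, y_pred,
                                   quantiles = c(5, 10, 25, 50, 75, 90, 95),
                                   window = 15L, overlap = 0.95,
                                   smooth_sigma = 2) {
  n <- length(y_true)
  if (n < window) {
    abort(sprintf("Need at least %d points for the window.", window))
  }
  if (n != length(y_pred)) abort("Vectors must have equal length.")
  ord <- order(y_true)
  yt <- y_true[ord]
  d <- (y_pred - y_true)[ord]
  stride <- max(1L, as.integer(round((1 - overlap) * window)))
  starts <- seq(1L, n - window + 1L, by = stride)
  centers <- numeric(length(starts))
  qmat <- matrix(0, length(starts), length(quantiles))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    centers[i] <- median(yt[idx])
    qmat[i, ] <- quantile(d[idx], quantiles / 100, names = FALSE)
  }
  for (j in seq_along(quantiles)) {
    qmat[, j] <- gaussian_kernel_smooth(qmat[, j], smooth_sigma)
  }
  out <- tibble::tibble(
    age_days = rep(centers, times = length(quantiles)),
    quantile = rep(quantiles, each = length(starts)),
    diff_days = as.vector(qmat)
  )
  class(out) <- c("ga_quantile_curves", class(out))
  out
}

#' Full evaluation report for a prediction table
#'
#' Computes R-squared, MAE (days), Lin's concordance correlation
#' coefficient with 95% CI and McBride class, and (when `n >= 15`) the
#' quantile Bland-Altman curves.
#'
#' @param predictions A data frame with columns `y_true` and `y_pred`
#'   (e.g. from [multiplane_predict()]).
#' @param ... Passed to [bland_altman_quantiles()].
#' @return A `ga_eval` object; see [glance.ga_eval()] and
#'   [autoplot.ga_eval()].
#' @export
evaluate_predictions <- function(predictions, ...) {
  stopifnot(is.data.frame(predictions),
            all(c("y_true", "y_pred") %in% names(predictions)))
  yt <- predictions$y_true; yp <- predictions$y_pred
  ccc <- lin_ccc(yt, yp)
  curves <- if (length(yt) >= 15L) bland_altman_quantiles(yt, yp, ...)
  structure(list(
    r2 = r2_score(yt, yp),
    mae = mae_days(yt, yp),
    ccc = ccc$ccc, ccc_ci = c(ccc$ci_low, ccc$ci_high),
    mcbride = mcbride_class(ccc$ccc),
    n = length(yt),
    curves = curves,
    predictions = tibble::as_tibble(predictions)
  ), class = "ga_eval")
}

#' @export
print.ga_eval <- function(x, ...) {
  cat(sprintf(
    "Gestational-age regression evaluation (n = %d)\n  R^2 = %.3f | MAE = %.2f days\n  Lin's CCC = %.3f [%.3f-%.3f], %s agreement\n",
    x$n, x$r2, x$mae, x$ccc, x$ccc_ci[1], x$ccc_ci[2],
    gsub("_", " ", as.character(x$mcbride))))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `ga_eval` object.
#' @param ... Unused.
#' @return A long tibble with one row per metric.
#' @export
tidy.ga_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("r2", "mae_days", "ccc", "ccc_ci_low", "ccc_ci_high"),
    value = c(x$r2, x$mae, x$ccc, x$ccc_ci[1], x$ccc_ci[2])
  )
}

#' One-row summary of an evaluation report
#'
#' @param x A `ga_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `r2`, `mae_days`, `ccc`, `ccc_ci_low`,
#'   `ccc_ci_high`, `mcbride`, `n`.
#' @export
glance.ga_eval <- function(x, ...) {
  tibble::tibble(r2 = x$r2, mae_days = x$mae, ccc = x$ccc,
                 ccc_ci_low = x$ccc_ci[1], ccc_ci_high = x$ccc_ci[2],
                 mcbride = as.character(x$mcbride), n = x$n)
}

#' Plot an evaluation report
#'
#' `which = "scatter"` draws predicted versus true age with the identity
#' line; `which = "bland_altman"` draws the prediction differences against
#' true age with the smoothed quantile curves.
#'
#' @param object A `ga_eval` object.
#' @param which `"scatter"` or `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_eval <- function(object, which = c("scatter", "bland_altman"),
                             ...) {
  which <- match.arg(which)
  preds <- object$predictions
  if (which == "scatter") {
    ggplot2::ggplot(preds, ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "True age (days)", y = "Predicted age (days)",
                    title = sprintf("R² = %.3f, MAE = %.1f d",
                                    object$r2, object$mae))
  } else {
    if (is.null(object$curves)) {
      abort("No quantile curves available (need n >= 15).")
    }
    ggplot2::ggplot(preds,
                    ggplot2::aes(x = .data$y_true,
                                 y = .data$y_pred - .data$y_true)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::geom_line(
        data = object$curves,
        ggplot2::aes(x = .data$age_days, y = .data$diff_days,
                     group = .data$quantile,
                     color = factor(.data$quantile))) +
      ggplot2::labs(x = "True age (days)",
                    y = "Prediction - truth (days)",
                    color = "Quantile (%)")
  }
}

#' Plot quantile Bland-Altman curves
#'
#' @param object A `ga_quantile_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_quantile_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$age_days, y = .data$diff_days,
                               color = factor(.data$quantile))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "True age (days)", y = "Prediction - truth (days)",
                  color = "Quantile (%)")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Did the attention heatmap localize the object?
#'
#' Checks whether the argmax of a (gaussian-weighted) heatmap falls inside
#' the truth mask dilated by `dilate_px` pixels (Euclidean).
#'
#' @param heatmap An [attention_heatmap()] (or plain matrix) at image
#'   resolution.
#' @param mask Logical truth mask of the same size.
#' @param dilate_px Dilation radius in pixels.
#' @return `TRUE` if the attention peak hits the dilated mask.
#' @export
localization_hit <- function(heatmap, mask, dilate_px = 5) {
  if (!identical(dim(heatmap), dim(mask))) {
    abort("Heatmap and mask must share dimensions.")
  }
  am <- which.max(heatmap)
  pr <- (am - 1) %% nrow(mask)
  pc <- (am - 1) %/% nrow(mask)
  mi <- which(mask)
  mr <- (mi - 1) %% nrow(mask)
  mc <- (mi - 1) %/% nrow(mask)
  any((pr - mr)^2 + (pc - mc)^2 <= dilate_px^2)
}
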
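#' Attention heatmaps
#'
#' An attention heatmap is a non-negative matrix tagged with a processing
#' stage: `"raw"` (channel-maximum of absolute activations), `"normalized"`
#' (truncated-ReLU rescaled to `[0, 1]`) or `"gaussian_weighted"` (after
#' multiplication with the centered 2D Gaussian prior).
#'
#' @param values Numeric matrix.
#' @param stage One of `"raw"`, `"normalized"`, `"gaussian_weighted"`.
#' @return An `attention_heatmap` (a matrix with a `stage` attribute).
#' @export
attention_heatmap <- function(values,
                              stage = c("raw", "normalized",
                                        "gaussian_weighted")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, stage = stage, class = c("attention_heatmap", "matrix"))
}

heatmap_stage <- function(h) attr(h, "stage") %||% "raw"

#' Channel-maximum attention heatmap
#'
#' Collapses a block of last-layer feature maps `f_k(x, y)` into a single
#' spatial map by taking, at every location, the maximum absolute
#' activation across the K channels. Large values flag locations where some
#' learned feature responds strongly, regardless of sign.
#'
#' @param features Numeric `h x w x K` array of activations.
#' @return A raw-stage [attention_heatmap()] of size `h x w`.
#' @export
channel_max_heatmap <- function(features) {
  d <- dim(features)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    abort("`features` must be an h x w x K array with K >= 1.")
  }
  if (!all(is.finite(features))) abort("`features` must be finite.")
  m <- matrix(abs(features), d[1] * d[2], d[3])
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  attention_heatmap(matrix(mx, d[1], d[2]), stage = "raw")
}

#' Truncated-ReLU normalization of a heatmap to [0, 1]
#'
#' Values are clamped below at 0 and above at a ceiling — the `q`-th
#' percentile of the map — then divided by that ceiling. The default
#' `q = 100` divides by the maximum; smaller `q` gives robustness against
#' single-pixel spikes. An all-zero map passes through unchanged (early in
#' training feature maps can be degenerate).
#'
#' @param h A raw-stage [attention_heatmap()] (any matrix is accepted).
#' @param q Percentile (0 < q <= 100) defining the clamp ceiling.
#' @return A normalized-stage [attention_heatmap()] with values in
#'   `[0, 1]`.
#' @export
normalize_heatmap <- function(h, q = 100) {
  assert_number(q, "q", lower = 1e-8, upper = 100)
  x <- unclass(h)
  attributes(x) <- list(dim = dim(h))
  x[x < 0] <- 0
  ceiling_v <- if (q >= 100) max(x) else unname(quantile(x, q / 100))
  if (ceiling_v <= 0) {
    return(attention_heatmap(x * 0, stage = "normalized"))
  }
  x[x > ceiling_v] <- ceiling_v
  attention_heatmap(x / ceiling_v, stage = "normalized")
}

# Row-interpolation matrix for separable bilinear resampling from
# `src` to `tgt` samples, half-pixel centers (corner alignment disabled).
bilinear_matrix <- function(tgt, src) {
  M <- matrix(0, tgt, src)
  pos <- ((seq_len(tgt) - 0.5) * src / tgt) - 0.5
  pos <- pmin(pmax(pos, 0), src - 1)
  lo <- pmin(floor(pos), src - 1)
  hi <- pmin(lo + 1, src - 1)
  w <- pos - lo
  for (i in seq_len(tgt)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - w[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + w[i]
  }
  M
}

#' Bilinearly upsample a heatmap to the input-image resolution
#'
#' Separable bilinear interpolation with half-pixel sample centers. Outputs
#' are convex combinations of inputs, so values never leave the source
#' range; the processing stage is preserved.
#'
#' @param h An [attention_heatmap()].
#' @param target Integer pair `(height, width)`, each at least as large as
#'   the source dimension.
#' @return The upsampled [attention_heatmap()].
#' @export
upsample_heatmap <- function(h, target) {
  d <- dim(h)
  if (length(target) != 2L || any(target < d)) {
    abort("`target` must be (height, width) with both >= the source size.")
  }
  Rw <- bilinear_matrix(target[1], d[1])
  Cw <- bilinear_matrix(target[2], d[2])
  attention_heatmap(Rw %*% unclass(h) %*% t(Cw), stage = heatmap_stage(h))
}

#' 2D Gaussian weight encoding the centered-brain prior
#'
#' A unit-peak Gaussian `exp(-((r - cr)^2 + (c - cc)^2) / (2 sigma^2))`
#' over a pixel grid, 0-based coordinates with the origin at the top-left.
#' Defaults place the center at the image center with
#' `sigma = 0.25 * side`, wide enough to cover a centered fetal brain while
#' decaying strongly at the borders.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param center `(row, col)` of the peak, 0-based; default image center.
#' @param sigma Standard deviation in pixels (> 0).
#' @return A `gaussian_weight` matrix with `center` and `sigma` attributes.
#' @export
gaussian_weight <- function(nrow, ncol, center = NULL, sigma = 0.25 * nrow) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (is.null(center)) center <- c((nrow - 1) / 2, (ncol - 1) / 2)
  r <- matrix(rep(seq_len(nrow) - 1, ncol), nrow, ncol)
  cc <- matrix(rep(seq_len(ncol) - 1, each = nrow), nrow, ncol)
  g <- exp(-((r - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
  structure(g, center = center, sigma = sigma,
            class = c("gaussian_weight", "matrix"))
}

#' Re-weight a normalized heatmap with the centered Gaussian prior
#'
#' Element-wise product of the heatmap with the unit-peak Gaussian. No
#' value ever increases, and the value at the Gaussian center is unchanged.
#'
#' @param h A normalized-stage [attention_heatmap()].
#' @param g A [gaussian_weight()] on the same grid.
#' @return A gaussian_weighted-stage [attention_heatmap()].
#' @export
gaussian_reweight <- function(h, g) {
  if (!identical(dim(h), dim(g))) {
    abort("Heatmap and Gaussian weight must share the same grid.")
  }
  if (heatmap_stage(h) == "raw") {
    abort("Normalize the heatmap before Gaussian re-weighting.")
  }
  attention_heatmap(unclass(h) * unclass(g), stage = "gaussian_weighted")
}

#' Mask an input slab with an attention heatmap
#'
#' Per-slice element-wise product of the image with the Gaussian-weighted
#' heatmap: high-attention regions are preserved, background is suppressed.
#' The masked slab is the local branch's input.
#'
#' @param slab A [plane_slab()].
#' @param h An [attention_heatmap()] matching the slab's spatial
#'   dimensions.
#' @return The masked [plane_slab()].
#' @export
apply_mask <- function(slab, h) {
  stopifnot(inherits(slab, "plane_slab"))
  d <- dim(slab$pixels)
  if (!identical(dim(h), d[1:2])) {
    abort("Heatmap dimensions must match the slab's spatial dimensions.")
  }
  slab$pixels <- slab$pixels * array(unclass(h), dim = d)
  slab
}
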
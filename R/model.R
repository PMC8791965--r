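#' Backbone specification
#'
#' @param family `"tiny"` (a small three-stage convolutional net for
#'   desk-scale experiments), `"resnet18"` or `"resnet50"` (residual
#'   networks with the standard block counts and widths; final feature
#'   depth K = 512 and 2048 respectively).
#' @param in_channels Number of input slices fed as channels: 1, 3 or 5.
#'   The first convolution is parameterized to accept exactly this count.
#' @param pretrained `FALSE` (random init) or a path to an RDS file holding
#'   a flat parameter list as produced by [save_checkpoint()]. When the
#'   stored first-layer kernel has 3 input channels and `in_channels`
#'   differs, the kernel is adapted with [adapt_first_conv()].
#' @param input_size Expected square input side in pixels (>= 32 for tiny,
#'   >= 64 otherwise).
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(family = c("tiny", "resnet18", "resnet50"),
                          in_channels = 3L, pretrained = FALSE,
                          input_size = 64L) {
  family <- match.arg(family)
  if (!in_channels %in% c(1L, 3L, 5L)) {
    abort("`in_channels` must be 1, 3 or 5.")
  }
  min_size <- if (family == "tiny") 32L else 64L
  if (input_size < min_size) {
    abort(sprintf("`input_size` must be >= %d for family '%s'.",
                  min_size, family))
  }
  if (isTRUE(pretrained)) {
    abort(paste("`pretrained = TRUE` requires a weights file: pass the path",
                "to a parameter RDS instead."))
  }
  structure(list(family = family, in_channels = as.integer(in_channels),
                 pretrained = pretrained, input_size = as.integer(input_size)),
            class = "backbone_spec")
}

basic_block <- function(cin, cout, stride) {
  body <- list(layer_conv(3, 3, cin, cout, stride, 1), layer_relu(),
               layer_conv(3, 3, cout, cout, 1, 1))
  proj <- if (stride != 1 || cin != cout) {
    layer_conv(1, 1, cin, cout, stride, 0)
  }
  layer_resblock(body, proj)
}

bottleneck_block <- function(cin, mid, cout, stride) {
  body <- list(layer_conv(1, 1, cin, mid, 1, 0), layer_relu(),
               layer_conv(3, 3, mid, mid, stride, 1), layer_relu(),
               layer_conv(1, 1, mid, cout, 1, 0))
  proj <- if (stride != 1 || cin != cout) {
    layer_conv(1, 1, cin, cout, stride, 0)
  }
  layer_resblock(body, proj)
}

# Feature extractor + regression head for one branch. `K` is the channel
# count of the last convolutional layer, the source of attention heatmaps.
build_backbone <- function(spec, pool = "max") {
  C <- spec$in_channels
  if (spec$family == "tiny") {
    features <- list(
      layer_conv(3, 3, C, 8, 2, 1), layer_relu(), layer_maxpool(2),
      layer_conv(3, 3, 8, 16, 1, 1), layer_relu(), layer_maxpool(2),
      layer_conv(3, 3, 16, 32, 1, 1), layer_relu()
    )
    K <- 32L
  } else {
    stem <- list(layer_conv(7, 7, C, 64, 2, 3), layer_relu(),
                 layer_maxpool(3, 2))
    if (spec$family == "resnet18") {
      plan <- list(c(64, 2, 1), c(128, 2, 2), c(256, 2, 2), c(512, 2, 2))
      cin <- 64L
      blocks <- list()
      for (st in plan) {
        for (b in seq_len(st[2])) {
          stride <- if (b == 1) st[3] else 1
          blocks <- c(blocks, list(basic_block(cin, st[1], stride)))
          cin <- st[1]
        }
      }
      K <- 512L
    } else {
      plan <- list(c(64, 256, 3, 1), c(128, 512, 4, 2),
                   c(256, 1024, 6, 2), c(512, 2048, 3, 2))
      cin <- 64L
      blocks <- list()
      for (st in plan) {
        for (b in seq_len(st[3])) {
          stride <- if (b == 1) st[4] else 1
          blocks <- c(blocks, list(bottleneck_block(cin, st[1], st[2],
                                                    stride)))
          cin <- st[2]
        }
      }
      K <- 2048L
    }
    features <- c(stem, blocks)
  }
  list(features = features,
       head = list(layer_pool_global(pool), layer_fc(K, 1L)),
       K = K)
}

#' Adapt a 3-channel first-layer kernel to a different slice count
#'
#' Averages the RGB kernels, replicates the average across the requested
#' channel count, and rescales by `3 / in_channels` so that the layer's
#' response magnitude to replicated inputs is preserved.
#'
#' @param w A `kh x kw x 3 x cout` kernel array.
#' @param in_channels Target channel count.
#' @return A `kh x kw x in_channels x cout` kernel array.
#' @export
adapt_first_conv <- function(w, in_channels) {
  d <- dim(w)
  if (length(d) != 4L || d[3] != 3L) {
    abort("`w` must be a kh x kw x 3 x cout kernel.")
  }
  avg <- apply(w, c(1, 2, 4), mean)  # kh x kw x cout
  out <- array(0, dim = c(d[1], d[2], in_channels, d[4]))
  for (c in seq_len(in_channels)) out[, , c, ] <- avg
  out * (3 / in_channels)
}

default_attention <- function(input_size) {
  list(sigma = 0.25 * input_size, center = NULL, q = 100)
}

#' Build the dual-branch age-regression model
#'
#' The global branch regresses age from the whole input; the local branch
#' regresses age from the same input masked by the attention heatmap
#' extracted from the global branch's last convolutional layer
#' (channel-max, upsample, truncated-ReLU normalization, Gaussian
#' re-weighting). The fused prediction is the arithmetic mean of both
#' branches. Branches never share weights.
#'
#' @param spec A [backbone_spec()].
#' @param mode `"dual"` or `"global_only"` (the basic-network comparator
#'   with no attention masking and `y_pred = y_global`).
#' @param seed Seed for weight initialization.
#' @param pool Global pooling type of the regression heads, `"max"`
#'   (default) or `"avg"`.
#' @param attention List overriding `sigma`, `center` (0-based pixel
#'   coordinates) or `q` (truncation percentile) of the attention pipeline.
#' @param gradient_through_mask If `TRUE` (default), the local-branch loss
#'   backpropagates through the attention pipeline into the global
#'   backbone, making the framework end-to-end trainable; `FALSE`
#'   stop-gradients the mask for ablation.
#' @return A `dual_branch_model`.
#' @export
build_model <- function(spec, mode = c("dual", "global_only"), seed = 1L,
                        pool = "max", attention = list(),
                        gradient_through_mask = TRUE) {
  stopifnot(inherits(spec, "backbone_spec"))
  mode <- match.arg(mode)
  att <- utils::modifyList(default_attention(spec$input_size), attention)
  model <- with_seed(seed, {
    g <- build_backbone(spec, pool)
    l <- if (mode == "dual") build_backbone(spec, pool)
    list(spec = spec, mode = mode, global = g, local = l, attention = att,
         gradient_through_mask = isTRUE(gradient_through_mask))
  })
  class(model) <- "dual_branch_model"
  if (is.character(spec$pretrained)) {
    model <- load_pretrained(model, spec$pretrained)
  }
  model
}

load_pretrained <- function(model, path) {
  if (!file.exists(path)) abort(sprintf("Weights file '%s' not found.", path))
  params <- readRDS(path)
  first <- "g.L1.w"
  if (!is.null(params[[first]])) {
    d <- dim(params[[first]])
    if (d[3] == 3L && model$spec$in_channels != 3L) {
      params[[first]] <- adapt_first_conv(params[[first]],
                                          model$spec$in_channels)
    }
  }
  set_model_params(model, params, missing_ok = TRUE)
}

model_params <- function(model) {
  p <- c(collect_params(model$global$features, "g.L"),
         collect_params(model$global$head, "gh.L"))
  if (!is.null(model$local)) {
    p <- c(p, collect_params(model$local$features, "l.L"),
           collect_params(model$local$head, "lh.L"))
  }
  p
}

set_model_params <- function(model, params, missing_ok = FALSE) {
  pick <- function(prefix, layers) {
    sub <- params[startsWith(names(params), prefix)]
    names(sub) <- substring(names(sub), nchar(prefix) + 1L)
    names(sub) <- paste0("L", names(sub))
    have <- collect_params(layers, "L")
    if (!missing_ok && !setequal(names(sub), names(have))) {
      abort("Parameter names do not match the model structure.")
    }
    set_params(layers, utils::modifyList(have, sub), "L")
  }
  model$global$features <- pick("g.L", model$global$features)
  model$global$head <- pick("gh.L", model$global$head)
  if (!is.null(model$local)) {
    model$local$features <- pick("l.L", model$local$features)
    model$local$head <- pick("lh.L", model$local$head)
  }
  model
}

# ---- attention pipeline with gradients -------------------------------------

# feats: (hf, wf, K, N); x: (H, W, C, N). Returns the masked batch, the
# per-sample gaussian-weighted heatmaps, and caches for the backward pass.
attention_forward <- function(feats, x, att) {
  fd <- dim(feats); xd <- dim(x)
  hf <- fd[1]; wf <- fd[2]; K <- fd[3]; N <- fd[4]
  H <- xd[1]; W <- xd[2]
  Rw <- bilinear_matrix(H, hf)
  Cw <- bilinear_matrix(W, wf)
  center <- att$center %||% c((H - 1) / 2, (W - 1) / 2)
  G <- unclass(gaussian_weight(H, W, center = center, sigma = att$sigma))
  masked <- array(0, dim = xd)
  heatmaps <- vector("list", N)
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    f <- feats[, , , n, drop = FALSE]
    dim(f) <- fd[1:3]
    m <- matrix(f, hf * wf, K)
    am <- max.col(abs(m), ties.method = "first")
    sel <- cbind(seq_len(hf * wf), am)
    raw <- matrix(abs(m[sel]), hf, wf)
    sgn <- sign(m[sel])
    U <- Rw %*% raw %*% t(Cw)
    cmax <- max(U)
    if (cmax > 0) {
      if (att$q >= 100) {
        Un <- U / cmax
        ceiling_v <- cmax
      } else {
        ceiling_v <- unname(quantile(U, att$q / 100))
        Un <- pmin(U, ceiling_v) / ceiling_v
      }
    } else {
      Un <- U * 0
      ceiling_v <- 0
    }
    Hgw <- Un * G
    masked[, , , n] <- array(x[, , , n], dim = xd[1:3]) *
      array(Hgw, dim = xd[1:3])
    heatmaps[[n]] <- attention_heatmap(Hgw, stage = "gaussian_weighted")
    cache[[n]] <- list(am = am, sgn = sgn, U = U, Un = Un,
                       ceiling_v = ceiling_v,
                       argmaxU = which.max(U))
  }
  list(masked = masked, heatmaps = heatmaps,
       shared = list(Rw = Rw, Cw = Cw, G = G, fd = fd, xd = xd),
       cache = cache)
}

# gmasked: gradient of the loss wrt the masked batch. Returns the gradient
# wrt the global-branch feature block.
attention_backward <- function(afwd, x, gmasked, q = 100) {
  sh <- afwd$shared
  fd <- sh$fd; xd <- sh$xd
  gfeats <- array(0, dim = fd)
  for (n in seq_len(fd[4])) {
    ca <- afwd$cache[[n]]
    # d loss / d Hgw, summing the per-slice products
    gH <- matrix(0, xd[1], xd[2])
    for (s in seq_len(xd[3])) {
      gH <- gH + gmasked[, , s, n] * x[, , s, n]
    }
    gUn <- gH * sh$G
    if (ca$ceiling_v > 0) {
      if (q >= 100) {
        # Un = U / max(U): quotient rule routes a correction to the argmax
        gU <- gUn / ca$ceiling_v
        gU[ca$argmaxU] <- gU[ca$argmaxU] -
          sum(gUn * ca$U) / ca$ceiling_v^2
      } else {
        # percentile ceiling treated as a constant (stop-gradient)
        gU <- gUn / ca$ceiling_v
        gU[ca$U > ca$ceiling_v] <- 0
      }
    } else {
      gU <- gUn * 0
    }
    graw <- t(sh$Rw) %*% gU %*% sh$Cw
    # scatter into the winning channel with the activation's sign
    gm <- matrix(0, fd[1] * fd[2], fd[3])
    gm[cbind(seq_len(fd[1] * fd[2]), ca$am)] <- as.vector(graw) * ca$sgn
    gfeats[, , , n] <- array(gm, dim = fd[1:3])
  }
  gfeats
}

# ---- dual-branch forward / backward ----------------------------------------

# x: (H, W, C, N). Returns branch outputs as length-N vectors plus all
# caches needed for dual_backward().
dual_forward <- function(model, x) {
  gf <- net_forward(model$global$features, x)
  gh <- net_forward(model$global$head, gf$out)
  y_global <- as.vector(gh$out)
  if (model$mode == "global_only") {
    return(list(y_global = y_global, y_local = NULL, y_pred = y_global,
                heatmaps = NULL,
                cache = list(gf = gf, gh = gh)))
  }
  att <- attention_forward(gf$out, x, model$attention)
  lf <- net_forward(model$local$features, att$masked)
  lh <- net_forward(model$local$head, lf$out)
  y_local <- as.vector(lh$out)
  list(y_global = y_global, y_local = y_local,
       y_pred = (y_global + y_local) / 2,
       heatmaps = att$heatmaps,
       cache = list(gf = gf, gh = gh, att = att, lf = lf, lh = lh, x = x))
}

# gy_global / gy_local: length-N gradients of the loss wrt each branch
# output. Returns a flat named gradient list aligned with model_params().
dual_backward <- function(model, fwd, gy_global, gy_local = NULL) {
  ca <- fwd$cache
  N <- length(fwd$y_global)
  gh_out <- matrix(gy_global, 1L, N)
  bh <- net_backward(model$global$head, ca$gh$caches, gh_out)
  gfeats <- bh$gx
  grads <- list()
  if (model$mode == "dual" && !is.null(gy_local)) {
    lh_out <- matrix(gy_local, 1L, N)
    blh <- net_backward(model$local$head, ca$lh$caches, lh_out)
    blf <- net_backward(model$local$features, ca$lf$caches, blh$gx)
    grads <- c(grads,
               collect_grads(model$local$features, blf$grads, "l.L"),
               collect_grads(model$local$head, blh$grads, "lh.L"))
    if (model$gradient_through_mask) {
      gfeats <- gfeats + attention_backward(ca$att, ca$x, blf$gx,
                                            q = model$attention$q)
    }
  }
  bgf <- net_backward(model$global$features, ca$gf$caches, gfeats)
  c(collect_grads(model$global$features, bgf$grads, "g.L"),
    collect_grads(model$global$head, bh$grads, "gh.L"),
    grads)
}

slab_batch <- function(slabs) {
  d <- dim(slabs[[1]]$pixels)
  x <- array(0, dim = c(d, length(slabs)))
  for (i in seq_along(slabs)) x[, , , i] <- slabs[[i]]$pixels
  x
}

#' Run the dual-branch model on one slab
#'
#' @param model A `dual_branch_model`.
#' @param slab A preprocessed [plane_slab()] whose slice count matches the
#'   model's `in_channels`.
#' @param y_true Optional true age in days, carried into the prediction
#'   table.
#' @return A list with `prediction` (a one-row tibble: `subject_id`,
#'   `plane`, `y_global`, `y_local`, `y_pred`, `y_true`) and `heatmap` (the
#'   gaussian-weighted [attention_heatmap()], `NULL` in global-only mode).
#' @export
forward_dual <- function(model, slab, y_true = NA_real_) {
  stopifnot(inherits(model, "dual_branch_model"), inherits(slab, "plane_slab"))
  if (slab$n_slices != model$spec$in_channels) {
    abort(sprintf("Slab has %d slices but the model expects %d channels.",
                  slab$n_slices, model$spec$in_channels))
  }
  fwd <- dual_forward(model, slab_batch(list(slab)))
  pred <- tibble::tibble(
    subject_id = slab$subject_id, plane = slab$plane,
    y_global = fwd$y_global[1],
    y_local = if (is.null(fwd$y_local)) NA_real_ else fwd$y_local[1],
    y_pred = fwd$y_pred[1], y_true = y_true
  )
  list(prediction = pred,
       heatmap = if (is.null(fwd$heatmaps)) NULL else fwd$heatmaps[[1]])
}

#' Multi-plane model: one dual-branch network per anatomical plane
#'
#' @param spec A [backbone_spec()].
#' @param planes Planes to build networks for.
#' @param mode,pool,attention,gradient_through_mask Passed to
#'   [build_model()].
#' @param seed Seed; per-plane initialization seeds are derived from it.
#' @param share_weights If `TRUE`, a single network serves all planes (the
#'   minimal weight-sharing reading); default `FALSE` trains independent
#'   networks under one summed loss.
#' @return A `ga_model` holding the per-plane networks.
#' @export
build_multiplane_model <- function(spec, planes = phantom_planes,
                                   mode = "dual", seed = 1L, pool = "max",
                                   attention = list(),
                                   gradient_through_mask = TRUE,
                                   share_weights = FALSE) {
  seeds <- derive_seeds(seed, length(planes))
  nets <- if (share_weights) {
    m <- build_model(spec, mode, seed = seeds[1], pool = pool,
                     attention = attention,
                     gradient_through_mask = gradient_through_mask)
    setNames(rep(list(m), length(planes)), planes)
  } else {
    setNames(purrr::map(seq_along(planes), function(i) {
      build_model(spec, mode, seed = seeds[i], pool = pool,
                  attention = attention,
                  gradient_through_mask = gradient_through_mask)
    }), planes)
  }
  structure(list(planes = nets, spec = spec, mode = mode,
                 share_weights = isTRUE(share_weights)),
            class = "ga_model")
}

#' Predict age for subjects from all available planes
#'
#' Runs every plane's dual-branch network on the prepared slabs and
#' averages the per-plane fused predictions (unweighted) into the final
#' estimate.
#'
#' @param model A `ga_model` (or a single `dual_branch_model`, treated as
#'   one plane).
#' @param data A prepared dataset tibble from [prepare_dataset()] with
#'   `slab_<plane>` list-columns for at least one of the model's planes.
#' @return A tibble: one row per subject with `y_global_<plane>`,
#'   `y_local_<plane>`, `y_pred_<plane>` columns, the fused `y_pred`, and
#'   `y_true` (the manifest's `age_days`).
#' @export
multiplane_predict <- function(model, data) {
  if (inherits(model, "dual_branch_model")) {
    model <- structure(list(planes = list(axial = model)), class = "ga_model")
  }
  stopifnot(inherits(model, "ga_model"), is.data.frame(data))
  avail <- intersect(names(model$planes),
                     sub("^slab_", "", grep("^slab_", names(data),
                                            value = TRUE)))
  if (length(avail) == 0L) {
    abort("No plane of the model has a matching slab column in `data`.")
  }
  out <- tibble::tibble(subject_id = data$subject_id,
                        y_true = data$age_days %||% NA_real_)
  fused <- matrix(0, nrow(data), length(avail))
  for (j in seq_along(avail)) {
    pl <- avail[j]
    x <- slab_batch(data[[paste0("slab_", pl)]])
    fwd <- dual_forward(model$planes[[pl]], x)
    out[[paste0("y_global_", pl)]] <- fwd$y_global
    out[[paste0("y_local_", pl)]] <-
      if (is.null(fwd$y_local)) NA_real_ else fwd$y_local
    out[[paste0("y_pred_", pl)]] <- fwd$y_pred
    fused[, j] <- fwd$y_pred
  }
  out$y_pred <- rowMeans(fused)
  out
}

#' @export
print.dual_branch_model <- function(x, ...) {
  cat(sprintf("<dual_branch_model %s, %d-slice, %s, K=%d>\n",
              x$spec$family, x$spec$in_channels, x$mode, x$global$K))
  invisible(x)
}

#' @export
print.ga_model <- function(x, ...) {
  cat(sprintf("<ga_model: %s over planes %s>\n", x$mode,
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}
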
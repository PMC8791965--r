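# Minimal static-graph neural network layers with manual backpropagation.
# Batches are (H, W, C, N) arrays; fully connected activations are
# (features, N) matrices. Every layer implements forward (returning an
# output and a cache) and backward (returning input gradients and, for
# parameterized layers, parameter gradients).

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  list(type = "conv",
       w = he_init(kh, kw, cin, cout),
       b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_relu <- function() list(type = "relu")

layer_maxpool <- function(size = 2L, stride = size) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride))
}

layer_pool_global <- function(pool = c("max", "avg")) {
  list(type = "pool_global", pool = match.arg(pool))
}

layer_fc <- function(cin, cout) {
  list(type = "fc",
       w = matrix(rnorm(cout * cin, 0, sqrt(1 / cin)), cout, cin),
       b = numeric(cout))
}

# Residual block: out = relu(body(x) + shortcut(x)); shortcut is identity
# or a 1x1 projection conv when shape changes.
layer_resblock <- function(body, proj = NULL) {
  list(type = "resblock", body = body, proj = proj)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      out <- conv2d_fwd_cpp(x, layer$w, layer$b, layer$stride, layer$pad)
      list(out = out, cache = list(x = x))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    maxpool = {
      r <- maxpool_fwd_cpp(x, layer$size, layer$stride)
      list(out = r$out, cache = list(idx = r$idx, H = dim(x)[1],
                                     W = dim(x)[2]))
    },
    pool_global = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2], d[3] * d[4])
      if (layer$pool == "max") {
        am <- max.col(t(m), ties.method = "first")
        out <- matrix(m[cbind(am, seq_along(am))], d[3], d[4])
        list(out = out, cache = list(d = d, am = am))
      } else {
        list(out = matrix(colMeans(m), d[3], d[4]), cache = list(d = d))
      }
    },
    fc = {
      list(out = layer$w %*% x + layer$b, cache = list(x = x))
    },
    resblock = {
      body_caches <- vector("list", length(layer$body))
      h <- x
      for (i in seq_along(layer$body)) {
        r <- layer_forward(layer$body[[i]], h)
        h <- r$out; body_caches[[i]] <- r$cache
      }
      if (is.null(layer$proj)) {
        s <- x; proj_cache <- NULL
      } else {
        r <- layer_forward(layer$proj, x)
        s <- r$out; proj_cache <- r$cache
      }
      pre <- h + s
      mask <- pre > 0
      list(out = pre * mask,
           cache = list(body = body_caches, proj = proj_cache, mask = mask))
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type))
  )
}

# Returns list(gx = gradient wrt input, grads = list(w = ..., b = ...) for
# parameterized layers, NULL otherwise).
layer_backward <- function(layer, cache, gout) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd_cpp(cache$x, layer$w, gout, layer$stride, layer$pad)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    relu = list(gx = gout * cache$mask, grads = NULL),
    maxpool = list(gx = maxpool_bwd_cpp(gout, cache$idx, cache$H, cache$W),
                   grads = NULL),
    pool_global = {
      d <- cache$d
      gx <- array(0, dim = d)
      gm <- matrix(gx, d[1] * d[2], d[3] * d[4])
      if (layer$pool == "max") {
        gm[cbind(cache$am, seq_along(cache$am))] <- as.vector(gout)
      } else {
        gm <- matrix(rep(as.vector(gout), each = d[1] * d[2]) /
                       (d[1] * d[2]), d[1] * d[2], d[3] * d[4])
      }
      list(gx = array(gm, dim = d), grads = NULL)
    },
    fc = {
      list(gx = t(layer$w) %*% gout,
           grads = list(w = gout %*% t(cache$x), b = rowSums(gout)))
    },
    resblock = {
      gpre <- gout * cache$mask
      grads <- list(body = vector("list", length(layer$body)), proj = NULL)
      g <- gpre
      for (i in rev(seq_along(layer$body))) {
        r <- layer_backward(layer$body[[i]], cache$body[[i]], g)
        grads$body[i] <- list(r$grads)
        g <- r$gx
      }
      if (is.null(layer$proj)) {
        gx <- g + gpre
      } else {
        r <- layer_backward(layer$proj, cache$proj, gpre)
        grads$proj <- r$grads
        gx <- g + r$gx
      }
      list(gx = gx, grads = grads)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type))
  )
}

net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out; caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, caches, gout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gout)
    grads[i] <- list(r$grads)  # keep NULL slots for parameter-free layers
    gout <- r$gx
  }
  list(gx = gout, grads = grads)
}

# Flatten the parameters of a layer list into a named list of arrays, and
# write such a flat list back. Names encode the path into the structure.
collect_params <- function(layers, prefix = "L") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- sprintf("%s%d", prefix, i)
    if (l$type %in% c("conv", "fc")) {
      out[[paste0(nm, ".w")]] <- l$w
      out[[paste0(nm, ".b")]] <- l$b
    } else if (l$type == "resblock") {
      out <- c(out, collect_params(l$body, paste0(nm, ".body.")))
      if (!is.null(l$proj)) {
        out <- c(out, collect_params(list(l$proj), paste0(nm, ".proj.")))
      }
    }
  }
  out
}

collect_grads <- function(layers, grads, prefix = "L") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]
    nm <- sprintf("%s%d", prefix, i)
    if (l$type %in% c("conv", "fc")) {
      out[[paste0(nm, ".w")]] <- g$w
      out[[paste0(nm, ".b")]] <- g$b
    } else if (l$type == "resblock") {
      out <- c(out, collect_grads(l$body, g$body, paste0(nm, ".body.")))
      if (!is.null(l$proj)) {
        out <- c(out, collect_grads(list(l$proj), list(g$proj),
                                    paste0(nm, ".proj.")))
      }
    }
  }
  out
}

set_params <- function(layers, params, prefix = "L") {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- sprintf("%s%d", prefix, i)
    if (l$type %in% c("conv", "fc")) {
      layers[[i]]$w <- params[[paste0(nm, ".w")]]
      layers[[i]]$b <- params[[paste0(nm, ".b")]]
    } else if (l$type == "resblock") {
      layers[[i]]$body <- set_params(l$body, params, paste0(nm, ".body."))
      if (!is.null(l$proj)) {
        layers[[i]]$proj <- set_params(list(l$proj), params,
                                       paste0(nm, ".proj."))[[1]]
      }
    }
  }
  layers
}
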
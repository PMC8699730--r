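# Minimal CNN engine: layer specs, initialization, forward/backward passes and
# Adam. Convolutions run through compiled im2col + GEMM kernels (src/) with a
# matching col2im input-gradient, so arbitrary stride/padding are exact.
# Tensors are H x W x C x N arrays between image layers and D x N matrices
# after global average pooling. Gradients are verified against finite
# differences in the test suite.

nn_conv <- function(filters, kernel = 3L, stride = 1L, pad = (kernel - 1L) %/% 2L,
                    bias = TRUE) {
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad), bias = bias)
}
nn_relu <- function() list(type = "relu")
nn_avgpool <- function(size = 2L) list(type = "avgpool", size = as.integer(size))
nn_maxpool <- function() list(type = "maxpool")
nn_batchnorm <- function() list(type = "batchnorm")
nn_gap <- function() list(type = "gap")
nn_linear <- function(out) list(type = "linear", out = as.integer(out))
nn_residual <- function(main, shortcut = NULL) {
  list(type = "residual", main = main, shortcut = shortcut)
}

layer_init <- function(spec, in_shape) {
  switch(spec$type,
    conv = {
      stopifnot(length(in_shape) == 3)
      k <- spec$kernel; c_in <- in_shape[3]
      ho <- (in_shape[1] + 2L * spec$pad - k) %/% spec$stride + 1L
      wo <- (in_shape[2] + 2L * spec$pad - k) %/% spec$stride + 1L
      stopifnot(ho >= 1, wo >= 1)
      fan_in <- k * k * c_in
      params <- list(W = matrix(rnorm(fan_in * spec$filters) * sqrt(2 / fan_in),
                                fan_in, spec$filters))
      if (spec$bias) params$b <- rep(0, spec$filters)
      list(layer = c(spec, list(in_shape = in_shape, params = params)),
           out_shape = c(ho, wo, spec$filters))
    },
    relu = list(layer = spec, out_shape = in_shape),
    avgpool = {
      stopifnot(in_shape[1] %% spec$size == 0, in_shape[2] %% spec$size == 0)
      list(layer = c(spec, list(in_shape = in_shape)),
           out_shape = c(in_shape[1:2] %/% spec$size, in_shape[3]))
    },
    maxpool = {
      stopifnot(in_shape[1] %% 2 == 0, in_shape[2] %% 2 == 0)
      list(layer = c(spec, list(in_shape = in_shape)),
           out_shape = c(in_shape[1:2] %/% 2L, in_shape[3]))
    },
    batchnorm = {
      ch <- in_shape[length(in_shape)]
      list(layer = c(spec, list(params = list(gamma = rep(1, ch), beta = rep(0, ch)))),
           out_shape = in_shape)
    },
    gap = list(layer = c(spec, list(in_shape = in_shape)), out_shape = in_shape[3]),
    linear = {
      stopifnot(length(in_shape) == 1)
      params <- list(W = matrix(rnorm(spec$out * in_shape) * sqrt(2 / in_shape),
                                spec$out, in_shape),
                     b = rep(0, spec$out))
      list(layer = c(spec, list(params = params)), out_shape = spec$out)
    },
    residual = {
      main <- seq_init(spec$main, in_shape)
      shortcut <- if (!is.null(spec$shortcut)) seq_init(spec$shortcut, in_shape)
      out_shape <- main$out_shape
      if (!is.null(shortcut)) stopifnot(identical(shortcut$out_shape, out_shape))
      list(layer = list(type = "residual", main = main$layers,
                        shortcut = shortcut$layers),
           out_shape = out_shape)
    },
    abort(sprintf("unknown layer type '%s'", spec$type))
  )
}

seq_init <- function(specs, in_shape) {
  layers <- vector("list", length(specs))
  shape <- in_shape
  for (i in seq_along(specs)) {
    ini <- layer_init(specs[[i]], shape)
    layers[[i]] <- ini$layer
    shape <- ini$out_shape
  }
  list(layers = layers, out_shape = shape)
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  f <- conv_fwd_cpp(x, as.integer(d), layer$params$W,
                    if (is.null(layer$params$b)) numeric(0) else layer$params$b,
                    layer$kernel, layer$stride, layer$pad)
  list(out = f$out, cache = list(patches = f$patches, d = as.integer(d)))
}

conv_backward <- function(layer, cache, dy, need_dx = TRUE) {
  b <- conv_bwd_cpp(dy, cache$patches, layer$params$W, cache$d,
                    layer$kernel, layer$stride, layer$pad,
                    !is.null(layer$params$b), need_dx)
  grads <- list(W = b$dW)
  if (!is.null(layer$params$b)) grads$b <- as.numeric(b$db)
  list(dx = b$dx, grads = grads)
}

avgpool_forward <- function(layer, x) {
  d <- dim(x)
  list(out = avgpool_fwd_cpp(x, as.integer(d), layer$size),
       cache = list(d = as.integer(d)))
}

avgpool_backward <- function(layer, cache, dy) {
  list(dx = avgpool_bwd_cpp(dy, cache$d, layer$size), grads = NULL)
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  ii <- list(seq(1, d[1], 2), seq(2, d[1], 2))
  jj <- list(seq(1, d[2], 2), seq(2, d[2], 2))
  out <- x[ii[[1]], jj[[1]], , , drop = FALSE]
  sel <- array(1L, dim(out))
  slot <- 1L
  for (a in 1:2) for (b in 1:2) {
    if (a == 1 && b == 1) { slot <- slot + 1L; next }
    cand <- x[ii[[a]], jj[[b]], , , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    sel[upd] <- slot
    slot <- slot + 1L
  }
  list(out = out, cache = list(sel = sel, d = d))
}

maxpool_backward <- function(layer, cache, dy) {
  d <- cache$d
  ii <- list(seq(1, d[1], 2), seq(2, d[1], 2))
  jj <- list(seq(1, d[2], 2), seq(2, d[2], 2))
  dx <- array(0, d)
  slot <- 1L
  for (a in 1:2) for (b in 1:2) {
    dx[ii[[a]], jj[[b]], , ] <- dy * (cache$sel == slot)
    slot <- slot + 1L
  }
  list(dx = dx, grads = NULL)
}

bn_eps <- 1e-5

batchnorm_forward <- function(layer, x) {
  d <- dim(x)
  ch <- d[length(d)]
  if (length(d) == 4) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
    ch <- d[3]
  } else {
    xm <- t(x)  # (D x N) -> rows are samples
  }
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  ivar <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  out <- if (length(d) == 4) {
    aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    t(y)
  }
  list(out = out, cache = list(xhat = xhat, ivar = ivar, d = d))
}

batchnorm_backward <- function(layer, cache, dy) {
  d <- cache$d
  dym <- if (length(d) == 4) matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3]) else t(dy)
  xhat <- cache$xhat
  m <- nrow(dym)
  grads <- list(gamma = colSums(dym * xhat), beta = colSums(dym))
  dxhat <- sweep(dym, 2, layer$params$gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
  dxm <- sweep(t1 - t2, 2, cache$ivar, `*`)
  dx <- if (length(d) == 4) {
    aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    t(dxm)
  }
  list(dx = dx, grads = grads)
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = conv_forward(layer, x),
    relu = list(out = relu_fwd_cpp(x), cache = list(x = x)),
    avgpool = avgpool_forward(layer, x),
    maxpool = maxpool_forward(layer, x),
    batchnorm = batchnorm_forward(layer, x),
    gap = {
      d <- dim(x)
      xm <- array(x, c(d[1] * d[2], d[3], d[4]))
      list(out = colMeans(xm), cache = list(d = d))
    },
    linear = {
      y <- layer$params$W %*% x + layer$params$b
      list(out = y, cache = list(x = x))
    },
    residual = {
      fm <- seq_forward(layer$main, x, training)
      fs <- if (!is.null(layer$shortcut)) seq_forward(layer$shortcut, x, training)
      pre <- fm$out + if (is.null(fs)) x else fs$out
      list(out = pmax(pre, 0),
           cache = list(main = fm$caches, shortcut = fs$caches, pos = pre > 0))
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dy, need_dx),
    relu = list(dx = relu_bwd_cpp(cache$x, dy), grads = NULL),
    avgpool = avgpool_backward(layer, cache, dy),
    maxpool = maxpool_backward(layer, cache, dy),
    batchnorm = batchnorm_backward(layer, cache, dy),
    gap = {
      d <- cache$d
      hw <- d[1] * d[2]
      list(dx = array(rep(as.vector(dy), each = hw) / hw, d), grads = NULL)
    },
    linear = list(dx = crossprod(layer$params$W, dy),
                  grads = list(W = dy %*% t(cache$x), b = rowSums(dy))),
    residual = {
      dpre <- dy * cache$pos
      bm <- seq_backward(layer$main, cache$main, dpre, need_input_grad = TRUE)
      grads <- list(main = bm$grads)
      dx <- bm$dx
      if (!is.null(layer$shortcut)) {
        bs <- seq_backward(layer$shortcut, cache$shortcut, dpre,
                           need_input_grad = TRUE)
        grads$shortcut <- bs$grads
        dx <- dx + bs$dx
      } else {
        dx <- dx + dpre
      }
      list(dx = dx, grads = grads)
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x, training)
    x <- f$out
    caches[[i]] <- f$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dy, need_input_grad = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_backward(layers[[i]], caches[[i]], dy,
                        need_dx = need_input_grad || i > 1L)
    dy <- b$dx
    grads[i] <- list(b$grads)   # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

# ---- parameter trees ---------------------------------------------------------
# Parameters live inside the (nested) layer lists; these helpers extract and
# reinsert them as matching trees so the optimizer can walk them uniformly.

seq_params <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "residual") {
      out <- list(main = seq_params(l$main))
      if (!is.null(l$shortcut)) out$shortcut <- seq_params(l$shortcut)
      out
    } else {
      l$params
    }
  })
}

seq_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "residual") {
      layers[[i]]$main <- seq_set_params(layers[[i]]$main, params[[i]]$main)
      if (!is.null(layers[[i]]$shortcut)) {
        layers[[i]]$shortcut <- seq_set_params(layers[[i]]$shortcut,
                                               params[[i]]$shortcut)
      }
    } else if (!is.null(params[[i]])) {
      layers[[i]]$params <- params[[i]]
    }
  }
  layers
}

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else if (is.null(tree)) NULL else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[i] <- list(tree_map2(f, a[[i]], b[[i]]))
    out
  } else if (is.null(a)) {
    NULL
  } else {
    f(a, b)
  }
}

tree_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_count, numeric(1))) else if (is.null(tree)) 0 else length(tree)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params, lr = 2e-6, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  mv <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + state$eps),
                  state$m, state$v)
  params <- tree_map2(function(p, u) p - state$lr * u, params, mv)
  list(state = state, params = params)
}
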
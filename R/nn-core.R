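# Minimal BLAS-backed neural-network engine.
#
# Feature maps are channels-last arrays of dim (slice, row, col, channels)
# for a single sample (the training protocol uses batch size 1; larger
# batches are handled by gradient accumulation in the trainer). Convolutions,
# batch-norm and ReLU run in C++ (src/conv_ops.cpp) as direct cache-blocked
# loops: at the small channel counts of width-reduced networks this beats
# im2col + BLAS, whose patch matrices dominate runtime through allocation
# traffic. The conv weight matrix is (out_channels, in_channels*K) with
# columns ordered kernel-offset fastest (slice offset innermost), channel
# slowest. Each module is a plain list with a `type` field; `mod_forward()`
# returns the output, a cache for the backward pass, and the (possibly
# updated, e.g. batch-norm running stats) module; `mod_backward()` returns
# the input gradient and a gradient tree mirroring the parameter tree.

# conv_mode is purely descriptive ("3D", "2D", "1D"): the kernel tuple is
# what defines the operation.
nn_conv3d <- function(in_ch, out_ch, kernel, stride = c(1L, 1L, 1L),
                      pad = c(0L, 0L, 0L), conv_mode = "3D", name = "conv") {
  k <- as.integer(kernel)
  fan_out <- out_ch * prod(k)
  w <- matrix(stats::rnorm(out_ch * in_ch * prod(k), 0, sqrt(2 / fan_out)),
              nrow = out_ch)
  list(type = "conv3d", name = name, in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), kernel = k, stride = as.integer(stride),
       pad = as.integer(pad), conv_mode = conv_mode,
       params = list(weight = w))
}

conv3d_out_dim <- function(in_sp, kernel, stride, pad) {
  (in_sp + 2L * pad - kernel) %/% stride + 1L
}

conv3d_forward <- function(m, x) {
  dmx <- dim(x)
  if (dmx[4] != m$in_ch) {
    stop(sprintf("layer '%s': expected %d input channels, got %d",
                 m$name, m$in_ch, dmx[4]), call. = FALSE)
  }
  od <- conv3d_out_dim(dmx[1:3], m$kernel, m$stride, m$pad)
  if (any(od < 1L)) {
    stop(sprintf("layer '%s': input %s too small for kernel %s / stride %s",
                 m$name, paste(dmx[1:3], collapse = "x"),
                 paste(m$kernel, collapse = "x"),
                 paste(m$stride, collapse = "x")),
         call. = FALSE)
  }
  y <- conv3d_fwd(x, dmx, m$params$weight, m$kernel, m$stride, m$pad, od)
  list(y = y, cache = list(x = x, xdim = dmx, od = od), mod = m)
}

conv3d_backward <- function(m, cache, dy) {
  od <- cache$od
  dW <- conv3d_bwd_weight(dy, cache$x, cache$xdim, m$out_ch, m$kernel,
                          m$stride, m$pad, od)
  # the network input needs no gradient: skip the transposed convolution
  # for the root (stem) convolution
  dx <- if (isTRUE(m$root_input)) NULL else
    conv3d_bwd_data(dy, cache$xdim, m$params$weight, m$kernel, m$stride,
                    m$pad, od)
  list(dx = dx, grads = list(weight = dW))
}

nn_bn3d <- function(ch, eps = 1e-5, momentum = 0.1, name = "bn") {
  list(type = "bn3d", name = name, ch = as.integer(ch), eps = eps,
       momentum = momentum,
       params = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buffers = list(running_mean = rep(0, ch), running_var = rep(1, ch)))
}

# Normalisation uses the sample's own per-channel spatial statistics in
# BOTH modes: with the batch-size-1 protocol, running-average statistics
# systematically mismatch the statistics used during optimisation (each
# training sample is normalised by its own), which breaks evaluation on
# small cohorts. Per-sample statistics keep evaluation deterministic (the
# map depends only on the input) and match the instance-normalisation
# convention widely used for volumetric medical images. Running statistics
# are still tracked during training and stored in checkpoints for
# reference.
bn3d_forward <- function(m, x, training) {
  d <- dim(x)
  ch <- d[4]
  n <- prod(d[1:3])
  r <- bn_fwd_train(x, n, ch, m$params$gamma, m$params$beta, m$eps)
  y <- r$y
  dim(y) <- d
  if (training) {
    mom <- m$momentum
    m$buffers$running_mean <- (1 - mom) * m$buffers$running_mean + mom * r$mu
    vu <- if (n > 1) r$var * n / (n - 1) else r$var
    m$buffers$running_var <- (1 - mom) * m$buffers$running_var + mom * vu
    list(y = y, cache = list(xhat = r$xhat, ivar = r$ivar, n = n, d = d),
         mod = m)
  } else {
    list(y = y, cache = NULL, mod = m)
  }
}

bn3d_backward <- function(m, cache, dy) {
  d <- cache$d
  r <- bn_bwd(dy, cache$xhat, cache$ivar, m$params$gamma, cache$n, d[4])
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

nn_relu <- function(name = "relu") list(type = "relu", name = name)

nn_gap <- function(name = "avgpool") list(type = "gap", name = name)

nn_dropout <- function(p, name = "dropout") {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", name = name, p = p)
}

nn_linear <- function(in_f, out_f, name = "fc") {
  bound <- 1 / sqrt(in_f)
  list(type = "linear", name = name, in_f = as.integer(in_f),
       out_f = as.integer(out_f),
       params = list(
         weight = matrix(stats::runif(out_f * in_f, -bound, bound), out_f),
         bias = stats::runif(out_f, -bound, bound)))
}

nn_seq <- function(children, name = "seq") {
  list(type = "seq", name = name, children = children)
}

# Residual block: y = relu(main(x) + shortcut(x)); shortcut NULL = identity.
nn_block <- function(main, shortcut = NULL, name = "block") {
  list(type = "block", name = name, main = main, shortcut = shortcut)
}

mod_forward <- function(m, x, training = FALSE) {
  switch(m$type,
    conv3d = conv3d_forward(m, x),
    bn3d = bn3d_forward(m, x, training),
    relu = {
      y <- relu_fwd(x)
      attributes(y) <- attributes(x)
      list(y = y, cache = y, mod = m)
    },
    gap = {
      d <- dim(x)
      y <- .colMeans(matrix(x, prod(d[1:3]), d[4]), prod(d[1:3]), d[4])
      list(y = y, cache = d, mod = m)
    },
    dropout = {
      if (training && m$p > 0) {
        keep <- (stats::runif(length(x)) >= m$p) / (1 - m$p)
        list(y = x * keep, cache = keep, mod = m)
      } else {
        list(y = x, cache = NULL, mod = m)
      }
    },
    linear = {
      y <- drop(m$params$weight %*% x + m$params$bias)
      list(y = y, cache = x, mod = m)
    },
    seq = {
      caches <- vector("list", length(m$children))
      for (i in seq_along(m$children)) {
        r <- mod_forward(m$children[[i]], x, training)
        x <- r$y
        caches[[i]] <- r$cache
        m$children[[i]] <- r$mod
      }
      list(y = x, cache = caches, mod = m)
    },
    block = {
      rm_ <- mod_forward(m$main, x, training)
      m$main <- rm_$mod
      if (is.null(m$shortcut)) {
        sc <- x
        sc_cache <- NULL
      } else {
        rs <- mod_forward(m$shortcut, x, training)
        m$shortcut <- rs$mod
        sc <- rs$y
        sc_cache <- rs$cache
      }
      y <- add_relu_fwd(rm_$y, sc)
      attributes(y) <- attributes(rm_$y)
      list(y = y, cache = list(main = rm_$cache, shortcut = sc_cache,
                               y = y), mod = m)
    },
    stop("unknown module type: ", m$type)
  )
}

mod_backward <- function(m, cache, dy) {
  switch(m$type,
    conv3d = conv3d_backward(m, cache, dy),
    bn3d = bn3d_backward(m, cache, dy),
    relu = {
      dx <- relu_bwd(dy, cache)
      attributes(dx) <- attributes(dy)
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache
      n_sp <- prod(d[1:3])
      dx <- array(rep(dy / n_sp, each = n_sp), d)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    },
    linear = {
      dyv <- as.numeric(dy)
      list(dx = drop(crossprod(m$params$weight, dyv)),
           grads = list(weight = tcrossprod(dyv, as.numeric(cache)),
                        bias = dyv))
    },
    seq = {
      grads <- vector("list", length(m$children))
      names(grads) <- names(m$children)
      for (i in rev(seq_along(m$children))) {
        r <- mod_backward(m$children[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dy, grads = grads)
    },
    block = {
      dy0 <- dy
      dy <- relu_bwd(dy0, cache$y)
      attributes(dy) <- attributes(dy0)
      rm_ <- mod_backward(m$main, cache$main, dy)
      if (is.null(m$shortcut)) {
        dsc <- dy
        gsc <- NULL
      } else {
        rs <- mod_backward(m$shortcut, cache$shortcut, dy)
        dsc <- rs$dx
        gsc <- rs$grads
      }
      list(dx = rm_$dx + dsc, grads = list(main = rm_$grads, shortcut = gsc))
    },
    stop("unknown module type: ", m$type)
  )
}

# Flatten the parameter tree to a named list ("stage2.block1.main.conv1.weight").
mod_flatten <- function(m, prefix = NULL, what = "params") {
  out <- list()
  if (!is.null(m[[what]])) {
    for (pn in names(m[[what]])) {
      key <- paste(c(prefix, pn), collapse = ".")
      out[[key]] <- m[[what]][[pn]]
    }
  }
  for (slot in c("children", "main", "shortcut")) {
    sub <- m[[slot]]
    if (is.null(sub)) next
    if (slot == "children") {
      for (nm in names(sub)) {
        out <- c(out, mod_flatten(sub[[nm]], c(prefix, nm), what))
      }
    } else {
      out <- c(out, mod_flatten(sub, c(prefix, slot), what))
    }
  }
  out
}

# Flatten a gradient tree produced by mod_backward using the module tree for
# naming; returns the same keys as mod_flatten(m).
grads_flatten <- function(m, g, prefix = NULL) {
  out <- list()
  if (!is.null(m$params)) {
    for (pn in names(m$params)) {
      out[[paste(c(prefix, pn), collapse = ".")]] <- g[[pn]]
    }
    return(out)
  }
  if (!is.null(m$children)) {
    for (nm in names(m$children)) {
      out <- c(out, grads_flatten(m$children[[nm]], g[[nm]], c(prefix, nm)))
    }
  }
  if (!is.null(m$main)) {
    out <- c(out, grads_flatten(m$main, g$main, c(prefix, "main")))
  }
  if (!is.null(m$shortcut)) {
    out <- c(out, grads_flatten(m$shortcut, g$shortcut, c(prefix, "shortcut")))
  }
  out
}

mod_set_params <- function(m, flat, prefix = NULL) {
  if (!is.null(m$params)) {
    for (pn in names(m$params)) {
      key <- paste(c(prefix, pn), collapse = ".")
      if (!is.null(flat[[key]])) {
        stopifnot(length(flat[[key]]) == length(m$params[[pn]]))
        val <- flat[[key]]
        if (!is.null(dim(m$params[[pn]]))) dim(val) <- dim(m$params[[pn]])
        m$params[[pn]] <- val
      }
    }
  }
  if (!is.null(m$children)) {
    for (nm in names(m$children)) {
      m$children[[nm]] <- mod_set_params(m$children[[nm]], flat,
                                         c(prefix, nm))
    }
  }
  if (!is.null(m$main)) m$main <- mod_set_params(m$main, flat, c(prefix, "main"))
  if (!is.null(m$shortcut)) {
    m$shortcut <- mod_set_params(m$shortcut, flat, c(prefix, "shortcut"))
  }
  m
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decoupled-from-nothing classic Adam with L2 weight decay folded into the
# gradient (the convention of the reference deep-learning stacks).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
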
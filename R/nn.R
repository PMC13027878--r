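# Minimal dense-tensor neural-network core: convolution, transposed
# convolution, batch normalization, ReLU and max-pooling layers with
# hand-written backward passes over a static module tree.  Tensors are
# column-major R arrays [H, W, C, N]; the compiled kernels in src/ do the
# heavy lifting through BLAS.

he_init <- function(kh, kw, cin, cout, fan) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan)),
        dim = c(kh, kw, cin, cout))
}

mConv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                  bias = FALSE) {
  list(kind = "conv",
       W = he_init(k, k, cin, cout, fan = k * k * cin),
       b = if (bias) numeric(cout) else NULL,
       stride = as.integer(stride), pad = as.integer(pad))
}

# weight layout [k, k, cout, cin]: the weight of the adjoint convolution
mConvT <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, bias = TRUE) {
  list(kind = "convt",
       W = he_init(k, k, cout, cin, fan = k * k * cin / (stride^2)),
       b = if (bias) numeric(cout) else NULL,
       stride = as.integer(stride), pad = as.integer(pad))
}

mBN <- function(c, frozen = FALSE, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c),
       momentum = momentum, eps = eps, frozen = frozen)
}

mReLU <- function() list(kind = "relu")

mMaxPool <- function(k, stride = k, pad = 0L) {
  list(kind = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

mSeq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.null(mods[[1]]$kind)) mods <- mods[[1]]
  list(kind = "seq", mods = mods)
}

# residual block: y = relu(branch(x) + shortcut(x))
mRes <- function(branch, down = NULL) {
  mods <- list(branch = branch)
  if (!is.null(down)) mods$down <- down
  list(kind = "res", mods = mods)
}

# the final batch norm of each residual branch starts at zero gain
# (zero-init residual): blocks are identity-like at initialization, which
# keeps activation variance bounded through deep stacks
mBNZero <- function(c) {
  m <- mBN(c)
  m$gamma <- numeric(c)
  m
}

mBasicBlock <- function(cin, cout, stride = 1L) {
  branch <- mSeq(mConv(cin, cout, 3L, stride), mBN(cout), mReLU(),
                 mConv(cout, cout, 3L), mBNZero(cout))
  down <- if (stride != 1L || cin != cout)
    mSeq(mConv(cin, cout, 1L, stride, pad = 0L), mBN(cout))
  mRes(branch, down)
}

mBottleneck <- function(cin, mid, cout, stride = 1L) {
  branch <- mSeq(mConv(cin, mid, 1L, pad = 0L), mBN(mid), mReLU(),
                 mConv(mid, mid, 3L, stride), mBN(mid), mReLU(),
                 mConv(mid, cout, 1L, pad = 0L), mBNZero(cout))
  down <- if (stride != 1L || cin != cout)
    mSeq(mConv(cin, cout, 1L, stride, pad = 0L), mBN(cout))
  mRes(branch, down)
}

# set rm/rv of every frozen batch norm from one forward pass of real data
# (one-shot statistics calibration; used when no pretrained statistics
# exist).  Temporarily runs the frozen layers in batch mode with
# momentum 1 so the running stats become the observed batch stats.
calibrate_frozen_bn <- function(mod, x) {
  open <- function(m) {
    if (identical(m$kind, "bn") && m$frozen) {
      m$frozen <- FALSE
      m$momentum <- 1
      m$was_frozen <- TRUE
    }
    if (!is.null(m$mods)) m$mods <- lapply(m$mods, open)
    m
  }
  refreeze <- function(m) {
    if (identical(m$kind, "bn") && isTRUE(m$was_frozen)) {
      m$frozen <- TRUE
      m$momentum <- 0.1
      m$was_frozen <- NULL
    }
    if (!is.null(m$mods)) m$mods <- lapply(m$mods, refreeze)
    m
  }
  r <- nnForward(open(mod), x, training = TRUE)
  refreeze(r$mod)
}

# ---- batch norm ------------------------------------------------------------

# per-channel statistics of an [HW, C, N] array without transposition:
# colSums collapses HW leaving a C x N matrix
bn_channel_stats <- function(x3) {
  hwn <- dim(x3)[1] * dim(x3)[3]
  mu <- rowSums(colSums(x3)) / hwn
  v <- rowSums(colSums(x3 * x3)) / hwn - mu^2
  list(mu = mu, var = pmax(v, 0))
}

# broadcast a per-channel vector over [HW, C, N] (recycles across N)
bn_rep <- function(a, hw) rep(a, each = hw)

bn_forward <- function(mod, x, training) {
  d <- dim(x)
  hw <- d[1] * d[2]
  x3 <- x; dim(x3) <- c(hw, d[3], d[4])
  batch_mode <- training && !mod$frozen
  if (batch_mode) {
    st <- bn_channel_stats(x3)
    mu <- st$mu; var <- st$var
    mod$rm <- (1 - mod$momentum) * mod$rm + mod$momentum * mu
    mod$rv <- (1 - mod$momentum) * mod$rv + mod$momentum * var
  } else {
    mu <- mod$rm; var <- mod$rv
  }
  invstd <- 1 / sqrt(var + mod$eps)
  xhat <- x3 * bn_rep(invstd, hw) - bn_rep(mu * invstd, hw)
  y <- xhat * bn_rep(mod$gamma, hw) + bn_rep(mod$beta, hw)
  dim(y) <- d
  cache <- list(xhat = if (training) xhat, invstd = invstd,
                batch = batch_mode, d = d)
  list(y = y, cache = cache, mod = mod)
}

bn_backward <- function(mod, cache, gy) {
  d <- cache$d
  hw <- d[1] * d[2]
  g3 <- gy; dim(g3) <- c(hw, d[3], d[4])
  ggamma <- rowSums(colSums(g3 * cache$xhat))
  gbeta <- rowSums(colSums(g3))
  if (cache$batch) {
    m <- hw * d[4]
    coef <- mod$gamma * cache$invstd / m
    gx3 <- (m * g3 - cache$xhat * bn_rep(ggamma, hw) - bn_rep(gbeta, hw)) *
      bn_rep(coef, hw)
  } else {
    gx3 <- g3 * bn_rep(mod$gamma * cache$invstd, hw)
  }
  dim(gx3) <- d
  list(gx = gx3, grads = list(gamma = ggamma, beta = gbeta))
}

# ---- forward / backward dispatch -------------------------------------------

nnForward <- function(mod, x, training = FALSE) {
  switch(mod$kind,
    conv = {
      y <- .conv2d_fw(x, mod$W, mod$b, mod$stride, mod$pad)
      list(y = y, cache = list(x = x), mod = mod)
    },
    convt = {
      y <- .convt2d_fw(x, mod$W, mod$b, mod$stride, mod$pad)
      list(y = y, cache = list(x = x), mod = mod)
    },
    bn = bn_forward(mod, x, training),
    relu = {
      y <- x
      y[y < 0] <- 0
      list(y = y, cache = list(mask = x > 0), mod = mod)
    },
    maxpool = {
      r <- .maxpool_fw(x, mod$k, mod$stride, mod$pad)
      list(y = r$y, cache = list(arg = r$arg, d = dim(x)), mod = mod)
    },
    seq = {
      caches <- vector("list", length(mod$mods))
      h <- x
      for (i in seq_along(mod$mods)) {
        r <- nnForward(mod$mods[[i]], h, training)
        h <- r$y
        caches[[i]] <- r$cache
        mod$mods[[i]] <- r$mod
      }
      list(y = h, cache = caches, mod = mod)
    },
    res = {
      rb <- nnForward(mod$mods$branch, x, training)
      mod$mods$branch <- rb$mod
      if (!is.null(mod$mods$down)) {
        rd <- nnForward(mod$mods$down, x, training)
        mod$mods$down <- rd$mod
        s <- rd$y
        dcache <- rd$cache
      } else {
        s <- x
        dcache <- NULL
      }
      pre <- rb$y + s
      y <- pre
      y[y < 0] <- 0
      list(y = y, cache = list(branch = rb$cache, down = dcache,
                               mask = pre > 0), mod = mod)
    },
    stop("unknown module kind: ", mod$kind))
}

nnBackward <- function(mod, cache, gy) {
  switch(mod$kind,
    conv = {
      r <- .conv2d_bw(cache$x, mod$W, gy, mod$stride, mod$pad,
                      !is.null(mod$b))
      list(gx = r$gx,
           grads = list(W = r$gw, b = if (!is.null(mod$b)) r$gb))
    },
    convt = {
      r <- .convt2d_bw(cache$x, mod$W, gy, mod$stride, mod$pad,
                       !is.null(mod$b))
      list(gx = r$gx,
           grads = list(W = r$gw, b = if (!is.null(mod$b)) r$gb))
    },
    bn = bn_backward(mod, cache, gy),
    relu = list(gx = gy * cache$mask, grads = NULL),
    maxpool = {
      d <- cache$d
      list(gx = .maxpool_bw(gy, cache$arg, d[1], d[2], d[3], d[4]),
           grads = NULL)
    },
    seq = {
      grads <- vector("list", length(mod$mods))
      g <- gy
      for (i in rev(seq_along(mod$mods))) {
        r <- nnBackward(mod$mods[[i]], cache[[i]], g)
        g <- r$gx
        grads[i] <- list(r$grads)  # keep NULL grads as placeholders
      }
      list(gx = g, grads = list(mods = grads))
    },
    res = {
      g <- gy * cache$mask
      rb <- nnBackward(mod$mods$branch, cache$branch, g)
      grads <- list(branch = rb$grads)
      if (!is.null(mod$mods$down)) {
        rd <- nnBackward(mod$mods$down, cache$down, g)
        gx <- rb$gx + rd$gx
        grads$down <- rd$grads
      } else {
        gx <- rb$gx + g
      }
      list(gx = gx, grads = list(mods = grads))
    },
    stop("unknown module kind: ", mod$kind))
}

# ---- parameter bookkeeping -------------------------------------------------

param_fields <- function(kind) {
  switch(kind, conv = , convt = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

#' Flat named list of trainable parameters of a model or module
#' @param mod a model built with [buildModel()] (or any internal module).
#' @param prefix name prefix used for the flat names.
#' @return named list of numeric arrays.
#' @export
nnParams <- function(mod, prefix = "m") {
  out <- list()
  for (f in param_fields(mod$kind)) {
    if (!is.null(mod[[f]])) out[[paste(prefix, f, sep = ".")]] <- mod[[f]]
  }
  if (!is.null(mod$mods)) {
    nms <- names(mod$mods)
    for (i in seq_along(mod$mods)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, nnParams(mod$mods[[i]], paste(prefix, nm, sep = ".")))
    }
  }
  out
}

#' Load a flat parameter list back into a model
#' @param mod a model or module.
#' @param flat named list as produced by [nnParams()].
#' @param prefix name prefix (must match the one used in [nnParams()]).
#' @return the model with parameters replaced.
#' @export
nnSetParams <- function(mod, flat, prefix = "m") {
  for (f in param_fields(mod$kind)) {
    nm <- paste(prefix, f, sep = ".")
    if (!is.null(mod[[f]])) {
      if (is.null(flat[[nm]])) stop("missing parameter: ", nm)
      if (length(flat[[nm]]) != length(mod[[f]]))
        stop("parameter size mismatch: ", nm)
      val <- flat[[nm]]
      if (!is.null(dim(mod[[f]]))) dim(val) <- dim(mod[[f]])
      mod[[f]] <- val
    }
  }
  if (!is.null(mod$mods)) {
    nms <- names(mod$mods)
    for (i in seq_along(mod$mods)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      mod$mods[[i]] <- nnSetParams(mod$mods[[i]], flat,
                                   paste(prefix, nm, sep = "."))
    }
  }
  mod
}

buffer_fields <- function(kind) {
  if (identical(kind, "bn")) c("rm", "rv") else character(0)
}

#' Flat named list of non-trainable buffers (batch-norm running stats)
#' @param mod a model or module.
#' @param prefix name prefix used for the flat names.
#' @return named list of numeric vectors.
#' @export
nnBuffers <- function(mod, prefix = "m") {
  out <- list()
  for (f in buffer_fields(mod$kind)) {
    out[[paste(prefix, f, sep = ".")]] <- mod[[f]]
  }
  if (!is.null(mod$mods)) {
    nms <- names(mod$mods)
    for (i in seq_along(mod$mods)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, nnBuffers(mod$mods[[i]], paste(prefix, nm, sep = ".")))
    }
  }
  out
}

#' Load flat buffers back into a model
#' @param mod a model or module.
#' @param flat named list as produced by [nnBuffers()].
#' @param prefix name prefix (must match [nnBuffers()]).
#' @return the model with buffers replaced.
#' @export
nnSetBuffers <- function(mod, flat, prefix = "m") {
  for (f in buffer_fields(mod$kind)) {
    nm <- paste(prefix, f, sep = ".")
    if (!is.null(flat[[nm]])) mod[[f]] <- flat[[nm]]
  }
  if (!is.null(mod$mods)) {
    nms <- names(mod$mods)
    for (i in seq_along(mod$mods)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      mod$mods[[i]] <- nnSetBuffers(mod$mods[[i]], flat,
                                    paste(prefix, nm, sep = "."))
    }
  }
  mod
}

# flatten a gradient tree (as returned by nnBackward) with names aligned
# to nnParams
nnFlattenGrads <- function(mod, grads, prefix = "m") {
  out <- list()
  for (f in param_fields(mod$kind)) {
    if (!is.null(mod[[f]]))
      out[[paste(prefix, f, sep = ".")]] <- grads[[f]]
  }
  if (!is.null(mod$mods)) {
    nms <- names(mod$mods)
    for (i in seq_along(mod$mods)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, nnFlattenGrads(mod$mods[[i]], grads$mods[[i]],
                                   paste(prefix, nm, sep = ".")))
    }
  }
  out
}
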
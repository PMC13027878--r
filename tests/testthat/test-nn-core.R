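# Finite-difference validation of every layer's hand-written backward
# pass, and of the parameter bookkeeping that feeds the optimizer.

ns <- asNamespace("sdresnet")

grad_check <- function(mod, x, training = TRUE, eps = 1e-6, tol = 1e-5) {
  fw <- ns$nnForward(mod, x, training)
  gy <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$nnBackward(mod, fw$cache, gy)
  lossAt <- function(xx, m) sum(ns$nnForward(m, xx, training)$y * gy)
  idx <- sample(length(x), 4)
  num <- vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (lossAt(x1, mod) - lossAt(x2, mod)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - bw$gx[idx]) / (abs(num) + 1e-6)), tol)
  # parameter gradients, via the flattened view the optimizer consumes
  flat <- ns$nnFlattenGrads(mod, bw$grads)
  pv <- nnParams(mod)
  expect_identical(names(flat), names(pv))
  for (nm in sample(names(pv), min(4, length(pv)))) {
    i <- sample(length(pv[[nm]]), 1)
    pert <- function(s) {
      p2 <- pv
      p2[[nm]][i] <- p2[[nm]][i] + s
      nnSetParams(mod, p2)
    }
    num <- (lossAt(x, pert(eps)) - lossAt(x, pert(-eps))) / (2 * eps)
    expect_lt(abs(num - flat[[nm]][i]) / (abs(num) + 1e-6), tol)
  }
}

test_that("layer backward passes match finite differences", {
  set.seed(77)
  x <- array(stats::rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  grad_check(ns$mConv(3L, 4L, 3L, bias = TRUE), x)
  grad_check(ns$mConv(3L, 4L, 3L, stride = 2L), x)
  grad_check(ns$mConvT(3L, 4L), x)
  grad_check(ns$mBN(3L), x)
  frozen <- ns$mBN(3L)
  frozen$rm <- stats::rnorm(3)
  frozen$rv <- stats::runif(3, 0.5, 2)
  frozen$frozen <- TRUE
  grad_check(frozen, x)
  grad_check(ns$mMaxPool(2L), x)
  grad_check(ns$mBasicBlock(3L, 6L, 2L), x)
  grad_check(ns$mBottleneck(3L, 2L, 8L, 2L), x)
})

test_that("whole-model gradients match finite differences", {
  set.seed(78)
  m <- buildModel(modelConfig("small", seed = 3L))
  x <- array(stats::rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  fw <- ns$model_forward_train(m, x)
  gy <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  g <- ns$model_backward(fw$model, fw$caches, gy)
  pv <- nnParams(m)
  expect_identical(names(g), names(pv))
  lossAt <- function(mm) sum(ns$model_forward_train(mm, x)$y * gy)
  eps <- 1e-5
  for (nm in sample(names(pv), 5)) {
    i <- sample(length(pv[[nm]]), 1)
    p2 <- pv; p2[[nm]][i] <- p2[[nm]][i] + eps
    up <- lossAt(nnSetParams(m, p2))
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    dn <- lossAt(nnSetParams(m, p2))
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - g[[nm]][i]) / (abs(num) + 1e-6), 1e-4)
  }
})

test_that("conv forward agrees with a direct loop on a small case", {
  set.seed(79)
  x <- array(stats::rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w <- array(stats::rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  got <- ns$nnForward(ns$mConv(2L, 3L, 3L), x)$y  # replace weights below
  mod <- ns$mConv(2L, 3L, 3L)
  mod$W <- w
  got <- ns$nnForward(mod, x)$y
  ref <- array(0, c(5, 5, 3, 1))
  for (co in 1:3) for (oy in 1:5) for (ox in 1:5) {
    acc <- 0
    for (ci in 1:2) for (kh in 1:3) for (kw in 1:3) {
      iy <- oy + kh - 2; ix <- ox + kw - 2
      if (iy >= 1 && iy <= 5 && ix >= 1 && ix <= 5)
        acc <- acc + x[iy, ix, ci, 1] * w[kh, kw, ci, co]
    }
    ref[oy, ox, co, 1] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  set.seed(80)
  # <conv(x), y> == <x, convT(y)> for matched weights
  x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  y <- array(stats::rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  w <- array(stats::rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  conv <- ns$mConv(2L, 3L, 4L, stride = 2L, pad = 1L); conv$W <- w
  convt <- ns$mConvT(3L, 2L, 4L, stride = 2L, pad = 1L)
  convt$W <- w  # [k, k, cout(=2), cin(=3)] matches conv's [k, k, 2, 3]
  convt$b <- NULL
  lhs <- sum(ns$nnForward(conv, x)$y * y)
  rhs <- sum(x * ns$nnForward(convt, y)$y)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("buffers round-trip and frozen-BN calibration freezes again", {
  m <- buildModel(modelConfig("small", seed = 5L))
  b <- nnBuffers(m)
  b2 <- lapply(b, function(v) v + 0.5)
  m2 <- nnSetBuffers(m, b2)
  expect_equal(nnBuffers(m2), b2)
  x <- array(stats::rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  enc <- ns$calibrate_frozen_bn(m$mods$encoder, x)
  isFrozen <- function(mod) {
    out <- TRUE
    walk <- function(mm) {
      if (identical(mm$kind, "bn") && !mm$frozen) out <<- FALSE
      if (!is.null(mm$mods)) lapply(mm$mods, walk)
    }
    walk(mod)
    out
  }
  expect_true(isFrozen(enc))
  # calibration moved the statistics towards the data
  expect_false(identical(nnBuffers(enc), nnBuffers(m$mods$encoder)))
})
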
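# Image-quality metrics, dB-compressed visualization and test-set
# aggregation.  SSIM follows the single global formula with additive
# constants C1 = 0.01 and C2 = 0.03 computed from whole-image moments
# (population, i.e. 1/N, variances); a conventional windowed variant is
# available behind a flag for comparison.

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch between images")
}

#' Mean squared error between two images
#' @param x,y numeric matrices of identical shape.
#' @return mean of squared differences (>= 0).
#' @export
imageMSE <- function(x, y) {
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(L^2 / MSE)`; identical images give `Inf`.
#'
#' @param x,y numeric matrices of identical shape.
#' @param L maximum possible intensity (1 for normalized images).
#' @return PSNR in dB.
#' @export
imagePSNR <- function(x, y, L = 1) {
  m <- imageMSE(x, y)
  if (m == 0) Inf else 10 * log10(L^2 / m)
}

#' Structural similarity (global formula)
#'
#' Single global value
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' from whole-image means, variances and covariance with `C1 = 0.01`,
#' `C2 = 0.03`.  With `windowed = TRUE` an 11 x 11 Gaussian-window mean
#' SSIM with the conventional `(K L)^2` constants is returned instead.
#'
#' @param x,y numeric matrices of identical shape (>= 2 pixels).
#' @param C1,C2 stabilizing constants of the global formula.
#' @param windowed use the sliding-window variant.
#' @return SSIM value (<= 1).
#' @export
imageSSIM <- function(x, y, C1 = 0.01, C2 = 0.03, windowed = FALSE) {
  check_same_shape(x, y)
  if (length(x) < 2) stop("need at least 2 pixels")
  if (windowed) return(ssim_windowed(x, y))
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# conventional mean SSIM over an 11x11 Gaussian window (sigma 1.5),
# constants (0.01 L)^2 and (0.03 L)^2 with L = 1
ssim_windowed <- function(x, y) {
  k <- 11L
  g <- outer(stats::dnorm(seq(-5, 5), sd = 1.5),
             stats::dnorm(seq(-5, 5), sd = 1.5))
  g <- g / sum(g)
  w <- array(g, c(k, k, 1, 1))
  f <- function(img) {
    a <- array(img, c(nrow(img), ncol(img), 1, 1))
    .conv2d_fw(a, w, NULL, 1L, 0L)[, , 1, 1]
  }
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2; vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  C1 <- 0.01^2; C2 <- 0.03^2
  s <- (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Pearson correlation coefficient over pixels
#'
#' @param x,y numeric matrices of identical shape.
#' @return correlation in `[-1, 1]`; if either image is constant the
#'   correlation is undefined and 0 is returned with attribute
#'   `undefined = TRUE`.
#' @export
imagePCC <- function(x, y) {
  check_same_shape(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- 0
    attr(r, "undefined") <- TRUE
    return(r)
  }
  stats::cor(as.numeric(x), as.numeric(y))
}

#' Log-compress an image to decibels
#'
#' `20 * log10(I / (max(I) + eps))`, clipped to `[-floorDb, 0]`.  The
#' maximum pixel maps to (numerically) 0 dB.
#'
#' @param img numeric matrix with a positive maximum.
#' @param floorDb dynamic-range floor in dB (displayed range
#'   `[-floorDb, 0]`).
#' @param eps small constant preventing `log(0)`.
#' @return matrix of dB values in `[-floorDb, 0]`.
#' @export
dbCompress <- function(img, floorDb = 50, eps = 1e-12) {
  m <- max(img)
  if (m <= 0) stop("image must have a positive maximum")
  v <- 20 * log10(pmax(img, 0) / (m + eps) + eps)
  pmin(pmax(v, -floorDb), 0)
}

#' Pixelwise absolute error map
#' @param img,gt numeric matrices of identical shape, normalized with the
#'   same scaling.
#' @return matrix of `|img - gt|`.
#' @export
absErrorMap <- function(img, gt) {
  check_same_shape(img, gt)
  abs(img - gt)
}

#' Evaluate a correction model on a test pair set
#'
#' For every pair, computes the four metrics (PSNR, SSIM, MSE, PCC)
#' against the ground truth both for the raw degraded reconstruction and
#' for the model-corrected output.  All images are normalized by their
#' highest absolute pixel value before metric computation.  Inputs to the
#' model go through the pairwise percentile normalization and 3-channel
#' replication of the training pipeline.
#'
#' @param model an SD-ResNet model (see [buildModel()]), or a plain
#'   function `f(array H x W x 3) -> matrix H x W` (useful for baseline
#'   stubs).
#' @param pairset a [PATPairSet-class]; must be non-empty.
#' @param weights optional flat weight list to load into the model before
#'   inference (e.g. EMA weights from a checkpoint).
#' @param buffers optional flat buffer list (batch-norm running
#'   statistics) matching the checkpointed weights.
#' @return list with `perImage` (data frame of per-image metrics) and
#'   `summary` (one row per method with metric means).
#' @export
evaluateTestSet <- function(model, pairset, weights = NULL, buffers = NULL) {
  stopifnot(is(pairset, "PATPairSet"))
  if (length(pairset@pairs) == 0) stop("empty test set")
  if (!is.function(model)) {
    if (!is.null(weights)) model <- nnSetParams(model, weights)
    if (!is.null(buffers)) model <- nnSetBuffers(model, buffers)
  }
  predict1 <- function(x3) {
    if (is.function(model)) return(model(x3))
    xb <- array(x3, c(dim(x3), 1))
    forwardModel(model, xb, training = FALSE)[, , 1, 1]
  }
  rows <- lapply(seq_along(pairset@pairs), function(i) {
    p <- pairset@pairs[[i]]
    np <- normalizePair(p$degraded, p$gt)
    out <- predict1(replicateChannels(np$degraded))
    gtN <- normalizeMax(np$gt)
    degN <- normalizeMax(np$degraded)
    corN <- normalizeMax(out)
    data.frame(
      pair = i, phantomId = p$phantomId, radiusUsed = p$radiusUsed,
      psnr_das = imagePSNR(degN, gtN), psnr_corr = imagePSNR(corN, gtN),
      ssim_das = imageSSIM(degN, gtN), ssim_corr = imageSSIM(corN, gtN),
      mse_das = imageMSE(degN, gtN), mse_corr = imageMSE(corN, gtN),
      pcc_das = as.numeric(imagePCC(degN, gtN)),
      pcc_corr = as.numeric(imagePCC(corN, gtN)))
  })
  perImage <- do.call(rbind, rows)
  summ <- data.frame(
    method = c("DAS", "corrected"),
    psnr = c(mean(perImage$psnr_das), mean(perImage$psnr_corr)),
    ssim = c(mean(perImage$ssim_das), mean(perImage$ssim_corr)),
    mse = c(mean(perImage$mse_das), mean(perImage$mse_corr)),
    pcc = c(mean(perImage$pcc_das), mean(perImage$pcc_corr)))
  list(perImage = perImage, summary = summ)
}
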
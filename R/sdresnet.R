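# SD-ResNet: residual encoder producing a stride-{4, 8, 16, 32} feature
# pyramid, and a five-stage anti-checkerboard transposed-convolution
# decoder fed only by the deepest feature map C5.

#' Model configuration
#'
#' @param encoder `"resnet50"` (the full 50-layer bottleneck encoder) or
#'   `"small"` (a 4-stage basic-block encoder with widths 16/32/64/128,
#'   same stride pattern, for CPU-scale experiments).
#' @param pretrained request externally pretrained encoder weights.  No
#'   weight file ships with the package, so requesting them falls back to
#'   random (He) initialization with a warning.
#' @param decoderStages number of doubling decoder stages (5 restores the
#'   stride-32 bottleneck to input resolution).
#' @param decoderChannels channel plan of the decoder stages; defaults to
#'   a geometric taper (2048 -> 512/256/128/64/32 for resnet50,
#'   128 -> 64/48/32/24/16 for small).
#' @param smoothing add the 3x3 smoothing convolution + batch norm + ReLU
#'   after every transposed convolution (the anti-checkerboard design);
#'   turning it off leaves plain transposed-convolution stages and exists
#'   for ablation.
#' @param seed RNG seed for weight initialization.
#' @return a named list of class `sdresnet_config`.
#' @export
modelConfig <- function(encoder = c("resnet50", "small"), pretrained = FALSE,
                        decoderStages = 5L, decoderChannels = NULL,
                        smoothing = TRUE, seed = 1L) {
  encoder <- match.arg(encoder)
  if (is.null(decoderChannels)) {
    decoderChannels <- if (encoder == "resnet50")
      c(512L, 256L, 128L, 64L, 32L) else c(64L, 48L, 32L, 24L, 16L)
  }
  if (length(decoderChannels) != decoderStages)
    stop("decoderChannels must have one entry per decoder stage")
  structure(list(encoder = encoder, pretrained = pretrained,
                 decoderStages = as.integer(decoderStages),
                 decoderChannels = as.integer(decoderChannels),
                 upKernel = 4L, upStride = 2L, smoothKernel = 3L,
                 smoothing = smoothing, seed = as.integer(seed)),
            class = "sdresnet_config")
}

freeze_bn <- function(mod) {
  if (identical(mod$kind, "bn")) mod$frozen <- TRUE
  if (!is.null(mod$mods))
    mod$mods <- lapply(mod$mods, freeze_bn)
  mod
}

build_encoder_resnet50 <- function() {
  stage <- function(cin, mid, cout, nblocks, stride) {
    blocks <- list(mBottleneck(cin, mid, cout, stride))
    for (i in seq_len(nblocks - 1)) {
      blocks <- c(blocks, list(mBottleneck(cout, mid, cout)))
    }
    mSeq(blocks)
  }
  list(kind = "seq", mods = list(
    stem = mSeq(mConv(3L, 64L, 7L, stride = 2L, pad = 3L), mBN(64L),
                mReLU(), mMaxPool(3L, 2L, 1L)),
    s1 = stage(64L, 64L, 256L, 3L, 1L),
    s2 = stage(256L, 128L, 512L, 4L, 2L),
    s3 = stage(512L, 256L, 1024L, 6L, 2L),
    s4 = stage(1024L, 512L, 2048L, 3L, 2L)))
}

build_encoder_small <- function() {
  stage <- function(cin, cout, stride) {
    mSeq(mBasicBlock(cin, cout, stride), mBasicBlock(cout, cout))
  }
  list(kind = "seq", mods = list(
    stem = mSeq(mConv(3L, 16L, 3L, stride = 2L), mBN(16L), mReLU(),
                mMaxPool(2L, 2L, 0L)),
    s1 = stage(16L, 16L, 1L),
    s2 = stage(16L, 32L, 2L),
    s3 = stage(32L, 64L, 2L),
    s4 = stage(64L, 128L, 2L)))
}

build_decoder <- function(cin, config) {
  mods <- list()
  ch <- cin
  for (i in seq_len(config$decoderStages)) {
    co <- config$decoderChannels[i]
    mods <- c(mods, list(mConvT(ch, co, config$upKernel, config$upStride,
                                pad = 1L, bias = TRUE)))
    if (config$smoothing) {
      mods <- c(mods, list(mConv(co, co, config$smoothKernel, bias = FALSE),
                           mBN(co), mReLU()))
    } else {
      mods <- c(mods, list(mReLU()))
    }
    ch <- co
  }
  final <- if (config$smoothing) mConv(ch, 1L, 3L, bias = TRUE)
           else mConv(ch, 1L, 1L, pad = 0L, bias = TRUE)
  mods <- c(mods, list(final))
  mSeq(mods)
}

#' Build an SD-ResNet model
#'
#' The encoder exposes a four-level feature pyramid C2..C5 at strides
#' 4/8/16/32; the decoder consumes only the deepest map C5 and restores
#' input resolution through `decoderStages` transposed-convolution stages
#' (kernel 4, stride 2, padding 1), each followed by a 3x3 smoothing
#' convolution with batch normalization and ReLU; a final 3x3 convolution
#' maps to one linear output channel.  Encoder batch-normalization layers
#' are frozen (evaluation mode, running statistics never updated).
#'
#' @param config a configuration from [modelConfig()].
#' @return a model object (list of class `sdresnet`).
#' @examples
#' m <- buildModel(modelConfig("small"))
#' x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3, 1))
#' dim(forwardModel(m, x))  # 64 64 1 1
#' @export
buildModel <- function(config = modelConfig()) {
  if (config$pretrained)
    warning("pretrained encoder weights are not available; ",
            "falling back to random initialization")
  enc <- with_seed(config$seed, {
    if (config$encoder == "resnet50") build_encoder_resnet50()
    else build_encoder_small()
  })
  enc <- freeze_bn(enc)
  c5 <- if (config$encoder == "resnet50") 2048L else 128L
  dec <- with_seed(config$seed + 1L, build_decoder(c5, config))
  structure(list(kind = "sdresnet",
                 mods = list(encoder = enc, decoder = dec),
                 config = config),
            class = "sdresnet")
}

#' @export
print.sdresnet <- function(x, ...) {
  np <- sum(vapply(nnParams(x$mods$encoder), length, numeric(1))) +
    sum(vapply(nnParams(x$mods$decoder), length, numeric(1)))
  cat(sprintf("SD-ResNet (%s encoder, %d decoder stages, %.2fM parameters)\n",
              x$config$encoder, x$config$decoderStages, np / 1e6))
  invisible(x)
}

check_input_dims <- function(x) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != 3)
    stop("input must be an [H, W, 3, N] array")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input height and width must be divisible by 32 (got ",
         d[1], "x", d[2], ")")
  invisible(d)
}

encoder_forward <- function(enc, x, training = FALSE) {
  feats <- list()
  caches <- list()
  h <- x
  for (nm in names(enc$mods)) {
    r <- nnForward(enc$mods[[nm]], h, training)
    h <- r$y
    caches[[nm]] <- r$cache
    enc$mods[[nm]] <- r$mod
    if (nm != "stem") feats[[paste0("C", 1 + length(feats) + 1)]] <- h
  }
  names(feats) <- paste0("C", 2:5)
  list(feats = feats, caches = caches, enc = enc)
}

#' Encoder feature pyramid
#'
#' Runs the encoder and returns the multi-scale features C2..C5 (strides
#' 4, 8, 16, 32 relative to the input).
#'
#' @param model an `sdresnet` model.
#' @param x input array `[H, W, 3, N]`, H and W divisible by 32.
#' @return named list with arrays `C2`, `C3`, `C4`, `C5`.
#' @export
encoderFeatures <- function(model, x) {
  check_input_dims(x)
  encoder_forward(model$mods$encoder, x, training = FALSE)$feats
}

#' Decode a feature pyramid to an image
#'
#' Only the deepest feature map `C5` is consumed; the shallower levels
#' are accepted (so a full pyramid can be passed) but have no influence
#' on the output.
#'
#' @param model an `sdresnet` model.
#' @param pyramid named list with at least `C5`, as returned by
#'   [encoderFeatures()].
#' @return output array `[H, W, 1, N]`.
#' @export
decodeFeatures <- function(model, pyramid) {
  c5 <- if (is.list(pyramid) && !is.null(pyramid$C5)) pyramid$C5 else pyramid
  nnForward(model$mods$decoder, c5, training = FALSE)$y
}

#' Full model forward pass
#'
#' @param model an `sdresnet` model.
#' @param x input array `[H, W, 3, N]`, spatial size divisible by 32.
#' @param training use training-mode batch statistics in the decoder's
#'   batch-normalization layers (encoder statistics are always frozen).
#' @return output array `[H, W, 1, N]` (linear, single channel).
#' @export
forwardModel <- function(model, x, training = FALSE) {
  check_input_dims(x)
  ef <- encoder_forward(model$mods$encoder, x, training)
  nnForward(model$mods$decoder, ef$feats$C5, training)$y
}

# forward with caches kept, for the training loop
model_forward_train <- function(model, x) {
  ef <- encoder_forward(model$mods$encoder, x, training = TRUE)
  rd <- nnForward(model$mods$decoder, ef$feats$C5, training = TRUE)
  model$mods$encoder <- ef$enc
  model$mods$decoder <- rd$mod
  list(y = rd$y, model = model,
       caches = list(encoder = ef$caches, decoder = rd$cache))
}

model_backward <- function(model, caches, gy) {
  rd <- nnBackward(model$mods$decoder, caches$decoder, gy)
  g <- rd$gx
  encGrads <- list()
  enc <- model$mods$encoder
  for (nm in rev(names(enc$mods))) {
    r <- nnBackward(enc$mods[[nm]], caches$encoder[[nm]], g)
    g <- r$gx
    encGrads[[nm]] <- r$grads
  }
  flat <- c(
    nnFlattenGrads(enc, list(mods = encGrads[names(enc$mods)]),
                   prefix = "m.encoder"),
    nnFlattenGrads(model$mods$decoder, rd$grads, prefix = "m.decoder"))
  flat
}

#' Checkerboard energy of an image
#'
#' Fraction of the (non-DC) spectral energy sitting in the Nyquist band
#' - components alternating +1/-1 along at least one axis - which is the
#' signature of uneven transposed-convolution kernel overlap (period-2
#' checkerboards and stripes).  0 for constant images; 1 for a perfect
#' checkerboard.
#'
#' @param img numeric matrix, at least 4 x 4.
#' @return score in `[0, 1]`.
#' @export
checkerboardEnergy <- function(img) {
  if (nrow(img) < 4 || ncol(img) < 4) stop("image must be at least 4x4")
  F <- Mod(stats::fft(img))^2
  total <- sum(F) - F[1, 1]
  if (total <= 0) return(0)
  iN <- floor(nrow(img) / 2) + 1L
  jN <- floor(ncol(img) / 2) + 1L
  (sum(F[iN, ]) + sum(F[, jN]) - F[iN, jN]) / total
}
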
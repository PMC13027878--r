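# Optimization of SD-ResNet: loss variants, warm-up + cosine learning
# rate schedule, AdamW with decoupled weight decay, per-step weight EMA,
# gated checkpointing and relative-improvement early stopping.

#' Training configuration
#'
#' @param maxEpochs conservative upper bound on epochs.
#' @param warmupEpochs linear warm-up length.
#' @param baseLr peak learning rate reached at the end of warm-up.
#' @param weightDecay decoupled AdamW weight-decay coefficient.
#' @param emaDecay per-step decay of the weight exponential moving
#'   average used for validation inference.
#' @param patience early stop after this many consecutive epochs without
#'   relative validation improvement.
#' @param gateEpoch best checkpoints are saved only at epochs strictly
#'   greater than this gate, so early unstable fluctuations cannot
#'   dominate model selection.
#' @param batchSize minibatch size.
#' @param seed RNG seed for shuffling, patch sampling and augmentation.
#' @param lossVariant `"absolute"` (L1, default) or `"squared"`.
#' @param cropSize centre-crop side applied to each image before patch
#'   sampling.
#' @param patchSize training patch side (must be divisible by 32).
#' @param relTol relative validation-loss reduction that counts as an
#'   improvement.
#' @param normScope `"patch"`: the percentile normalization interval is
#'   computed on each sampled ground-truth patch; `"image"`: it is
#'   computed once per image pair before cropping/patching, giving every
#'   patch of a pair the same intensity mapping.
#' @return named list of class `sdresnet_train_config`.
#' @export
trainConfig <- function(maxEpochs = 2000L, warmupEpochs = 5L, baseLr = 2e-4,
                        weightDecay = 1e-2, emaDecay = 0.992,
                        patience = 20L, gateEpoch = 21L, batchSize = 8L,
                        seed = 1L, lossVariant = c("absolute", "squared"),
                        cropSize = 80L, patchSize = 64L, relTol = 1e-4,
                        normScope = c("patch", "image")) {
  lossVariant <- match.arg(lossVariant)
  normScope <- match.arg(normScope)
  stopifnot(warmupEpochs < maxEpochs, emaDecay > 0, emaDecay < 1,
            patience >= 1, patchSize %% 32 == 0, patchSize <= cropSize)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 warmupEpochs = as.integer(warmupEpochs), baseLr = baseLr,
                 weightDecay = weightDecay, emaDecay = emaDecay,
                 patience = as.integer(patience),
                 gateEpoch = as.integer(gateEpoch),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 lossVariant = lossVariant, cropSize = as.integer(cropSize),
                 patchSize = as.integer(patchSize), relTol = relTol,
                 normScope = normScope),
            class = "sdresnet_train_config")
}

#' Reconstruction loss
#'
#' Mean over all pixels of `|pred - gt|` (variant `"absolute"`, the
#' default) or `(pred - gt)^2` (variant `"squared"`).  Zero iff the
#' prediction equals the target.
#'
#' @param pred,gt arrays of identical shape.
#' @param variant `"absolute"` or `"squared"`.
#' @return non-negative scalar.
#' @export
lossFn <- function(pred, gt, variant = c("absolute", "squared")) {
  variant <- match.arg(variant)
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch in loss")
  d <- pred - gt
  if (variant == "absolute") mean(abs(d)) else mean(d^2)
}

loss_grad <- function(pred, gt, variant) {
  d <- pred - gt
  n <- length(d)
  if (variant == "absolute") sign(d) / n else 2 * d / n
}

#' Learning-rate schedule: linear warm-up then cosine annealing
#'
#' Epochs `0 .. warmup-1` ramp linearly from `baseLr / warmupEpochs` up to
#' `baseLr`; afterwards the rate follows
#' `baseLr * (1 + cos(pi (e - w) / (E - w))) / 2` down to ~0 at the final
#' epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < maxEpochs`.
#' @param config a [trainConfig()].
#' @return learning rate for that epoch.
#' @export
lrSchedule <- function(epoch, config) {
  w <- config$warmupEpochs
  E <- config$maxEpochs
  if (epoch < 0 || epoch >= E) stop("epoch out of range")
  if (epoch < w) return(config$baseLr * (epoch + 1) / w)
  config$baseLr * 0.5 * (1 + cos(pi * (epoch - w) / (E - w)))
}

#' One exponential-moving-average update of a weight set
#'
#' `ema <- decay * ema + (1 - decay) * weights`, per parameter.
#'
#' @param ema,weights flat named parameter lists with matching names.
#' @param decay EMA decay in (0, 1).
#' @return updated flat parameter list.
#' @export
emaUpdate <- function(ema, weights, decay) {
  if (!identical(names(ema), names(weights)))
    stop("mismatched parameter sets in EMA update")
  for (nm in names(ema)) {
    ema[[nm]] <- decay * ema[[nm]] + (1 - decay) * weights[[nm]]
  }
  ema
}

adamw_init <- function(params) {
  z <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = z, v = z, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(params, grads, state, lr, weightDecay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weightDecay * params[[nm]]
  }
  list(params = params, state = state)
}

# assemble one training batch: joint crop -> random patch -> pairwise
# percentile normalization (per patch or per image) -> joint flips ->
# 3-channel input
make_batch <- function(pairs, idx, config) {
  B <- length(idx)
  ps <- config$patchSize
  perImage <- identical(config$normScope, "image")
  x <- array(0, c(ps, ps, 3, B))
  tgt <- array(0, c(ps, ps, 1, B))
  for (b in seq_len(B)) {
    p <- pairs[[idx[b]]]
    if (perImage) p <- normalizePair(p$degraded, p$gt)
    cs <- min(config$cropSize, nrow(p$gt))
    deg <- centerCrop(p$degraded, cs)
    gt <- centerCrop(p$gt, cs)
    pt <- samplePatch(deg, gt, ps)
    np <- if (perImage) pt else normalizePair(pt$degraded, pt$gt)
    fl <- augmentFlip(np$degraded, np$gt)
    x[, , , b] <- replicateChannels(fl$degraded)
    tgt[, , 1, b] <- fl$gt
  }
  list(x = x, gt = tgt)
}

# deterministic centred validation patch, normalization scope as in
# training
make_val_batch <- function(pairs, idx, config) {
  B <- length(idx)
  ps <- config$patchSize
  perImage <- identical(config$normScope, "image")
  x <- array(0, c(ps, ps, 3, B))
  tgt <- array(0, c(ps, ps, 1, B))
  for (b in seq_len(B)) {
    p <- pairs[[idx[b]]]
    if (perImage) {
      np <- normalizePair(p$degraded, p$gt)
      np <- list(degraded = centerCrop(np$degraded, ps),
                 gt = centerCrop(np$gt, ps))
    } else {
      np <- normalizePair(centerCrop(p$degraded, ps), centerCrop(p$gt, ps))
    }
    x[, , , b] <- replicateChannels(np$degraded)
    tgt[, , 1, b] <- np$gt
  }
  list(x = x, gt = tgt)
}

#' Train an SD-ResNet model
#'
#' AdamW with decoupled weight decay, 5-epoch linear warm-up followed by
#' cosine annealing, a per-step exponential moving average of the weights
#' (used for validation inference), gated best-checkpointing (best raw and
#' EMA weights stored only after the gate epoch, judged by relative
#' validation-loss reduction) and early stopping after `patience`
#' consecutive epochs without improvement.  Encoder batch-normalization
#' layers run in evaluation mode throughout.
#'
#' @param model an `sdresnet` model from [buildModel()].
#' @param trainPairs,valPairs lists of pairs (each with `degraded` and
#'   `gt` matrices), e.g. the `pairs` of a [PATPairSet-class] subset.
#' @param config a [trainConfig()].
#' @param verbose print one line per epoch.
#' @return list with `model` (final raw weights), `ema` (final EMA flat
#'   weights), `checkpoint` (best state: `bestValLoss`, `bestRawWeights`,
#'   `bestEmaWeights`, `lastWeights`, `bestEpoch`, `gated`), and
#'   `history` (data frame: epoch, lr, train loss, EMA validation loss).
#' @export
trainModel <- function(model, trainPairs, valPairs, config = trainConfig(),
                       verbose = FALSE) {
  if (length(trainPairs) == 0 || length(valPairs) == 0)
    stop("training and validation sets must be non-empty")
  if (inherits(trainPairs, "PATPairSet")) trainPairs <- trainPairs@pairs
  if (inherits(valPairs, "PATPairSet")) valPairs <- valPairs@pairs

  params <- nnParams(model)
  ema <- params
  state <- adamw_init(params)
  bestVal <- Inf
  sinceImprove <- 0L
  ckpt <- list(bestValLoss = NA_real_, bestRawWeights = NULL,
               bestEmaWeights = NULL, bestBuffers = NULL,
               lastWeights = NULL, lastBuffers = NULL,
               bestEpoch = NA_integer_, gated = FALSE)
  hist <- vector("list", config$maxEpochs)

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(config$seed)

  nTr <- length(trainPairs)

  # one-shot calibration of the frozen encoder statistics from a
  # deterministic batch (stands in for pretrained running statistics;
  # they stay fixed for the whole run afterwards)
  calib <- make_val_batch(trainPairs,
                          seq_len(min(config$batchSize, nTr)), config)
  model$mods$encoder <- calibrate_frozen_bn(model$mods$encoder, calib$x)

  for (epoch in seq_len(config$maxEpochs)) {
    lr <- lrSchedule(epoch - 1L, config)
    ord <- sample.int(nTr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    for (bidx in batches) {
      bat <- make_batch(trainPairs, bidx, config)
      fw <- model_forward_train(model, bat$x)
      model <- fw$model
      l <- lossFn(fw$y, bat$gt, config$lossVariant)
      if (!is.finite(l))
        stop("non-finite training loss at epoch ", epoch,
             " (lr = ", signif(lr, 3), "); aborting")
      epochLoss <- epochLoss + l * length(bidx)
      gy <- loss_grad(fw$y, bat$gt, config$lossVariant)
      grads <- model_backward(model, fw$caches, gy)
      params <- nnParams(model)
      st <- adamw_step(params, grads, state, lr, config$weightDecay)
      state <- st$state
      model <- nnSetParams(model, st$params)
      ema <- emaUpdate(ema, st$params, config$emaDecay)
    }
    epochLoss <- epochLoss / nTr

    # validation with EMA weights (gradient-free, eval mode)
    emaModel <- nnSetParams(model, ema)
    valLoss <- 0
    vb <- split(seq_along(valPairs),
                ceiling(seq_along(valPairs) / config$batchSize))
    for (vidx in vb) {
      bat <- make_val_batch(valPairs, vidx, config)
      pred <- forwardModel(emaModel, bat$x, training = FALSE)
      valLoss <- valLoss + lossFn(pred, bat$gt, config$lossVariant) *
        length(vidx)
    }
    valLoss <- valLoss / length(valPairs)
    if (!is.finite(valLoss))
      stop("non-finite validation loss at epoch ", epoch, "; aborting")

    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = epochLoss,
                                val_loss_ema = valLoss)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.5f  val(ema) %.5f",
                      epoch, lr, epochLoss, valLoss))

    improved <- is.infinite(bestVal) ||
      (bestVal - valLoss) / bestVal > config$relTol
    if (improved) {
      bestVal <- valLoss
      sinceImprove <- 0L
      if (epoch > config$gateEpoch) {
        ckpt$bestValLoss <- valLoss
        ckpt$bestRawWeights <- nnParams(model)
        ckpt$bestEmaWeights <- ema
        ckpt$bestBuffers <- nnBuffers(model)
        ckpt$bestEpoch <- epoch
        ckpt$gated <- TRUE
      }
    } else {
      sinceImprove <- sinceImprove + 1L
    }
    if (sinceImprove >= config$patience) break
  }

  ckpt$lastWeights <- nnParams(model)
  ckpt$lastBuffers <- nnBuffers(model)
  if (!ckpt$gated) {
    # no improvement ever occurred past the gate; fall back to last
    ckpt$bestRawWeights <- ckpt$lastWeights
    ckpt$bestEmaWeights <- ema
    ckpt$bestBuffers <- ckpt$lastBuffers
    ckpt$bestEpoch <- NA_integer_
    ckpt$bestValLoss <- bestVal
  }
  list(model = model, ema = ema, checkpoint = ckpt,
       history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
}
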
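# Paired degraded / ground-truth dataset construction and the training
# preprocessing: percentile normalization, cropping, patch sampling,
# flip augmentation, channel replication and phantom-level splitting.

#' Build a paired degraded / ground-truth dataset
#'
#' For every phantom the RF data are simulated exactly once.  The
#' noise-free reconstruction at the true scanning radius is the ground
#' truth; for each radius of the mismatch grid, white noise is added to
#' the RF record and the noisy data are reconstructed with that (biased)
#' radius to form the degraded member of the pair.
#'
#' @param specs list of [PhantomSpec-class] objects (one per phantom).
#' @param acq acquisition configuration, as returned by
#'   [deskAcquisition()] or [paperAcquisition()].
#' @param seed master seed; all noise seeds are derived from it.
#' @param verbose print progress.
#' @return A [PATPairSet-class] with `length(specs) * length(acq$radii)`
#'   pairs.
#' @export
buildDataset <- function(specs, acq = deskAcquisition(), seed = 1L,
                         verbose = FALSE) {
  pairs <- list()
  for (i in seq_along(specs)) {
    ph <- generatePhantom(specs[[i]], dx = acq$simDx)
    rf <- simulateRF(ph, acq$medium, acq$ring, nT = acq$nT, fs = acq$fs,
                     pmlSize = acq$pmlSize)
    rf <- applyTransducerBand(rf, acq$ring@f0, acq$ring@fracBw)
    pairs <- c(pairs, pairs_from_rf(rf, i, acq, seed))
    if (verbose) message(sprintf("phantom %d/%d done", i, length(specs)))
  }
  new("PATPairSet", pairs = pairs, radii = acq$radii,
      meta = list(seed = seed, nPhantoms = length(specs),
                  ringRadius = acq$ring@radius, fs = acq$fs))
}

# one ground truth (true radius, noise-free) plus one degraded image per
# radius of the mismatch grid, all from a single band-limited RF record
pairs_from_rf <- function(rf, phantomId, acq, seed) {
  angles <- sensorAngles(acq$ring)
  gt <- dasReconstruct(rf, angles, dasConfig(acq$ring@radius, acq$cAssumed),
                       acq$recon)
  lapply(seq_along(acq$radii), function(j) {
    nseed <- (seed * 97L + phantomId * 1009L + j * 31L) %% 2147483647L
    noisy <- addWhiteNoise(rf, acq$noiseDb, seed = nseed)
    deg <- dasReconstruct(noisy, angles,
                          dasConfig(acq$radii[j], acq$cAssumed), acq$recon)
    list(degraded = deg, gt = gt, phantomId = phantomId,
         radiusUsed = acq$radii[j], noiseSeed = nseed)
  })
}

#' Pairwise percentile normalization
#'
#' The 0.5-99.5 percentile range of the ground-truth image defines a
#' shared normalization interval; both members of the pair are mapped by
#' `x -> (x - lo) / (hi - lo)` and clipped to `[0, 1]`.  A constant ground
#' truth maps both images to zero and sets `constant = TRUE`.
#'
#' @param degraded,gt numeric matrices of identical shape.
#' @param probs the two percentiles defining the interval.
#' @return list with `degraded`, `gt`, `interval = c(lo, hi)`, `constant`.
#' @export
normalizePair <- function(degraded, gt, probs = c(0.005, 0.995)) {
  if (!identical(dim(degraded), dim(gt))) stop("shape mismatch")
  q <- stats::quantile(gt, probs = probs, names = FALSE)
  lo <- q[1]; hi <- q[2]
  if (hi <= lo) {
    z <- matrix(0, nrow(gt), ncol(gt))
    return(list(degraded = z, gt = z, interval = c(lo, hi), constant = TRUE))
  }
  clip01 <- function(x) pmin(pmax((x - lo) / (hi - lo), 0), 1)
  list(degraded = clip01(degraded), gt = clip01(gt),
       interval = c(lo, hi), constant = FALSE)
}

#' Centre-crop an image
#'
#' @param img numeric matrix.
#' @param size crop side length (<= both image sides).
#' @return `size x size` centred window.
#' @export
centerCrop <- function(img, size) {
  size <- as.integer(size)
  if (size > nrow(img) || size > ncol(img)) stop("crop larger than image")
  oi <- floor((nrow(img) - size) / 2)
  oj <- floor((ncol(img) - size) / 2)
  img[oi + seq_len(size), oj + seq_len(size), drop = FALSE]
}

#' Sample a random patch jointly from a pair
#'
#' The same uniformly random window is applied to both members.
#'
#' @param degraded,gt numeric matrices of identical shape.
#' @param patch patch side length.
#' @return list with the two patches and the (1-based) `corner`.
#' @export
samplePatch <- function(degraded, gt, patch) {
  if (!identical(dim(degraded), dim(gt))) stop("shape mismatch")
  patch <- as.integer(patch)
  if (patch > nrow(gt) || patch > ncol(gt)) stop("patch larger than image")
  ci <- sample.int(nrow(gt) - patch + 1L, 1L)
  cj <- sample.int(ncol(gt) - patch + 1L, 1L)
  ii <- ci + seq_len(patch) - 1L
  jj <- cj + seq_len(patch) - 1L
  list(degraded = degraded[ii, jj, drop = FALSE],
       gt = gt[ii, jj, drop = FALSE], corner = c(ci, cj))
}

#' Joint random horizontal / vertical flips
#'
#' Each axis is flipped with probability 0.5; the same flip is applied to
#' both members of the pair.
#'
#' @param degraded,gt numeric matrices of identical shape.
#' @return list with flipped `degraded` and `gt` and the flips applied.
#' @export
augmentFlip <- function(degraded, gt) {
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  if (fh) {
    degraded <- degraded[rev(seq_len(nrow(degraded))), , drop = FALSE]
    gt <- gt[rev(seq_len(nrow(gt))), , drop = FALSE]
  }
  if (fv) {
    degraded <- degraded[, rev(seq_len(ncol(degraded))), drop = FALSE]
    gt <- gt[, rev(seq_len(ncol(gt))), drop = FALSE]
  }
  list(degraded = degraded, gt = gt, flips = c(horizontal = fh, vertical = fv))
}

#' Replicate a grayscale patch into three identical channels
#'
#' @param patch numeric matrix.
#' @return `H x W x 3` array with all channels equal to the input.
#' @export
replicateChannels <- function(patch) {
  array(rep(as.numeric(patch), 3), dim = c(nrow(patch), ncol(patch), 3))
}

#' Phantom-level train / validation / test split
#'
#' Splitting is by phantom, so all scanning-radius conditions of one
#' phantom stay in one subset and no phantom leaks across subsets.
#' Subset sizes are `floor(n * ratio)` for train and validation with the
#' remainder assigned to test.
#'
#' @param nPhantoms number of phantoms.
#' @param ratios train/validation/test ratios (positive, summing to 1).
#' @param seed RNG seed for the permutation.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @examples
#' lengths(splitDataset(480L))  # 336 / 96 / 48
#' @export
splitDataset <- function(nPhantoms, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three positive numbers summing to 1")
  nTr <- floor(nPhantoms * ratios[1])
  nVa <- floor(nPhantoms * ratios[2])
  nTe <- nPhantoms - nTr - nVa
  if (nTr < 1 || nVa < 1 || nTe < 1)
    stop("too few phantoms for a non-empty split")
  perm <- with_seed(seed, sample.int(nPhantoms))
  list(train = sort(perm[seq_len(nTr)]),
       val = sort(perm[nTr + seq_len(nVa)]),
       test = sort(perm[nTr + nVa + seq_len(nTe)]))
}

#' Subset a PATPairSet by phantom ids
#'
#' @param pairset a [PATPairSet-class].
#' @param phantomIds phantom ids to keep.
#' @return A [PATPairSet-class] with only the selected phantoms' pairs.
#' @export
subsetByPhantom <- function(pairset, phantomIds) {
  stopifnot(is(pairset, "PATPairSet"))
  keep <- vapply(pairset@pairs, function(p) p$phantomId %in% phantomIds,
                 logical(1))
  new("PATPairSet", pairs = pairset@pairs[keep], radii = pairset@radii,
      meta = pairset@meta)
}

#' Save / load a PATPairSet
#'
#' Serializes the pair set (RDS container) together with a CSV index of
#' pairs and a YAML manifest of the build metadata.
#'
#' @param pairset a [PATPairSet-class].
#' @param path output path (`.rds`); the index and manifest are written
#'   alongside with `.csv` / `.yml` extensions.
#' @return `path`, invisibly.
#' @export
saveTrainingSet <- function(pairset, path) {
  stopifnot(is(pairset, "PATPairSet"))
  saveRDS(pairset, path)
  idx <- data.frame(
    pair = seq_along(pairset@pairs),
    phantomId = vapply(pairset@pairs, `[[`, numeric(1), "phantomId"),
    radiusUsed = vapply(pairset@pairs, `[[`, numeric(1), "radiusUsed"),
    noiseSeed = vapply(pairset@pairs, `[[`, numeric(1), "noiseSeed"))
  utils::write.csv(idx, sub("\\.rds$", ".csv", path), row.names = FALSE)
  yaml::write_yaml(pairset@meta, sub("\\.rds$", ".yml", path))
  invisible(path)
}

#' @rdname saveTrainingSet
#' @export
readTrainingSet <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "PATPairSet"))
  obj
}
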
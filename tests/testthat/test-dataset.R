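test_that("dataset build simulates once per phantom and counts pairs", {
  acq <- tiny_acq()
  specs <- lapply(1:2, function(i)
    phantomSpec(nStructures = 2L, sizeRange = acq$phantomSize,
                canvas = acq$simN, seed = i,
                placementFraction = acq$placementFraction))
  calls <- 0L
  real <- sdresnet::simulateRF
  local_mocked_bindings(
    simulateRF = function(...) { calls <<- calls + 1L; real(...) },
    .package = "sdresnet")
  ds <- buildDataset(specs, acq, seed = 3L)
  expect_equal(calls, 2L)                           # RF simulated once each
  expect_length(ds, 2L * length(acq$radii))         # phantoms x radii
  perPh <- table(vapply(ds@pairs, `[[`, numeric(1), "phantomId"))
  expect_true(all(perPh == length(acq$radii)))
  # ground truth: identical across radii of a phantom, noise-free
  expect_identical(ds[[1]]$gt, ds[[2]]$gt)
  # degraded members differ between radii (different bias + noise)
  expect_false(identical(ds[[1]]$degraded, ds[[2]]$degraded))
})

test_that("dataset build is deterministic under a fixed master seed", {
  acq <- tiny_acq()
  acq$radii <- acq$radii[1:2]
  specs <- list(phantomSpec(nStructures = 2L, sizeRange = acq$phantomSize,
                            canvas = acq$simN, seed = 4L,
                            placementFraction = acq$placementFraction))
  d1 <- buildDataset(specs, acq, seed = 9L)
  d2 <- buildDataset(specs, acq, seed = 9L)
  expect_identical(d1@pairs, d2@pairs)
})

test_that("pairwise normalization uses the ground-truth interval", {
  # linear ramp spanning [0, 1]: percentiles land at ~0.005 / ~0.995
  gt <- matrix(seq(0, 1, length.out = 10000), 100)
  np <- normalizePair(gt * 0.5, gt)
  expect_equal(np$interval[1], 0.005, tolerance = 1e-3)
  expect_equal(np$interval[2], 0.995, tolerance = 1e-3)
  expect_equal(range(np$gt), c(0, 1))

  # probe: an outlier in the degraded member must not move the interval
  deg <- gt * 0.5; deg[1] <- 100
  np2 <- normalizePair(deg, gt)
  expect_equal(np2$interval, np$interval)
  expect_equal(max(np2$degraded), 1)   # clipped into [0, 1]

  npc <- normalizePair(matrix(1:4, 2), matrix(5, 2, 2))
  expect_true(npc$constant)
  expect_true(all(npc$degraded == 0) && all(npc$gt == 0))
})

test_that("centre crop uses exact offsets and composes idempotently", {
  img <- matrix(seq_len(512 * 512), 512)
  cr <- centerCrop(img, 400L)
  expect_equal(cr, img[56 + 1:400, 56 + 1:400])
  expect_identical(centerCrop(img, 512L), img)
  expect_identical(centerCrop(centerCrop(img, 448L), 400L),
                   centerCrop(img, 400L))
  expect_error(centerCrop(img, 600L), "larger")
})

test_that("patch sampling applies one uniform window to both members", {
  # coordinate-encoded probe: identical windows iff patches stay equal
  cood <- matrix(seq_len(40 * 40), 40)
  set.seed(2)
  for (k in 1:20) {
    pt <- samplePatch(cood, cood, 17L)
    expect_identical(pt$degraded, pt$gt)
  }
  expect_error(samplePatch(cood, cood, 41L), "larger")

  # corner distribution uniform over the admissible range (chi-square)
  img <- matrix(0, 12, 12)
  set.seed(3)
  corners <- t(replicate(10000, samplePatch(img, img, 5L)$corner))
  expect_true(all(corners >= 1 & corners <= 8))
  for (ax in 1:2) {
    tab <- tabulate(corners[, ax], 8)
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("flips are joint, involutive and balanced", {
  a <- matrix(seq_len(36), 6)
  set.seed(4)
  fl <- augmentFlip(a, a)
  expect_identical(fl$degraded, fl$gt)       # same flip on both members
  # double flip restores the original
  flip_h <- function(m) m[6:1, ]
  expect_identical(flip_h(flip_h(a)), a)
  rates <- rowMeans(replicate(10000, augmentFlip(a, a)$flips))
  expect_equal(unname(rates), c(0.5, 0.5), tolerance = 0.02)
})

test_that("channel replication produces three identical channels", {
  p <- matrix(stats::runif(25), 5)
  r <- replicateChannels(p)
  expect_equal(dim(r), c(5L, 5L, 3L))
  expect_identical(r[, , 1], r[, , 2])
  expect_identical(r[, , 2], r[, , 3])
  expect_equal(apply(r, c(1, 2), mean), p)
  expect_true(all(replicateChannels(matrix(0, 3, 3)) == 0))
})

test_that("phantom-level splitting is exact, disjoint and reproducible", {
  sp <- splitDataset(480L, seed = 1L)
  expect_equal(lengths(sp), c(train = 336L, val = 96L, test = 48L))
  sp10 <- splitDataset(10L, seed = 2L)
  expect_equal(lengths(sp10), c(train = 7L, val = 2L, test = 1L))
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  expect_setequal(unlist(sp), 1:480)
  expect_identical(splitDataset(40L, seed = 5L), splitDataset(40L, seed = 5L))
  expect_error(splitDataset(3L, ratios = c(0.98, 0.01, 0.01)), "non-empty")
  expect_error(splitDataset(10L, ratios = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("pair sets round-trip through disk with index and manifest", {
  ps <- stub_pairset()
  path <- file.path(tempdir(), "pairs.rds")
  saveTrainingSet(ps, path)
  expect_true(file.exists(sub("rds$", "csv", path)))
  expect_true(file.exists(sub("rds$", "yml", path)))
  back <- readTrainingSet(path)
  expect_identical(back@pairs, ps@pairs)
  idx <- utils::read.csv(sub("rds$", "csv", path))
  expect_equal(nrow(idx), length(ps))
  # phantom-level subsetting keeps whole phantoms
  sub1 <- subsetByPhantom(ps, 1)
  expect_true(all(vapply(sub1@pairs, `[[`, numeric(1), "phantomId") == 1))
})
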
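test_that("solver matches the closed-form spectral propagator", {
  # independent oracle: on a periodic lossless domain the solution is
  # p(t) = IFFT(cos(c|k|t) FFT(p0)); compare at early times before the
  # absorbing boundary can influence the sensor
  n <- 64L; dx <- 2e-4; c0 <- 1500
  xs <- ((1:n) - (n + 1) / 2) * dx
  p0 <- exp(-(outer(xs^2, xs^2, "+")) / (2 * (3 * dx)^2))
  ph <- pressureMap(p0 / max(p0), dx = dx)
  ring <- sensorRing(4L, radius = 4e-3, f0 = 2e6)
  sino <- simulateRF(ph, medium(), ring, nT = 110L, fs = 25e6,
                     pmlSize = 10L, smoothP0 = FALSE)
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * dx)
  kk <- 2 * pi * sqrt(outer(f^2, f^2, "+"))
  P <- stats::fft(ph@values)
  half <- (n - 1) / 2
  # bilinear sample of the oracle field at the sensor position
  sample_at <- function(pt, xy) {
    fi <- xy[1] / dx + half + 1; fj <- xy[2] / dx + half + 1
    i0 <- floor(fi); j0 <- floor(fj); a <- fi - i0; b <- fj - j0
    (1 - a) * (1 - b) * pt[i0, j0] + a * (1 - b) * pt[i0 + 1, j0] +
      (1 - a) * b * pt[i0, j0 + 1] + a * b * pt[i0 + 1, j0 + 1]
  }
  oracle <- vapply(seq_len(110), function(i) {
    tt <- (i - 1) / 25e6
    pt <- Re(stats::fft(P * cos(c0 * kk * tt), inverse = TRUE)) / n^2
    sample_at(pt, c(4e-3, 0))
  }, numeric(1))
  got <- sinoData(sino)[1, ]
  expect_lt(max(abs(got - oracle)), 0.005 * max(abs(oracle)))
})

test_that("a centred source gives identical channels and zero input gives zero", {
  acq <- tiny_acq()
  n <- acq$simN
  xs <- ((1:n) - (n + 1) / 2) * acq$simDx
  blob <- exp(-outer(xs^2, xs^2, "+") / (2 * (2 * acq$simDx)^2))
  ph <- pressureMap(blob / max(blob), dx = acq$simDx)
  sino <- simulateRF(ph, acq$medium, acq$ring, nT = 200L, fs = acq$fs,
                     pmlSize = acq$pmlSize)
  d <- sinoData(sino)
  # axis-aligned sensors sit on exact grid symmetries ...
  for (s in c(3, 5, 7)) expect_lt(max(abs(d[s, ] - d[1, ])), 1e-9 * max(abs(d)))
  # ... diagonal ones see the slightly asymmetric staggered PML ...
  for (s in c(4, 6, 8)) expect_lt(max(abs(d[s, ] - d[2, ])), 1e-3 * max(abs(d)))
  # ... and all channels agree within the bilinear interpolation tolerance
  for (s in 2:nrow(d)) expect_lt(max(abs(d[s, ] - d[1, ])), 0.02 * max(abs(d)))

  z <- pressureMap(matrix(0, acq$simN, acq$simN), dx = acq$simDx)
  expect_true(all(sinoData(simulateRF(z, acq$medium, acq$ring, nT = 50L,
                                      fs = acq$fs, pmlSize = acq$pmlSize)) == 0))
})

test_that("the solver is linear in the initial pressure", {
  acq <- tiny_acq()
  set.seed(8)
  p1 <- disk_map(acq$simN, acq$simDx, 1e-3, 0, 5e-4)
  p2 <- disk_map(acq$simN, acq$simDx, -0.5e-3, 1e-3, 4e-4)
  mix <- pressureMap(pmin(0.4 * p1@values + 0.3 * p2@values, 1),
                     dx = acq$simDx)
  run <- function(p) sinoData(simulateRF(p, acq$medium, acq$ring, nT = 200L,
                                         fs = acq$fs, pmlSize = acq$pmlSize))
  lhs <- run(mix)
  rhs <- 0.4 * run(p1) + 0.3 * run(p2)
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(rhs)))
})

test_that("rotating the source by 90 degrees cyclically shifts the channels", {
  acq <- tiny_acq()  # 8 sensors: a quarter turn is a shift by 2 channels
  ph <- disk_map(acq$simN, acq$simDx, 1.2e-3, 0.6e-3, 5e-4)
  rot <- pressureMap(t(ph@values)[acq$simN:1, ], dx = acq$simDx)
  d1 <- sinoData(simulateRF(ph, acq$medium, acq$ring, nT = 200L, fs = acq$fs,
                            pmlSize = acq$pmlSize))
  d2 <- sinoData(simulateRF(rot, acq$medium, acq$ring, nT = 200L, fs = acq$fs,
                            pmlSize = acq$pmlSize))
  shifted <- d1[c(7, 8, 1:6), ]  # sensor k of rotated scene = sensor k-2
  # staggered-grid derivatives leave a small O(dx^2) asymmetry
  expect_lt(max(abs(d2 - shifted)), 1e-3 * max(abs(d1)))
})

test_that("disk leading edges arrive at the geometric time", {
  acq <- tiny_acq()
  ph <- disk_map(acq$simN, acq$simDx, 1e-3, 0.5e-3, 8e-4)
  sino <- simulateRF(ph, acq$medium, acq$ring, nT = 300L, fs = acq$fs,
                     pmlSize = acq$pmlSize)
  pos <- sensorPositions(acq$ring)
  for (s in c(1L, 4L)) {
    d <- sqrt(sum((pos[s, ] - c(1e-3, 0.5e-3))^2))
    tTrue <- (d - 8e-4) / acq$medium@c
    expect_lt(abs(leadingEdgeTime(sino, s) - tTrue), 2 / acq$fs)
  }
  # quiet before the earliest geometric arrival
  d1 <- sqrt(sum((pos[1, ] - c(1e-3, 0.5e-3))^2))
  cut <- floor(((d1 - 8e-4) / acq$medium@c - 0.4e-6) * acq$fs)
  ch <- sinoData(sino)[1, ]
  expect_lt(max(abs(ch[1:cut])), 0.01 * max(abs(ch)))
})

test_that("geometry and stability guards reject bad configurations", {
  acq <- tiny_acq()
  ph <- disk_map(acq$simN, acq$simDx, 0, 0, 5e-4)
  big <- sensorRing(8L, radius = 6e-3, f0 = 2e6)  # outside 64 x 0.2 mm grid
  expect_error(simulateRF(ph, acq$medium, big, nT = 50L, fs = acq$fs),
               "does not fit")
  expect_error(simulateRF(ph, acq$medium, acq$ring, nT = 50L, fs = 1e6,
                          pmlSize = acq$pmlSize, cfl = 2), "unstable")
})

test_that("the transducer band-pass has the specified response", {
  fs <- 25e6; nt <- 2000L; f0 <- 2e6; bw <- 0.7
  tt <- (0:(nt - 1)) / fs
  mk <- function(f) sinogram(matrix(sin(2 * pi * f * tt), 1), fs = fs)
  amp <- function(s) max(abs(sinoData(s)[1, 500:1500]))  # avoid edge taper
  expect_equal(amp(applyTransducerBand(mk(f0), f0, bw)), 1, tolerance = 0.01)
  lo <- amp(applyTransducerBand(mk(f0 * (1 - bw / 2)), f0, bw))
  hi <- amp(applyTransducerBand(mk(f0 * (1 + bw / 2)), f0, bw))
  expect_equal(lo, 0.5, tolerance = 0.02)
  expect_equal(hi, 0.5, tolerance = 0.02)
  dc <- applyTransducerBand(sinogram(matrix(1, 1, nt), fs = fs), f0, bw)
  expect_lt(max(abs(sinoData(dc))), 1e-6)
  expect_error(applyTransducerBand(mk(f0), f0 = 13e6, bw), "below fs / 2")
})

test_that("white noise follows the peak-referenced dB convention", {
  set.seed(5)
  base <- sinogram(matrix(rnorm(4 * 250000), 4), fs = 25e6)
  peak <- max(abs(sinoData(base)))
  noisy <- addWhiteNoise(base, -30, seed = 99L)
  resid <- sinoData(noisy) - sinoData(base)
  expect_equal(stats::sd(resid), 10^(-30 / 20) * peak, tolerance = 0.01)
  expect_equal(10^(-30 / 20), 0.03162, tolerance = 1e-4)
  # zero level: sigma equals the peak
  noisy0 <- addWhiteNoise(base, 0, seed = 1L)
  expect_equal(stats::sd(sinoData(noisy0) - sinoData(base)), peak,
               tolerance = 0.01)
  # reproducible under the same seed
  expect_identical(sinoData(addWhiteNoise(base, -30, seed = 7L)),
                   sinoData(addWhiteNoise(base, -30, seed = 7L)))
  z <- sinogram(matrix(0, 2, 10), fs = 1e6)
  expect_warning(zn <- addWhiteNoise(z, -30), "all-zero")
  expect_identical(sinoData(zn), sinoData(z))
})
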
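# Forward simulation of ring-array photoacoustic acquisition: k-space
# pseudospectral propagation of the initial pressure, transducer
# band-limiting, and calibrated additive white noise.

#' Simulate RF signals at a sensor ring
#'
#' Solves the lossless homogeneous 2D wave equation as an initial-value
#' problem (\eqn{p(0) = p_0}, \eqn{\partial p/\partial t(0) = 0}) with a
#' first-order coupled k-space pseudospectral scheme (k-space dispersion
#' correction, staggered grids, split-field perfectly matched layer) and
#' records the pressure at the sensor positions by bilinear interpolation.
#'
#' The internal time step honours both the requested sampling interval and
#' the target CFL number; when `1/fs` is larger than the CFL-limited step
#' the solver substeps and records every m-th sample.
#'
#' @param p0 a [PressureMap-class] (square) used as the initial pressure.
#' @param med a [Medium-class].
#' @param ring a [SensorRing-class]; must lie inside the domain with a
#'   margin for the absorbing boundary layer.
#' @param nT number of recorded time samples.
#' @param fs output sampling rate (Hz).
#' @param pmlSize absorbing boundary thickness in grid points.
#' @param pmlAlpha absorption strength of the boundary layer.
#' @param cfl target CFL number for the internal time step.
#' @param smoothP0 spectrally smooth the initial pressure (Blackman taper)
#'   to limit staircasing-induced ringing; on by default.
#' @return A [Sinogram-class] with `t0 = 0`.
#' @export
simulateRF <- function(p0, med, ring, nT = 1024L, fs = 25e6, pmlSize = 14L,
                       pmlAlpha = 2, cfl = 0.3, smoothP0 = TRUE) {
  stopifnot(is(p0, "PressureMap"), is(med, "Medium"), is(ring, "SensorRing"))
  v <- p0@values
  n <- nrow(v)
  if (ncol(v) != n) stop("simulation grid must be square; use padToGrid()")
  dx <- p0@dx
  halfw <- (n / 2 - pmlSize - 2) * dx
  if (ring@radius + max(abs(ring@center)) > halfw)
    stop("sensor ring does not fit inside the computational domain ",
         "(radius + PML margin exceeds the grid)")
  dtMax <- cfl * dx / med@c
  m <- max(1L, as.integer(ceiling((1 / fs) / dtMax - 1e-12)))
  dt <- 1 / (fs * m)
  if (med@c * dt / dx >= 1) stop("unstable internal time step")
  sxy <- sensorPositions(ring)
  rf <- .kspace_solve_2d(v, dx, med@c, med@rho, dt, as.integer(nT),
                         m, sxy, as.integer(pmlSize), pmlAlpha, smoothP0)
  sinogram(rf, fs = fs, t0 = 0)
}

#' Apply the transducer band-pass response
#'
#' Filters every channel with a zero-phase Gaussian band-pass whose -6 dB
#' fractional bandwidth about the centre frequency matches the transducer
#' specification.  The DC component is removed.
#'
#' @param sino a [Sinogram-class].
#' @param f0 centre frequency (Hz); must be below `fs / 2`.
#' @param fracBw fractional -6 dB bandwidth (e.g. 0.7 for 70%).
#' @return A filtered [Sinogram-class].
#' @export
applyTransducerBand <- function(sino, f0, fracBw) {
  stopifnot(is(sino, "Sinogram"))
  fs <- sino@fs
  if (f0 >= fs / 2) stop("centre frequency must be below fs / 2")
  nt <- ncol(sino@data)
  f <- (seq_len(nt) - 1) / nt * fs
  f <- ifelse(f > fs / 2, f - fs, f)          # signed FFT frequencies
  # Gaussian magnitude response, -6 dB (amplitude 1/2) at f0 * (1 +- bw/2)
  sigma <- (fracBw * f0 / 2) / sqrt(2 * log(2))
  g <- exp(-(abs(f) - f0)^2 / (2 * sigma^2))
  g[1] <- 0                                   # kill DC
  sp <- stats::mvfft(t(sino@data))            # time along rows
  out <- Re(stats::mvfft(sp * g, inverse = TRUE)) / nt
  sinogram(t(out), fs = fs, t0 = sino@t0)
}

#' Add calibrated white noise to a sinogram
#'
#' Additive Gaussian noise whose standard deviation is
#' `10^(levelDb / 20) * max(abs(data))` over the whole sinogram (peak
#' amplitude reference, amplitude dB convention).
#'
#' @param sino a [Sinogram-class].
#' @param levelDb noise level in dB relative to the sinogram peak
#'   (e.g. -30).
#' @param seed RNG seed for reproducibility.
#' @return A noisy [Sinogram-class]; an all-zero input is returned
#'   unchanged with a warning.
#' @export
addWhiteNoise <- function(sino, levelDb = -30, seed = 1L) {
  stopifnot(is(sino, "Sinogram"))
  peak <- max(abs(sino@data))
  if (peak == 0) {
    warning("all-zero sinogram: noise scale undefined, returned unchanged")
    return(sino)
  }
  sigma <- 10^(levelDb / 20) * peak
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(sino@data), 0, sigma), nrow(sino@data)))
  sinogram(sino@data + noise, fs = sino@fs, t0 = sino@t0)
}

#' Leading-edge arrival time of a sinogram channel
#'
#' Time of the first sample whose magnitude exceeds `frac` of the channel
#' peak.  With the default half-peak threshold the estimate is robust to
#' the symmetric onset smearing introduced by the band limit of the grid
#' (a symmetric smoothing kernel preserves the half-height crossing of a
#' step-like onset).
#'
#' @param sino a [Sinogram-class].
#' @param channel channel (sensor) index.
#' @param frac threshold as a fraction of the channel peak magnitude.
#' @return arrival time in seconds (relative to `t0`).
#' @export
leadingEdgeTime <- function(sino, channel, frac = 0.5) {
  stopifnot(is(sino, "Sinogram"))
  ch <- sino@data[channel, ]
  pk <- max(abs(ch))
  if (pk == 0) stop("all-zero channel has no arrival")
  sino@t0 + (which(abs(ch) > frac * pk)[1] - 1) / sino@fs
}

#' Desk-scale acquisition configuration
#'
#' A self-contained configuration small enough for CPU experiments:
#' 128 x 128 simulation grid at 0.2 mm, a 9 mm ring of 32 sensors with a
#' 2.5 MHz / 70% bandwidth transducer (the grid supports content up to
#' 3.75 MHz), 25 MHz sampling with 1024 samples, -30 dB RF noise, an
#' 11-radius mismatch grid of 7.5-10.5 mm in 0.3 mm steps, and a 96 x 96
#' reconstruction grid at 0.1 mm.  See the methods vignette for the
#' rationale behind each value.
#'
#' @return A named list with elements `medium`, `ring`, `simN`, `simDx`,
#'   `nT`, `fs`, `pmlSize`, `noiseDb`, `radii`, `recon`, `cAssumed`,
#'   `placementFraction`, `phantomSize`.
#' @export
deskAcquisition <- function() {
  ring <- sensorRing(32L, radius = 9e-3, f0 = 2.5e6, fracBw = 0.7)
  list(
    medium = medium(c = 1500, rho = 1000, alpha0 = 0.5),
    ring = ring,
    simN = 128L, simDx = 2e-4,
    nT = 1024L, fs = 25e6, pmlSize = 14L,
    noiseDb = -30,
    radii = radiusGrid(7.5e-3, 10.5e-3, 0.3e-3),
    recon = reconGrid(96L, dx = 1e-4),
    cAssumed = 1500,
    placementFraction = 0.53,   # centres within 3.4 mm of the ring centre
    phantomSize = c(2, 6)       # structure sizes in simulation pixels
  )
}

#' Full-scale acquisition configuration
#'
#' The full-resolution configuration: 768 x 768 grid at 40 um, 256 sensors
#' on a 24.8 mm ring, 5 MHz / 70% bandwidth transducer, 50 MHz sampling
#' with 4500 samples, -30 dB noise, radius grid 23.8-25.8 mm in 0.2 mm
#' steps, 512 x 512 reconstruction at 40 um.  Provided behind the same
#' interface as [deskAcquisition()]; simulation at this scale is
#' CPU-expensive and is not exercised by the test suite.
#'
#' @return A named list, same shape as [deskAcquisition()].
#' @export
paperAcquisition <- function() {
  ring <- sensorRing(256L, radius = 24.8e-3, f0 = 5e6, fracBw = 0.7)
  list(
    medium = medium(c = 1500, rho = 1000, alpha0 = 0.5),
    ring = ring,
    simN = 768L, simDx = 4e-5,
    nT = 4500L, fs = 50e6, pmlSize = 20L,
    noiseDb = -30,
    radii = radiusGrid(23.8e-3, 25.8e-3, 0.2e-3),
    recon = reconGrid(512L, dx = 4e-5),
    cAssumed = 1500,
    placementFraction = 0.53,
    phantomSize = c(4, 40)
  )
}
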
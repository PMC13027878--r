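# Delay-and-sum reconstruction parameterized by an assumed scanning
# radius, and the biased-radius sweep that produces degraded images.

#' Time of flight from an assumed sensor position to a pixel
#'
#' Euclidean distance from the sensor (placed at `radiusAssumed` along
#' `sensorAngle` from the ring centre) to the pixel, divided by the
#' assumed speed of sound.
#'
#' @param sensorAngle sensor angle in radians.
#' @param pixel pixel position `(x, y)` in metres (ring centre at origin).
#' @param config a [DASConfig-class].
#' @return time of flight in seconds (vectorized over `sensorAngle`).
#' @export
timeOfFlight <- function(sensorAngle, pixel, config) {
  stopifnot(is(config, "DASConfig"))
  sx <- config@radiusAssumed * cos(sensorAngle)
  sy <- config@radiusAssumed * sin(sensorAngle)
  sqrt((sx - pixel[1])^2 + (sy - pixel[2])^2) / config@cAssumed
}

#' Inclusive evenly spaced radius grid
#'
#' Generated with integer indexing (`rMin + step * 0:k`) so consecutive
#' spacings equal `step` exactly, with no floating-point drift.
#'
#' @param rMin,rMax grid limits in metres (`rMin <= rMax`).
#' @param step positive increment in metres.
#' @return ascending numeric vector of radii, including `rMin` and
#'   (within floating tolerance) `rMax`.
#' @examples
#' length(radiusGrid(23.8e-3, 25.8e-3, 0.2e-3))  # 11
#' @export
radiusGrid <- function(rMin, rMax, step) {
  if (step <= 0) stop("step must be positive")
  if (rMin > rMax) stop("rMin must be <= rMax")
  k <- floor((rMax - rMin) / step + 1e-9)
  rMin + step * (0:k)
}

#' Delay-and-sum image reconstruction
#'
#' For each pixel, sums every channel sampled at that pixel's time of
#' flight under the assumed radius and sound speed:
#' \eqn{\hat p_0(Q) = \sum_i p_i(t_i(Q))}.  Delays outside the recorded
#' window contribute zero.  No apodization or weighting is applied.
#'
#' @param sino a [Sinogram-class].
#' @param ringAngles sensor angles (radians); length must equal the number
#'   of sinogram channels.
#' @param config a [DASConfig-class] (assumed radius/speed, interpolation).
#' @param grid a [ReconGrid-class], centred on the ring centre.
#' @return numeric `nx x ny` image matrix (x along rows).
#' @export
dasReconstruct <- function(sino, ringAngles, config, grid) {
  stopifnot(is(sino, "Sinogram"), is(config, "DASConfig"),
            is(grid, "ReconGrid"))
  dat <- sino@data
  if (length(ringAngles) != nrow(dat))
    stop("ringAngles length must match the sinogram channel count")
  nt <- ncol(dat)
  px <- (seq_len(grid@nx) - (grid@nx + 1) / 2) * grid@dx
  py <- (seq_len(grid@ny) - (grid@ny + 1) / 2) * grid@dy
  img <- matrix(0, grid@nx, grid@ny)
  onesy <- rep(1, grid@ny)
  onesx <- rep(1, grid@nx)
  for (i in seq_along(ringAngles)) {
    sx <- config@radiusAssumed * cos(ringAngles[i])
    sy <- config@radiusAssumed * sin(ringAngles[i])
    d2 <- outer((px - sx)^2, onesy) + outer(onesx, (py - sy)^2)
    idx <- (sqrt(d2) / config@cAssumed - sino@t0) * sino@fs + 1
    ch <- dat[i, ]
    if (config@interpolation == "nearest") {
      j <- round(idx)
      ok <- j >= 1 & j <= nt
      v <- numeric(length(j))
      v[ok] <- ch[j[ok]]
    } else {
      j0 <- floor(idx)
      w <- idx - j0
      ok0 <- j0 >= 1 & j0 <= nt
      ok1 <- j0 + 1 >= 1 & j0 + 1 <= nt
      v <- numeric(length(j0))
      v[ok0] <- ch[j0[ok0]] * (1 - w[ok0])
      v[ok1] <- v[ok1] + ch[j0[ok1] + 1] * w[ok1]
    }
    img <- img + v
  }
  img
}

#' Radial location of a ring artifact
#'
#' Estimates the radius at which the reconstruction of a centred point
#' source concentrates its energy: the intensity-weighted mean radius
#' over pixels whose magnitude exceeds half the image maximum.  For a
#' scanning-radius error `dR`, a centred point is smeared into an annulus
#' of radius approximately `|dR|`.
#'
#' @param img reconstruction of a centred point source (matrix).
#' @param grid the [ReconGrid-class] the image was reconstructed on.
#' @return estimated artifact radius in metres.
#' @export
ringArtifactRadius <- function(img, grid) {
  px <- (seq_len(grid@nx) - (grid@nx + 1) / 2) * grid@dx
  py <- (seq_len(grid@ny) - (grid@ny + 1) / 2) * grid@dy
  R <- sqrt(outer(px^2, py^2, "+"))
  a <- abs(img)
  w <- pmax(a - 0.5 * max(a), 0)
  sum(R * w) / sum(w)
}

#' Normalize an image by its highest absolute pixel value
#'
#' @param img numeric matrix.
#' @return `img / max(abs(img))`; an all-zero image is returned unchanged.
#' @export
normalizeMax <- function(img) {
  m <- max(abs(img))
  if (m == 0) img else img / m
}
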
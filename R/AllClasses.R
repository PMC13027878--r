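#' @import methods
NULL

#' Initial-pressure map
#'
#' A 2D non-negative initial-pressure field \eqn{p_0(\mathbf{r})} with its
#' physical pixel size.  Values are kept on a normalized scale in
#' \eqn{[0, 1]}; the absolute pressure scale is arbitrary because both the
#' delay-and-sum reconstruction and the learned correction are invariant to
#' a global rescaling of the source amplitude.
#'
#' @slot values numeric matrix, the pressure field (x along rows, y along
#'   columns, origin at the matrix centre).
#' @slot dx,dy pixel size in metres.
#' @export
setClass("PressureMap",
  representation(values = "matrix", dx = "numeric", dy = "numeric"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) < 1 || ncol(v) < 1) return("empty pressure map")
    if (length(object@dx) != 1 || length(object@dy) != 1 ||
        object@dx <= 0 || object@dy <= 0)
      return("dx and dy must be positive scalars")
    if (any(!is.finite(v))) return("non-finite pressure values")
    if (min(v) < 0) return("pressure values must be non-negative")
    if (max(v) > 1 + 1e-9) return("pressure values must be <= 1")
    TRUE
  })

#' Acoustic medium
#'
#' Homogeneous acoustic medium.  The absorption coefficient is carried for
#' provenance only; propagation is lossless (see the methods vignette).
#'
#' @slot c speed of sound (m/s).
#' @slot rho density (kg/m^3).
#' @slot alpha0 absorption coefficient, dB/(MHz cm), informational.
#' @export
setClass("Medium",
  representation(c = "numeric", rho = "numeric", alpha0 = "numeric"),
  validity = function(object) {
    if (object@c <= 0) return("speed of sound must be positive")
    if (object@rho <= 0) return("density must be positive")
    if (object@alpha0 < 0) return("absorption must be >= 0")
    TRUE
  })

#' Circular sensor ring
#'
#' Geometry and transducer response of an evenly spaced circular detection
#' array.  Sensor `i` (1-based) sits at angle `2*pi*(i-1)/nSensors` on a
#' circle of the given radius about `center`.
#'
#' @slot nSensors number of sensors (>= 3).
#' @slot radius true scanning radius in metres.
#' @slot center ring centre (x, y) in metres.
#' @slot f0 transducer centre frequency (Hz).
#' @slot fracBw fractional -6 dB bandwidth (dimensionless, in (0, 2)).
#' @export
setClass("SensorRing",
  representation(nSensors = "integer", radius = "numeric",
                 center = "numeric", f0 = "numeric", fracBw = "numeric"),
  validity = function(object) {
    if (object@nSensors < 3L) return("need at least 3 sensors")
    if (object@radius <= 0) return("radius must be positive")
    if (length(object@center) != 2) return("center must be length 2")
    if (object@f0 <= 0) return("f0 must be positive")
    if (object@fracBw <= 0 || object@fracBw >= 2)
      return("fractional bandwidth must be in (0, 2)")
    TRUE
  })

#' RF sinogram
#'
#' Time-resolved pressure records, one row per sensor.
#'
#' @slot data nSensors x nT matrix of pressure samples (arbitrary units).
#' @slot fs sampling rate (Hz).
#' @slot t0 time of the first sample (s).
#' @export
setClass("Sinogram",
  representation(data = "matrix", fs = "numeric", t0 = "numeric"),
  validity = function(object) {
    if (ncol(object@data) < 1) return("need at least one time sample")
    if (any(!is.finite(object@data))) return("non-finite sinogram entries")
    if (object@fs <= 0) return("sampling rate must be positive")
    TRUE
  })

#' Synthetic phantom specification
#'
#' Recipe for a random 2D initial-pressure phantom.  Sizes are in pixels
#' of the phantom canvas; structure centres are constrained to a disk of
#' radius `placementFraction * canvas / 2` so that all sources lie well
#' inside the detection ring.
#'
#' @slot family one of `"points_disks_ellipses"`, `"curvilinear"`,
#'   `"vascular_tree"`, `"mixed"`.
#' @slot nStructures number of structures (>= 0).
#' @slot sizeRange structure size range in pixels (disk radii / line widths
#'   are derived from this range).
#' @slot intensityRange intensity range, within \eqn{[0, 1]}.
#' @slot canvas canvas side length in pixels.
#' @slot seed RNG seed; a fixed seed yields a bit-identical phantom.
#' @slot placementFraction fraction of the half-canvas usable for centres.
#' @slot allowOverlap allow overlapping disks/ellipses.
#' @export
setClass("PhantomSpec",
  representation(family = "character", nStructures = "integer",
                 sizeRange = "numeric", intensityRange = "numeric",
                 canvas = "integer", seed = "integer",
                 placementFraction = "numeric", allowOverlap = "logical"),
  validity = function(object) {
    fams <- c("points_disks_ellipses", "curvilinear", "vascular_tree", "mixed")
    if (!object@family %in% fams)
      return(paste("family must be one of:", paste(fams, collapse = ", ")))
    if (object@nStructures < 0L) return("nStructures must be >= 0")
    if (length(object@sizeRange) != 2 || any(object@sizeRange <= 0) ||
        diff(object@sizeRange) < 0)
      return("sizeRange must be positive and increasing")
    if (length(object@intensityRange) != 2 ||
        any(object@intensityRange < 0) || any(object@intensityRange > 1))
      return("intensityRange must lie in [0, 1]")
    if (object@canvas < 8L) return("canvas too small")
    if (2 * max(object@sizeRange) > object@canvas)
      return("structure larger than canvas")
    if (object@placementFraction <= 0 || object@placementFraction > 1)
      return("placementFraction must be in (0, 1]")
    TRUE
  })

#' Reconstruction grid
#'
#' Square pixel grid for delay-and-sum reconstruction, centred on the ring
#' centre.
#'
#' @slot nx,ny pixel counts.
#' @slot dx,dy pixel size in metres.
#' @export
setClass("ReconGrid",
  representation(nx = "integer", ny = "integer",
                 dx = "numeric", dy = "numeric"),
  validity = function(object) {
    if (object@nx < 1L || object@ny < 1L) return("grid must be non-empty")
    if (object@dx <= 0 || object@dy <= 0) return("pixel size must be positive")
    TRUE
  })

#' Delay-and-sum configuration
#'
#' The assumed scanning radius and sound speed used to compute per-pixel
#' delays, plus the temporal interpolation rule.
#'
#' @slot radiusAssumed assumed scanning radius (m); biasing this away from
#'   the true ring radius produces the artifacts this package corrects.
#' @slot cAssumed assumed speed of sound (m/s).
#' @slot interpolation `"linear"` or `"nearest"`.
#' @export
setClass("DASConfig",
  representation(radiusAssumed = "numeric", cAssumed = "numeric",
                 interpolation = "character"),
  validity = function(object) {
    if (object@radiusAssumed <= 0) return("radiusAssumed must be positive")
    if (object@cAssumed <= 0) return("cAssumed must be positive")
    if (!object@interpolation %in% c("linear", "nearest"))
      return("interpolation must be 'linear' or 'nearest'")
    TRUE
  })

#' Paired degraded / ground-truth image set
#'
#' Container for supervised training pairs.  Each pair holds a degraded
#' reconstruction (biased radius, noisy RF), the ground-truth
#' reconstruction (true radius, noise-free RF), the phantom id, the radius
#' used and the noise seed.
#'
#' @slot pairs list of pairs (each a list with elements `degraded`, `gt`,
#'   `phantomId`, `radiusUsed`, `noiseSeed`).
#' @slot radii the radius grid used for the degraded members (m).
#' @slot meta build metadata (seeds, geometry, configuration).
#' @export
setClass("PATPairSet",
  representation(pairs = "list", radii = "numeric", meta = "list"),
  validity = function(object) {
    ok <- vapply(object@pairs, function(p) {
      is.list(p) && all(c("degraded", "gt", "phantomId", "radiusUsed") %in%
                          names(p)) &&
        identical(dim(p$degraded), dim(p$gt))
    }, logical(1))
    if (!all(ok)) return("malformed pair entries")
    TRUE
  })

# ---- constructors ----------------------------------------------------------

#' Create a PressureMap
#' @param values numeric matrix of non-negative intensities (max <= 1).
#' @param dx,dy pixel size in metres.
#' @return A [PressureMap-class] object.
#' @export
pressureMap <- function(values, dx, dy = dx) {
  new("PressureMap", values = values, dx = dx, dy = dy)
}

#' Create a Medium
#' @param c speed of sound (m/s).
#' @param rho density (kg/m^3).
#' @param alpha0 absorption coefficient, dB/(MHz cm), informational.
#' @return A [Medium-class] object.
#' @export
medium <- function(c = 1500, rho = 1000, alpha0 = 0.5) {
  new("Medium", c = c, rho = rho, alpha0 = alpha0)
}

#' Create a SensorRing
#' @param nSensors number of evenly spaced sensors.
#' @param radius scanning radius (m).
#' @param center ring centre (m).
#' @param f0 transducer centre frequency (Hz).
#' @param fracBw fractional -6 dB bandwidth.
#' @return A [SensorRing-class] object.
#' @export
sensorRing <- function(nSensors, radius, center = c(0, 0), f0 = 5e6,
                       fracBw = 0.7) {
  new("SensorRing", nSensors = as.integer(nSensors), radius = radius,
      center = center, f0 = f0, fracBw = fracBw)
}

#' Create a Sinogram
#' @param data nSensors x nT matrix.
#' @param fs sampling rate (Hz).
#' @param t0 time of first sample (s).
#' @return A [Sinogram-class] object.
#' @export
sinogram <- function(data, fs, t0 = 0) {
  new("Sinogram", data = data, fs = fs, t0 = t0)
}

#' Create a PhantomSpec
#' @param family structure family.
#' @param nStructures number of structures.
#' @param sizeRange size range in pixels.
#' @param intensityRange intensity range in `[0, 1]`.
#' @param canvas canvas side in pixels.
#' @param seed RNG seed.
#' @param placementFraction fraction of the half-canvas usable for centres.
#' @param allowOverlap allow overlapping disk/ellipse structures.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(family = "points_disks_ellipses", nStructures = 5L,
                        sizeRange = c(3, 10), intensityRange = c(0.3, 1),
                        canvas = 128L, seed = 1L, placementFraction = 0.55,
                        allowOverlap = FALSE) {
  new("PhantomSpec", family = family, nStructures = as.integer(nStructures),
      sizeRange = as.numeric(sizeRange),
      intensityRange = as.numeric(intensityRange), canvas = as.integer(canvas),
      seed = as.integer(seed), placementFraction = placementFraction,
      allowOverlap = allowOverlap)
}

#' Create a ReconGrid
#' @param nx,ny pixel counts.
#' @param dx,dy pixel size (m).
#' @return A [ReconGrid-class] object.
#' @export
reconGrid <- function(nx, ny = nx, dx, dy = dx) {
  new("ReconGrid", nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy)
}

#' Create a DASConfig
#' @param radiusAssumed assumed scanning radius (m).
#' @param cAssumed assumed speed of sound (m/s).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [DASConfig-class] object.
#' @export
dasConfig <- function(radiusAssumed, cAssumed = 1500,
                      interpolation = "linear") {
  new("DASConfig", radiusAssumed = radiusAssumed, cAssumed = cAssumed,
      interpolation = interpolation)
}

# ---- accessors & show ------------------------------------------------------

#' Sensor angles of a ring
#' @param ring a [SensorRing-class].
#' @return numeric vector of `nSensors` evenly spaced angles in `[0, 2*pi)`.
#' @export
sensorAngles <- function(ring) {
  stopifnot(is(ring, "SensorRing"))
  2 * pi * (seq_len(ring@nSensors) - 1) / ring@nSensors
}

#' Sensor cartesian positions of a ring
#' @param ring a [SensorRing-class].
#' @return nSensors x 2 matrix of (x, y) positions in metres.
#' @export
sensorPositions <- function(ring) {
  a <- sensorAngles(ring)
  cbind(ring@center[1] + ring@radius * cos(a),
        ring@center[2] + ring@radius * sin(a))
}

#' Pressure values of a map
#' @param x a [PressureMap-class].
#' @return numeric matrix.
#' @export
mapValues <- function(x) {
  stopifnot(is(x, "PressureMap"))
  x@values
}

#' Sinogram sample matrix
#' @param x a [Sinogram-class].
#' @return nSensors x nT matrix.
#' @export
sinoData <- function(x) {
  stopifnot(is(x, "Sinogram"))
  x@data
}

#' Number of pairs in a PATPairSet
#' @param x a [PATPairSet-class].
#' @export
setMethod("length", "PATPairSet", function(x) length(x@pairs))

#' Extract one pair from a PATPairSet
#' @param x a [PATPairSet-class].
#' @param i pair index.
#' @export
setMethod("[[", "PATPairSet", function(x, i) x@pairs[[i]])

setMethod("show", "PressureMap", function(object) {
  v <- object@values
  cat(sprintf("PressureMap %dx%d, dx=%.3g m, range [%.3g, %.3g]\n",
              nrow(v), ncol(v), object@dx, min(v), max(v)))
})

setMethod("show", "SensorRing", function(object) {
  cat(sprintf(
    "SensorRing: %d sensors, radius %.4g mm, f0 %.3g MHz, bw %.0f%%\n",
    object@nSensors, object@radius * 1e3, object@f0 / 1e6,
    100 * object@fracBw))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d sensors x %d samples @ %.3g MHz (t0 = %.3g us)\n",
              nrow(object@data), ncol(object@data), object@fs / 1e6,
              object@t0 * 1e6))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: family '%s', %d structures, canvas %d, seed %d\n",
              object@family, object@nStructures, object@canvas, object@seed))
})

setMethod("show", "PATPairSet", function(object) {
  cat(sprintf("PATPairSet: %d pairs (%d phantoms x %d radii)\n",
              length(object@pairs),
              length(unique(vapply(object@pairs, `[[`, 1, "phantomId"))),
              length(object@radii)))
})
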
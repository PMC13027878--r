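# Synthetic 2D initial-pressure phantoms emulating the structural variety
# of anatomy-derived sources: point-like/circular/elliptical absorbers,
# irregular curvilinear structures, and branching vascular-like trees.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# stamp a filled disk of radius r (pixels) and given intensity at (cx, cy)
stamp_disk <- function(img, cx, cy, r, val) {
  n <- nrow(img)
  i0 <- max(1L, floor(cx - r)); i1 <- min(n, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(ncol(img), ceiling(cy + r))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  m <- outer((ii - cx)^2, (jj - cy)^2, `+`) <= r^2
  blk <- img[ii, jj, drop = FALSE]
  blk[m] <- pmax(blk[m], val)
  img[ii, jj] <- blk
  img
}

stamp_ellipse <- function(img, cx, cy, a, b, theta, val) {
  n <- nrow(img)
  r <- max(a, b)
  i0 <- max(1L, floor(cx - r)); i1 <- min(n, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(ncol(img), ceiling(cy + r))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  X <- outer(ii - cx, rep(1, length(jj)))
  Y <- outer(rep(1, length(ii)), jj - cy)
  Xr <- X * cos(theta) + Y * sin(theta)
  Yr <- -X * sin(theta) + Y * cos(theta)
  m <- (Xr / a)^2 + (Yr / b)^2 <= 1
  blk <- img[ii, jj, drop = FALSE]
  blk[m] <- pmax(blk[m], val)
  img[ii, jj] <- blk
  img
}

# stamp disks along a polyline sampled at ~0.5 px spacing
stamp_path <- function(img, xs, ys, width, val) {
  r <- max(width / 2, 0.5)
  for (k in seq_along(xs)) img <- stamp_disk(img, xs[k], ys[k], r, val)
  img
}

random_center <- function(rmax, cx0) {
  # uniform over the placement disk
  rr <- rmax * sqrt(runif(1))
  th <- runif(1, 0, 2 * pi)
  c(cx0 + rr * cos(th), cx0 + rr * sin(th))
}

gen_disks <- function(img, n, spec, rmax, c0) {
  placed <- matrix(numeric(0), ncol = 3)  # cx, cy, r
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(400)) {
      r <- runif(1, spec@sizeRange[1], spec@sizeRange[2])
      ctr <- random_center(max(rmax - r, 1), c0)
      if (!spec@allowOverlap && nrow(placed) > 0) {
        d <- sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2)
        if (any(d < placed[, 3] + r + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place non-overlapping structure; ",
                  "reduce counts or sizes, or set allowOverlap = TRUE")
    val <- runif(1, spec@intensityRange[1], spec@intensityRange[2])
    shape <- sample(c("point", "disk", "ellipse"), 1)
    if (shape == "point") {
      img <- stamp_disk(img, ctr[1], ctr[2], max(1, spec@sizeRange[1] / 2), val)
      placed <- rbind(placed, c(ctr, max(1, spec@sizeRange[1] / 2)))
    } else if (shape == "disk") {
      img <- stamp_disk(img, ctr[1], ctr[2], r, val)
      placed <- rbind(placed, c(ctr, r))
    } else {
      b <- runif(1, 0.4, 0.9) * r
      img <- stamp_ellipse(img, ctr[1], ctr[2], r, b, runif(1, 0, pi), val)
      placed <- rbind(placed, c(ctr, r))
    }
  }
  img
}

gen_curvilinear <- function(img, n, spec, rmax, c0) {
  for (k in seq_len(n)) {
    ctr <- random_center(rmax * 0.8, c0)
    len <- runif(1, 0.8, 1.8) * rmax
    npts <- max(8L, ceiling(len / 0.5))
    ang <- runif(1, 0, 2 * pi)
    xs <- numeric(npts); ys <- numeric(npts)
    xs[1] <- ctr[1]; ys[1] <- ctr[2]
    for (i in 2:npts) {
      ang <- ang + rnorm(1, 0, 0.25)
      xs[i] <- xs[i - 1] + 0.5 * cos(ang)
      ys[i] <- ys[i - 1] + 0.5 * sin(ang)
      # steer back towards the placement disk
      d <- sqrt((xs[i] - c0)^2 + (ys[i] - c0)^2)
      if (d > rmax) ang <- atan2(c0 - ys[i], c0 - xs[i]) + rnorm(1, 0, 0.3)
    }
    w <- runif(1, 1, 4)
    val <- runif(1, spec@intensityRange[1], spec@intensityRange[2])
    img <- stamp_path(img, xs, ys, w, val)
  }
  img
}

gen_tree <- function(img, n, spec, rmax, c0) {
  branch <- function(img, x, y, ang, len, w, depth, val) {
    if (depth <= 0 || len < 2 || w < 0.8) return(img)
    npts <- max(4L, ceiling(len / 0.5))
    xs <- x + (seq_len(npts) / npts) * len * cos(ang)
    ys <- y + (seq_len(npts) / npts) * len * sin(ang)
    keep <- sqrt((xs - c0)^2 + (ys - c0)^2) <= rmax
    img <- stamp_path(img, xs[keep], ys[keep], w, val)
    xe <- xs[npts]; ye <- ys[npts]
    for (s in c(-1, 1)) {
      img <- branch(img, xe, ye, ang + s * runif(1, 0.3, 0.7), len * 0.72,
                    w * 0.75, depth - 1, val)
    }
    img
  }
  for (k in seq_len(n)) {
    ctr <- random_center(rmax * 0.5, c0)
    val <- runif(1, spec@intensityRange[1], spec@intensityRange[2])
    img <- branch(img, ctr[1], ctr[2], runif(1, 0, 2 * pi),
                  runif(1, 0.5, 0.8) * rmax, runif(1, 2.5, 4), 4L, val)
  }
  img
}

#' Generate a synthetic initial-pressure phantom
#'
#' Draws a reproducible random phantom on a square canvas.  Structure
#' centres are confined to the interior placement disk so that all sources
#' lie inside the detection ring.  With `nStructures = 0` the map is all
#' zero.
#'
#' @param spec a [PhantomSpec-class].
#' @param dx pixel size in metres attached to the returned map.
#' @return A [PressureMap-class] with values in `[0, 1]`.
#' @examples
#' ph <- generatePhantom(phantomSpec(nStructures = 3L, seed = 7L), dx = 2e-4)
#' range(mapValues(ph))
#' @export
generatePhantom <- function(spec, dx = 2e-4) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@canvas
  c0 <- (n + 1) / 2
  rmax <- spec@placementFraction * n / 2
  img <- matrix(0, n, n)
  if (spec@nStructures > 0L) {
    img <- with_seed(spec@seed, {
      if (spec@family == "points_disks_ellipses") {
        gen_disks(img, spec@nStructures, spec, rmax, c0)
      } else if (spec@family == "curvilinear") {
        gen_curvilinear(img, spec@nStructures, spec, rmax, c0)
      } else if (spec@family == "vascular_tree") {
        gen_tree(img, spec@nStructures, spec, rmax, c0)
      } else {  # mixed
        counts <- tabulate(1 + (seq_len(spec@nStructures) %% 3), 3)
        i2 <- gen_disks(img, counts[1], spec, rmax, c0)
        i2 <- gen_curvilinear(i2, counts[2], spec, rmax, c0)
        gen_tree(i2, counts[3], spec, rmax, c0)
      }
    })
  }
  img[img > 1] <- 1
  pressureMap(img, dx = dx)
}

#' Load a grayscale image as an initial-pressure phantom
#'
#' Reads a PNG or TIFF image, converts it to grayscale (channel average)
#' and min-max normalizes the intensities to `[0, 1]`.  A constant image
#' maps to all zeros.
#'
#' @param path path to a PNG or TIFF file.
#' @param dx pixel size in metres attached to the returned map.
#' @return A [PressureMap-class].
#' @export
loadImagePhantom <- function(path, dx = 4e-5) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) {
    nc <- min(dim(img)[3], 3L)  # drop alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  if (length(img) == 0) stop("empty image: ", path)
  lo <- min(img); hi <- max(img)
  v <- if (hi > lo) (img - lo) / (hi - lo) else matrix(0, nrow(img), ncol(img))
  pressureMap(v, dx = dx)
}

#' Serialize / read a phantom specification as YAML
#'
#' @param spec a [PhantomSpec-class].
#' @param path YAML file path.
#' @return `writePhantomSpec` returns `path` invisibly;
#'   `readPhantomSpec` returns the [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  yaml::write_yaml(list(
    family = spec@family, nStructures = spec@nStructures,
    sizeRange = spec@sizeRange, intensityRange = spec@intensityRange,
    canvas = spec@canvas, seed = spec@seed,
    placementFraction = spec@placementFraction,
    allowOverlap = spec@allowOverlap), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  phantomSpec(family = y$family, nStructures = y$nStructures,
              sizeRange = y$sizeRange, intensityRange = y$intensityRange,
              canvas = y$canvas, seed = y$seed,
              placementFraction = y$placementFraction,
              allowOverlap = y$allowOverlap)
}

#' Zero-pad a pressure map to a larger square grid
#'
#' The original content is centred on the target grid; added pixels are
#' exactly zero, so total intensity is conserved.
#'
#' @param map a [PressureMap-class].
#' @param targetN target side length in pixels (>= current size).
#' @return A [PressureMap-class] of size `targetN x targetN`.
#' @export
padToGrid <- function(map, targetN) {
  stopifnot(is(map, "PressureMap"))
  v <- map@values
  targetN <- as.integer(targetN)
  if (targetN < max(nrow(v), ncol(v)))
    stop("targetN smaller than the input map")
  if (targetN == nrow(v) && targetN == ncol(v)) return(map)
  out <- matrix(0, targetN, targetN)
  oi <- floor((targetN - nrow(v)) / 2)
  oj <- floor((targetN - ncol(v)) / 2)
  out[oi + seq_len(nrow(v)), oj + seq_len(ncol(v))] <- v
  pressureMap(out, dx = map@dx, dy = map@dy)
}
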
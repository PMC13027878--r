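# Shared small-scale fixtures, built in code and cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# tiny acquisition: 64-grid, 4 mm ring of 8 sensors, fast enough for
# per-test simulation
tiny_acq <- function() {
  list(medium = medium(), simN = 64L, simDx = 2e-4,
       ring = sensorRing(8L, radius = 4e-3, f0 = 2e6, fracBw = 0.7),
       nT = 400L, fs = 25e6, pmlSize = 10L, noiseDb = -30,
       radii = radiusGrid(3.4e-3, 4.6e-3, 0.4e-3),
       recon = reconGrid(24L, dx = 1.5e-4), cAssumed = 1500,
       placementFraction = 0.5, phantomSize = c(2, 5))
}

# pressure map holding a single disk at (x0, y0) with radius a
disk_map <- function(n, dx, x0, y0, a) {
  cx <- (n + 1) / 2
  xs <- ((1:n) - cx) * dx
  m <- outer((xs - x0)^2, (xs - y0)^2, "+") <= a^2
  v <- matrix(0, n, n)
  v[m] <- 1
  pressureMap(v, dx = dx)
}

# independent 4-connectivity connected-component count (flood fill)
count_components_4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 ||
              p[2] > ncol(mask)) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- cur
          stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                                 c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
        }
      }
    }
  }
  cur
}

# brute-force triple-loop DAS reference (pixel x sensor x sample)
das_bruteforce <- function(sino, ringAngles, config, grid,
                           interpolation = config@interpolation) {
  dat <- sinoData(sino)
  nt <- ncol(dat)
  img <- matrix(0, grid@nx, grid@ny)
  for (ix in seq_len(grid@nx)) {
    for (iy in seq_len(grid@ny)) {
      x <- (ix - (grid@nx + 1) / 2) * grid@dx
      y <- (iy - (grid@ny + 1) / 2) * grid@dy
      acc <- 0
      for (s in seq_along(ringAngles)) {
        t <- timeOfFlight(ringAngles[s], c(x, y), config)
        idx <- (t - sino@t0) * sino@fs + 1
        if (interpolation == "nearest") {
          j <- round(idx)
          if (j >= 1 && j <= nt) acc <- acc + dat[s, j]
        } else {
          j0 <- floor(idx)
          w <- idx - j0
          if (j0 >= 1 && j0 <= nt) acc <- acc + dat[s, j0] * (1 - w)
          if (j0 + 1 >= 1 && j0 + 1 <= nt) acc <- acc + dat[s, j0 + 1] * w
        }
      }
      img[ix, iy] <- acc
    }
  }
  img
}

# leading-edge arrival time: first crossing of frac * channel peak
leading_edge <- function(channel, fs, frac = 0.5) {
  pk <- max(abs(channel))
  (which(abs(channel) > frac * pk)[1] - 1) / fs
}

# small stub pair set for metric / evaluation tests
stub_pairset <- function(nPhantoms = 2, nRadii = 3, n = 32, seed = 7) {
  set.seed(seed)
  pairs <- list()
  radii <- radiusGrid(4e-3, 4e-3 + (nRadii - 1) * 1e-4, 1e-4)
  for (i in seq_len(nPhantoms)) {
    gt <- matrix(runif(n * n), n)
    for (j in seq_len(nRadii)) {
      pairs <- c(pairs, list(list(
        degraded = gt + matrix(rnorm(n * n, 0, 0.1), n),
        gt = gt, phantomId = i, radiusUsed = radii[j], noiseSeed = j)))
    }
  }
  new("PATPairSet", pairs = pairs, radii = radii, meta = list())
}
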
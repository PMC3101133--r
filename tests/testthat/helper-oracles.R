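# Independent brute-force oracles; deliberately naive implementations that
# share no code path with the package internals (the package rasterizes by
# scanline fill and computes means via vectorized sums; these oracles
# evaluate pixel centres one at a time and sum with Kahan compensation).

# Kahan-compensated mean of a numeric vector, element by element
kahanMean <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s / length(x)
}

# even-odd point-in-polygon evaluated per pixel centre (crossing count per
# point, PNPOLY-style); only the polygon's bounding box needs visiting --
# centres outside it are outside the polygon by construction
pnpolyMaskOracle <- function(poly, width, height) {
  px <- poly[, 1]; py <- poly[, 2]
  pxj <- c(px[length(px)], px[-length(px)])
  pyj <- c(py[length(py)], py[-length(py)])
  m <- matrix(FALSE, nrow = height, ncol = width)
  xr <- max(0L, floor(min(px)) - 1L):min(width - 1L, ceiling(max(px)) + 1L)
  yr <- max(0L, floor(min(py)) - 1L):min(height - 1L, ceiling(max(py)) + 1L)
  for (y in yr) {
    cross <- (py > y) != (pyj > y)
    if (!any(cross)) next
    xint <- px[cross] + (y - py[cross]) * (pxj[cross] - px[cross]) /
      (pyj[cross] - py[cross])
    for (x in xr) {
      if (sum(x < xint) %% 2 == 1) m[y + 1L, x + 1L] <- TRUE
    }
  }
  m
}

# per-pixel double-loop region statistics over an explicit logical mask
loopRegionOracle <- function(image, mask) {
  px <- pixels(image)
  cols <- which(colSums(mask) > 0)
  rows <- which(rowSums(mask) > 0)
  vals <- numeric(0)
  area <- 0L; excluded <- 0L
  for (col in cols) {
    for (row in rows) {
      if (!mask[row, col]) next
      area <- area + 1L
      r <- px[row, col, 1]; g <- px[row, col, 2]; b <- px[row, col, 3]
      s <- r + g + b
      if (s == 0) excluded <- excluded + 1L
      else vals <- c(vals, (g + b) / s)
    }
  }
  list(mean = kahanMean(vals), areaPx = area, excludedPixels = excluded)
}

# exhaustive sup-distance between two empirical CDFs
ksDOracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# uniform-colour image helper
uniformImage <- function(width, height, rgb, bitDepth = 8L, id = "uniform") {
  px <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  RGBImage(px, bitDepth = bitDepth, id = id)
}

# axis-aligned square ROI covering pixels [x0, x0+side) x [y0, y0+side)
squareRoi <- function(label, kind, x0, y0, side, paired = NA_character_) {
  ROI(label, kind,
      cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side)),
      pairedBackground = paired)
}

# random simple (star-shaped) polygon around a centre, seeded by caller
starPolygon <- function(cx, cy, rMin, rMax, nVertices) {
  th <- sort(stats::runif(nVertices, 0, 2 * pi))
  r <- stats::runif(nVertices, rMin, rMax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}
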
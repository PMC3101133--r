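#' Rasterize a polygon to pixel coordinates
#'
#' Scanline fill under the even-odd rule on the pixel-centre grid. A pixel
#' (x, y) -- 0-based column x, row y -- belongs to the polygon when a
#' horizontal ray from its centre crosses the polygon boundary an odd number
#' of times. Crossings are counted half-open (an edge spans the scanline when
#' one endpoint lies strictly below it and the other does not), which makes
#' the fill half-open on the top/left: centres lying exactly on a left or
#' top boundary are included, those on a right or bottom boundary are not.
#' A square with corner vertices (0,0), (w,0), (w,h), (0,h) therefore covers
#' exactly \code{w * h} pixels.
#'
#' @param polygon numeric \code{n x 2} matrix of (x, y) vertices
#' @return integer matrix with columns \code{x}, \code{y}: the covered pixel
#'   coordinates (0-based), ordered by row then column
#' @examples
#' nrow(polygonPixels(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))  # 100
#' @export
polygonPixels <- function(polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  y0 <- ceiling(min(py))
  y1 <- floor(max(py))
  out_x <- integer(0); out_y <- integer(0)
  if (y1 < y0)
    return(cbind(x = out_x, y = out_y))
  for (y in y0:y1) {
    cross <- (py > y) != (ny > y)
    if (!any(cross)) next
    xi <- px[cross] + (y - py[cross]) * (nx[cross] - px[cross]) /
      (ny[cross] - py[cross])
    xi <- sort(xi)
    # pixels with an odd number of crossings strictly to their right:
    # fill [ceiling(xi[2k-1]), ceiling(xi[2k]) - 1]
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      xlo <- ceiling(xi[k]); xhi <- ceiling(xi[k + 1L]) - 1L
      if (xhi >= xlo) {
        out_x <- c(out_x, xlo:xhi)
        out_y <- c(out_y, rep.int(y, xhi - xlo + 1L))
      }
    }
  }
  cbind(x = as.integer(out_x), y = as.integer(out_y))
}

#' Rasterize a polygon to a logical mask
#'
#' Same fill semantics as \code{\link{polygonPixels}}, returned as a
#' \code{height x width} logical matrix indexed [row, column] = [y+1, x+1].
#' Pixels falling outside the image bounds are dropped.
#'
#' @param polygon numeric \code{n x 2} vertex matrix
#' @param width,height image size in pixels
#' @return logical \code{height x width} matrix
#' @examples
#' sum(polygonMask(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)), 8, 8))  # 16
#' @export
polygonMask <- function(polygon, width, height) {
  p <- polygonPixels(polygon)
  keep <- p[, 1] >= 0L & p[, 1] < width & p[, 2] >= 0L & p[, 2] < height
  m <- matrix(FALSE, nrow = height, ncol = width)
  m[cbind(p[keep, 2] + 1L, p[keep, 1] + 1L)] <- TRUE
  m
}

# pixel list restricted to the image; errors if the polygon spills outside
roiPixelsChecked <- function(roi, width, height) {
  p <- polygonPixels(roi@polygon)
  if (nrow(p) == 0L)
    stop(sprintf("empty ROI: '%s' rasterizes to no pixels", roi@label))
  if (any(p[, 1] < 0L | p[, 1] >= width | p[, 2] < 0L | p[, 2] >= height))
    stop(sprintf("ROI '%s' extends outside the %d x %d image",
                 roi@label, width, height))
  p
}

# regular 64-gon approximating an ellipse; used for synthetic cells and
# imported ImageJ ovals so all regions share the rasterization path
ellipsePolygon <- function(cx, cy, a, b, nVertices = 64L) {
  th <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  cbind(cx + a * cos(th), cy + b * sin(th))
}

polygonCentroid <- function(polygon) {
  c(mean(polygon[, 1]), mean(polygon[, 2]))
}
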
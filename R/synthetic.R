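clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# grid-slot layout shared by placement and capacity checks
slotLayout <- function(spec) {
  amax <- spec@cellAxes["majorMean"] + 3 * spec@cellAxes["majorSd"]
  bmax <- spec@cellAxes["minorMean"] + 3 * spec@cellAxes["minorSd"]
  slotW <- ceiling(2 * amax) + ceiling(2 * spec@patchRadius) + 6L
  slotH <- ceiling(2 * max(bmax, spec@patchRadius)) + 4L
  cols <- (spec@width - 2L) %/% slotW
  rows <- (spec@height - 2L) %/% slotH
  list(amax = unname(amax), bmax = unname(bmax), slotW = slotW, slotH = slotH,
       cols = cols, rows = rows, capacity = cols * rows)
}

#' Maximum number of cells placeable in a synthetic scene
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @return integer capacity of the non-overlapping grid layout
#' @export
sceneCapacity <- function(spec) slotLayout(spec)$capacity

#' Render a synthetic stained scene with ground truth
#'
#' Draws an eosin-like background (base colour plus an optional linear
#' illumination gradient), places non-overlapping elliptical cells each with
#' an adjacent background disc, recolours cytoplasm pixels so that their
#' chromatic ratio equals the local background ratio times the cell's
#' log-normal staining quotient (capped so ratios stay at most 1), and adds
#' truncated per-channel Gaussian noise. Rendering is fully deterministic
#' for a fixed spec (the spec's seed drives a single RNG stream).
#'
#' Cells sit in randomly chosen slots of a jittered grid, which guarantees
#' disjoint cells and patches fully inside the image; the total cytoplasm
#' area may not exceed 40\% of the image.
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @param config a \linkS4class{QuantConfig}; its \code{bgavScale} defines
#'   the ground-truth BGAV \code{bgavScale * log(quotient)}
#' @return list with \code{image} (an \linkS4class{RGBImage}) and
#'   \code{truth}: \code{rois} (cytoplasm + paired background ROIs),
#'   \code{quotients}, \code{trueBgav}, \code{trueAreaPx}
#' @examples
#' sc <- renderImage(syntheticSpec(seed = 7, nCells = 5, noiseSd = 0))
#' sc$truth$trueBgav
#' @export
renderImage <- function(spec, config = quantConfig()) {
  validObject(spec)
  lay <- slotLayout(spec)
  if (lay$capacity < spec@nCells)
    stop(sprintf("infeasible placement: %d cells requested, layout capacity %d",
                 spec@nCells, lay$capacity))
  if (spec@nCells * pi * lay$amax * lay$bmax > 0.4 * spec@width * spec@height)
    stop("infeasible placement: total cell area would exceed 40% of the image")
  W <- spec@width; H <- spec@height
  maxval <- 2^spec@bitDepth - 1

  set.seed(spec@seed)
  slots <- sample.int(lay$capacity, spec@nCells)

  # expected background, channel-wise linear in pixel-centre coordinates
  xs <- matrix(rep(0:(W - 1L), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1L), times = W), nrow = H)
  E <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    E[, , ch] <- clamp(spec@backgroundBaseRgb[ch] +
                         spec@gradient[1, ch] * xs +
                         spec@gradient[2, ch] * ys, 0, maxval)
  bgRatio <- (E[, , 2] + E[, , 3]) / (E[, , 1] + E[, , 2] + E[, , 3])
  qCap <- 1 / max(bgRatio)

  rois <- vector("list", 2L * spec@nCells)
  quotients <- numeric(spec@nCells)
  trueArea <- integer(spec@nCells)
  hw <- H * W
  for (i in seq_len(spec@nCells)) {
    s <- slots[i] - 1L
    sx <- (s %% lay$cols) * lay$slotW + 1L
    sy <- (s %/% lay$cols) * lay$slotH + 1L
    jx <- stats::runif(1, -1, 1); jy <- stats::runif(1, -1, 1)
    a <- clamp(stats::rnorm(1, spec@cellAxes["majorMean"], spec@cellAxes["majorSd"]),
               1, lay$amax)
    b <- clamp(stats::rnorm(1, spec@cellAxes["minorMean"], spec@cellAxes["minorSd"]),
               1, lay$bmax)
    q <- min(exp(stats::rnorm(1, spec@ratioMu, spec@ratioSigma)), qCap)
    cx <- sx + lay$amax + 1 + jx
    cy <- sy + lay$slotH / 2 + jy
    pcx <- sx + 2 * lay$amax + 3 + spec@patchRadius
    pcy <- sy + lay$slotH / 2
    cellPoly <- ellipsePolygon(cx, cy, a, b)
    patchPoly <- ellipsePolygon(pcx, pcy, spec@patchRadius, spec@patchRadius)
    pix <- polygonPixels(cellPoly)
    base <- pix[, 1] * H + pix[, 2] + 1L
    r0 <- E[base]; g0 <- E[base + hw]; b0 <- E[base + 2L * hw]
    tt <- r0 + g0 + b0
    rho <- pmin(q * (g0 + b0) / tt, 1)
    f <- rho * tt / (g0 + b0)
    E[base] <- (1 - rho) * tt
    E[base + hw] <- g0 * f
    E[base + 2L * hw] <- b0 * f
    lab <- sprintf("cell%03d", i)
    blab <- sprintf("bg%03d", i)
    rois[[2L * i - 1L]] <- ROI(lab, "cytoplasm", cellPoly,
                               pairedBackground = blab)
    rois[[2L * i]] <- ROI(blab, "background", patchPoly)
    quotients[i] <- q
    trueArea[i] <- nrow(pix)
  }
  if (spec@noiseSd > 0)
    E <- clamp(E + array(stats::rnorm(length(E), 0, spec@noiseSd), dim = dim(E)),
               0, maxval)
  img <- RGBImage(E, bitDepth = spec@bitDepth,
                  id = sprintf("synthetic-seed%d", spec@seed))
  list(image = img,
       truth = list(rois = rois, quotients = quotients,
                    trueBgav = config@bgavScale * log(quotients),
                    trueAreaPx = trueArea))
}

renderLevel <- function(spec, nCellsTotal, seedBase) {
  cap <- min(sceneCapacity(spec), spec@nCells)
  nImages <- ceiling(nCellsTotal / cap)
  renders <- vector("list", nImages)
  left <- nCellsTotal
  for (k in seq_len(nImages)) {
    sp <- spec
    sp@nCells <- as.integer(min(cap, left))
    sp@seed <- as.integer((seedBase + k) %% .Machine$integer.max)
    r <- renderImage(sp)
    r$image@id <- sprintf("%s-img%02d", r$image@id, k)
    renders[[k]] <- r
    left <- left - sp@nCells
  }
  renders
}

#' Measure the rendered images of one condition level
#'
#' Runs the measurement pipeline (explicit cell-to-patch pairing from the
#' ground truth) over every render of a simulated level and returns the
#' labelled dataset.
#'
#' @param level one element of the list returned by the simulate functions
#'   (or a list with \code{renders}, \code{label}, \code{covariate})
#' @param config a \linkS4class{QuantConfig}
#' @return a \linkS4class{ConditionDataset}
#' @export
measureLevel <- function(level, config = quantConfig()) {
  if (isTRUE(level$noCells))
    stop(sprintf("level '%s' has no cells (lethal condition)", level$label))
  imgs <- lapply(level$renders, `[[`, "image")
  rois <- lapply(level$renders, function(r) r$truth$rois)
  res <- measureBatch(imgs, rois, config)
  m <- res$measurements
  m$condition_label <- level$label
  m$covariate <- level$covariate
  conditionDataset(level$label, m, covariate = level$covariate)
}

#' Simulate a replicative-senescence series
#'
#' One level per population doubling: the designed mean of the log staining
#' quotient increases linearly with PD (\code{muSlope} per doubling), so the
#' designed mean BGAV increases at \code{bgavScale * muSlope} per doubling;
#' cell areas grow with \code{sizeSlope} (relative area growth per
#' doubling), emulating the enlargement of cells approaching senescence.
#'
#' @param baseSpec a \linkS4class{SyntheticSpec}; its \code{ratioMu} is the
#'   designed mu at the first level and \code{nCells} caps cells per image
#' @param pdLevels ordered population doublings (>= 2 levels)
#' @param muSlope change in mu per population doubling
#' @param sizeSlope relative cell-area growth per population doubling
#' @param nCellsPerLevel cells measured per level (default 250)
#' @param seed series seed (default the base spec's)
#' @return list of levels, each with \code{label}, \code{covariate},
#'   \code{trueMu}, \code{renders}
#' @export
simulateRsSeries <- function(baseSpec, pdLevels, muSlope, sizeSlope = 0,
                             nCellsPerLevel = 250L, seed = baseSpec@seed) {
  if (length(pdLevels) < 2L)
    stop("need at least 2 PD levels")
  if (!all(is.finite(c(muSlope, sizeSlope))))
    stop("slopes must be finite")
  lapply(seq_along(pdLevels), function(i) {
    pd <- pdLevels[i]
    dpd <- pd - pdLevels[1]
    sp <- baseSpec
    sp@ratioMu <- baseSpec@ratioMu + muSlope * dpd
    grow <- sqrt(1 + sizeSlope * dpd)
    sp@cellAxes[c("majorMean", "minorMean")] <-
      baseSpec@cellAxes[c("majorMean", "minorMean")] * grow
    lvl <- list(label = sprintf("PD %g", pd), covariate = pd,
                trueMu = sp@ratioMu)
    lvl$renders <- renderLevel(sp, nCellsPerLevel, seed + 1000L * i)
    lvl
  })
}

#' Designed mean shift of the H2O2 dose response
#'
#' Saturating (Michaelis-Menten-shaped) shift of the log staining quotient:
#' \code{muMax * dose / (halfDose + dose)}.
#'
#' @param dose H2O2 dose (same units as \code{halfDose}, e.g. uM)
#' @param muMax asymptotic mu shift
#' @param halfDose dose giving half the asymptotic shift
#' @return numeric shift(s)
#' @export
sipsDoseShift <- function(dose, muMax, halfDose) {
  if (any(dose < 0)) stop("doses must be non-negative")
  if (halfDose <= 0) stop("halfDose must be positive")
  muMax * dose / (halfDose + dose)
}

#' Simulate a stress-induced premature senescence dose response
#'
#' The designed mean BGAV rises with H2O2 dose along a saturating curve
#' (plateauing at high dose); doses above \code{lethalDose} return an
#' explicit no-cells marker instead of renders, emulating dose-limiting
#' cell death.
#'
#' @param baseSpec a \linkS4class{SyntheticSpec}
#' @param doses non-negative H2O2 doses
#' @param muMax,halfDose dose-response parameters (see
#'   \code{\link{sipsDoseShift}})
#' @param lethalDose doses strictly above this yield \code{noCells = TRUE}
#' @param nCellsPerLevel cells measured per level (default 250)
#' @param seed series seed
#' @return list of levels (\code{label}, \code{covariate}, \code{trueMu},
#'   \code{renders} or \code{noCells})
#' @export
simulateSipsDoseResponse <- function(baseSpec, doses, muMax, halfDose,
                                     lethalDose = 50, nCellsPerLevel = 250L,
                                     seed = baseSpec@seed) {
  if (any(doses < 0)) stop("doses must be non-negative")
  lapply(seq_along(doses), function(i) {
    dose <- doses[i]
    lvl <- list(label = sprintf("%g uM H2O2", dose), covariate = dose)
    if (dose > lethalDose) {
      lvl$noCells <- TRUE
      return(lvl)
    }
    sp <- baseSpec
    sp@ratioMu <- baseSpec@ratioMu + sipsDoseShift(dose, muMax, halfDose)
    lvl$trueMu <- sp@ratioMu
    lvl$renders <- renderLevel(sp, nCellsPerLevel, seed + 1000L * i)
    lvl
  })
}

#' Simulate a staining-pH series
#'
#' BGAV amplitudes fall as the reaction pH rises towards the suboptimal
#' pH 6.0; the caller supplies the designed mean BGAV per pH, which must be
#' strictly decreasing in pH (the contract of this scenario).
#'
#' @param baseSpec a \linkS4class{SyntheticSpec}
#' @param phLevels increasing staining pH values
#' @param amplitudes designed mean BGAV at each pH (strictly decreasing)
#' @param scale the BGAV scale converting amplitudes to mu (default 100)
#' @param nCellsPerLevel cells measured per level (default 250)
#' @param seed series seed
#' @return list of levels (\code{label}, \code{covariate}, \code{trueMu},
#'   \code{renders})
#' @export
simulatePhSeries <- function(baseSpec, phLevels, amplitudes, scale = 100,
                             nCellsPerLevel = 250L, seed = baseSpec@seed) {
  if (length(phLevels) != length(amplitudes))
    stop("phLevels and amplitudes must be parallel")
  if (any(diff(phLevels) <= 0))
    stop("phLevels must be strictly increasing")
  if (any(diff(amplitudes) >= 0))
    stop("amplitudes must be strictly decreasing in pH")
  lapply(seq_along(phLevels), function(i) {
    sp <- baseSpec
    sp@ratioMu <- amplitudes[i] / scale
    lvl <- list(label = sprintf("pH %.1f", phLevels[i]),
                covariate = phLevels[i], trueMu = sp@ratioMu)
    lvl$renders <- renderLevel(sp, nCellsPerLevel, seed + 1000L * i)
    lvl
  })
}
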
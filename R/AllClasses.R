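#' @import methods
NULL

ROI_KINDS <- c("cytoplasm", "background", "tubule", "nucleus")

#' RGBImage: a three-channel intensity raster
#'
#' Container for a colour micrograph. Pixels are stored as a numeric
#' \code{height x width x 3} array in red/green/blue channel order, in raw
#' intensity units of the stated bit depth (values in
#' \code{[0, 2^bitDepth - 1]}). Fractional values are permitted so that
#' float-path operations (e.g. illumination rescaling) do not force premature
#' quantization; quantization happens only on file write.
#'
#' @slot pixels numeric array, \code{height x width x 3}
#' @slot bitDepth integer, 8 or 16
#' @slot id free-text provenance label (file name, scene id, ...)
#' @export
setClass("RGBImage",
  representation(pixels = "array", bitDepth = "integer", id = "character"))

setValidity("RGBImage", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have height >= 1 and width >= 1")
  if (!is.numeric(p) || anyNA(p))
    return("pixels must be numeric with no missing values")
  if (!(object@bitDepth %in% c(8L, 16L)))
    return("bitDepth must be 8 or 16")
  mx <- 2^object@bitDepth - 1
  if (min(p) < 0 || max(p) > mx)
    return(sprintf("channel values must lie in [0, %d]", mx))
  if (length(object@id) != 1L || is.na(object@id))
    return("id must be a single string")
  TRUE
})

#' Construct an RGBImage
#'
#' @param pixels numeric \code{height x width x 3} array (red, green, blue)
#' @param bitDepth 8 or 16
#' @param id provenance label
#' @return an \linkS4class{RGBImage}
#' @examples
#' img <- RGBImage(array(128, dim = c(4, 4, 3)), bitDepth = 8, id = "flat")
#' dim(pixels(img))
#' @export
RGBImage <- function(pixels, bitDepth = 8L, id = "image") {
  new("RGBImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      id = as.character(id))
}

#' RegionOfInterest: a labelled polygon in image pixel coordinates
#'
#' Vertices address the pixel-centre grid with 0-based coordinates: the
#' centre of the top-left pixel is (0, 0), x grows rightwards (columns) and
#' y downwards (rows). A measurable region (cytoplasm or tubule) may carry
#' the label of its paired adjacent background patch; when absent, pairing
#' falls back to the nearest background ROI centroid in the same image.
#'
#' @slot label region label, unique within an image
#' @slot kind one of \code{"cytoplasm"}, \code{"background"}, \code{"tubule"},
#'   \code{"nucleus"}
#' @slot polygon numeric \code{n x 2} matrix of (x, y) vertices, \code{n >= 3}
#' @slot pairedBackground label of the paired background ROI, or
#'   \code{NA_character_}
#' @export
setClass("RegionOfInterest",
  representation(label = "character", kind = "character",
                 polygon = "matrix", pairedBackground = "character"))

setValidity("RegionOfInterest", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  if (!(object@kind %in% ROI_KINDS))
    return(sprintf("kind must be one of: %s", paste(ROI_KINDS, collapse = ", ")))
  p <- object@polygon
  if (!is.numeric(p) || ncol(p) != 2L)
    return("polygon must be a numeric n x 2 matrix")
  if (nrow(p) < 3L)
    return("polygon needs at least 3 vertices")
  if (anyNA(p) || any(!is.finite(p)))
    return("polygon vertices must be finite")
  if (length(object@pairedBackground) != 1L)
    return("pairedBackground must be a single string or NA")
  TRUE
})

#' Construct a RegionOfInterest
#'
#' @param label region label
#' @param kind region kind (\code{"cytoplasm"}, \code{"background"},
#'   \code{"tubule"} or \code{"nucleus"})
#' @param polygon numeric \code{n x 2} matrix of (x, y) pixel-centre
#'   coordinates, 0-based
#' @param pairedBackground optional label of the adjacent background ROI
#' @return a \linkS4class{RegionOfInterest}
#' @examples
#' roi <- ROI("cell01", "cytoplasm", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' roiKind(roi)
#' @export
ROI <- function(label, kind, polygon, pairedBackground = NA_character_) {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  dimnames(polygon) <- NULL
  new("RegionOfInterest", label = as.character(label), kind = as.character(kind),
      polygon = polygon, pairedBackground = as.character(pairedBackground))
}

#' QuantConfig: quantification parameters
#'
#' @slot bgavScale positive multiplier applied to the natural logarithm of
#'   CSI/BSI; default 100, which maps a staining ratio of ~1.93 to a BGAV of
#'   ~65.8 (the magnitude scale of reported fibroblast measurements)
#' @slot zeroPixelPolicy how to treat pixels whose three channels sum to zero:
#'   \code{"exclude"} drops them from the mean (and counts them), or
#'   \code{"epsilon"} adds \code{epsilon} to the denominator (yielding a ratio
#'   of 0 for such pixels)
#' @slot epsilon small positive denominator guard for the epsilon policy
#' @slot minCellsWarn warn when a batch/condition yields fewer measurements
#'   than this (250 for cultured cells; the tissue workflow uses 50)
#' @slot csiMode \code{"mean_ratio"} (default): region intensity is the mean of
#'   per-pixel (G+B)/(R+G+B) ratios; \code{"sum_ratio"}: the ratio of channel
#'   sums over the region, offered for comparison studies
#' @export
setClass("QuantConfig",
  representation(bgavScale = "numeric", zeroPixelPolicy = "character",
                 epsilon = "numeric", minCellsWarn = "integer",
                 csiMode = "character"))

setValidity("QuantConfig", function(object) {
  if (length(object@bgavScale) != 1L || !is.finite(object@bgavScale) ||
      object@bgavScale <= 0)
    return("bgavScale must be a positive number")
  if (!(object@zeroPixelPolicy %in% c("exclude", "epsilon")))
    return("zeroPixelPolicy must be 'exclude' or 'epsilon'")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    return("epsilon must be a positive number")
  if (length(object@minCellsWarn) != 1L || object@minCellsWarn < 1L)
    return("minCellsWarn must be >= 1")
  if (!(object@csiMode %in% c("mean_ratio", "sum_ratio")))
    return("csiMode must be 'mean_ratio' or 'sum_ratio'")
  TRUE
})

#' Construct a QuantConfig
#'
#' @param bgavScale positive log multiplier (default 100)
#' @param zeroPixelPolicy \code{"exclude"} or \code{"epsilon"}
#' @param epsilon denominator guard used when \code{zeroPixelPolicy} is
#'   \code{"epsilon"}
#' @param minCellsWarn under-count warning threshold (default 250)
#' @param csiMode \code{"mean_ratio"} or \code{"sum_ratio"}
#' @return a \linkS4class{QuantConfig}
#' @examples
#' cfg <- quantConfig()
#' bgavScale(cfg)
#' @export
quantConfig <- function(bgavScale = 100, zeroPixelPolicy = c("exclude", "epsilon"),
                        epsilon = 1e-6, minCellsWarn = 250L,
                        csiMode = c("mean_ratio", "sum_ratio")) {
  new("QuantConfig", bgavScale = as.numeric(bgavScale),
      zeroPixelPolicy = match.arg(zeroPixelPolicy),
      epsilon = as.numeric(epsilon), minCellsWarn = as.integer(minCellsWarn),
      csiMode = match.arg(csiMode))
}

#' ConditionDataset: measurements for one experimental condition
#'
#' Groups per-region measurements (one row per cell or tubule) under a
#' condition label -- a population doubling, an H2O2 dose, a staining pH, or
#' a tissue group -- with an optional ordered numeric covariate used for
#' trend analyses.
#'
#' @slot conditionLabel condition name, e.g. \code{"PD 34"} or
#'   \code{"DM week 13"}
#' @slot covariate ordered numeric value (PD, dose, pH, week) or \code{NA}
#' @slot measurements data.frame with at least columns \code{bgav} and
#'   \code{area_px}
#' @export
setClass("ConditionDataset",
  representation(conditionLabel = "character", covariate = "numeric",
                 measurements = "data.frame"))

setValidity("ConditionDataset", function(object) {
  m <- object@measurements
  if (nrow(m) < 1L)
    return("a condition needs at least one measurement")
  if (!all(c("bgav", "area_px") %in% names(m)))
    return("measurements must have columns 'bgav' and 'area_px'")
  if (any(!is.finite(m$bgav)))
    return("bgav values must be finite")
  if (length(object@covariate) != 1L)
    return("covariate must be a single number or NA")
  if (!is.na(object@covariate) && !is.finite(object@covariate))
    return("covariate, when present, must be finite")
  TRUE
})

#' Construct a ConditionDataset
#'
#' @param conditionLabel condition name
#' @param measurements measurement table (as from \code{\link{measureBatch}}),
#'   or a bare numeric vector of BGAVs (area then defaults to \code{NA})
#' @param covariate optional ordered numeric covariate
#' @return a \linkS4class{ConditionDataset}
#' @examples
#' ds <- conditionDataset("PD 34", c(-10.2, -14.1, -11.9), covariate = 34)
#' summarizeCondition(ds)
#' @export
conditionDataset <- function(conditionLabel, measurements, covariate = NA_real_) {
  if (is.numeric(measurements))
    measurements <- data.frame(bgav = as.numeric(measurements),
                               area_px = NA_integer_)
  new("ConditionDataset", conditionLabel = as.character(conditionLabel),
      covariate = as.numeric(covariate), measurements = measurements)
}

#' ComparisonResult: the outcome of a statistical comparison
#'
#' @slot testName one of \code{"shapiro_wilk_w"}, \code{"ks_two_sample"},
#'   \code{"anova_one_way"}, \code{"pearson_chi_square"},
#'   \code{"pearson_correlation"}
#' @slot statistic the test statistic (W, D, F, chi-square, or r)
#' @slot pValue p-value in [0, 1]; \code{NA} for the correlation coefficient
#' @slot nPerGroup sample size of each group
#' @slot details test-specific extras (degrees of freedom, method notes)
#' @export
setClass("ComparisonResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", nPerGroup = "integer", details = "list"))

setValidity("ComparisonResult", function(object) {
  ok <- c("shapiro_wilk_w", "ks_two_sample", "anova_one_way",
          "pearson_chi_square", "pearson_correlation")
  if (!(object@testName %in% ok))
    return("unknown testName")
  if (!is.finite(object@statistic))
    return("statistic must be finite")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  TRUE
})

comparisonResult <- function(testName, statistic, pValue, nPerGroup,
                             details = list()) {
  new("ComparisonResult", testName = testName,
      statistic = as.numeric(statistic), pValue = as.numeric(pValue),
      nPerGroup = as.integer(nPerGroup), details = details)
}

#' FociContingency: gamma-H2AX foci counts for two tissue groups
#'
#' A two-row table of nuclei counts per foci-count category (0..k foci per
#' nucleus), one row per group (e.g. control vs diabetic).
#'
#' @slot groups the two group labels
#' @slot counts integer matrix, 2 rows (groups) by k+1 foci categories
#' @export
setClass("FociContingency",
  representation(groups = "character", counts = "matrix"))

setValidity("FociContingency", function(object) {
  ct <- object@counts
  if (length(object@groups) != 2L || nrow(ct) != 2L)
    return("exactly two groups are required")
  if (any(ct < 0) || any(ct != round(ct)))
    return("counts must be non-negative integers")
  if (any(rowSums(ct) < 1))
    return("each group must contain at least one nucleus")
  TRUE
})

#' Construct a FociContingency table
#'
#' @param groups two group labels
#' @param counts 2 x (k+1) matrix of nuclei counts; columns are foci-count
#'   categories 0..k
#' @return a \linkS4class{FociContingency}
#' @examples
#' tab <- fociContingency(c("control", "DM"),
#'                        rbind(c(80, 15, 4, 1), c(35, 30, 22, 13)))
#' pearsonChiSquare(tab)
#' @export
fociContingency <- function(groups, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("foci_", seq_len(ncol(counts)) - 1L)
  rownames(counts) <- groups
  new("FociContingency", groups = as.character(groups), counts = counts)
}

#' SyntheticSpec: parameterization of a simulated stained scene
#'
#' Describes one synthetic X-gal-stained field: a (possibly uneven) eosin-like
#' background, elliptical cells whose cytoplasmic chromatic ratio is a
#' multiplicative quotient of the local background ratio, a background patch
#' adjacent to every cell, and per-channel Gaussian pixel noise. The
#' per-cell quotient is drawn log-normally, so the designed BGAV of a cell
#' with quotient q is \code{bgavScale * log(q)} and the designed mean BGAV is
#' \code{bgavScale * mu}.
#'
#' @slot seed integer RNG seed; identical specs render bit-identically
#' @slot width,height image size in pixels
#' @slot backgroundBaseRgb base background colour (red, green, blue), raw
#'   intensity units
#' @slot gradient 2 x 3 matrix of linear illumination coefficients: row 1 the
#'   per-channel intensity change per pixel in x, row 2 in y
#' @slot noiseSd per-channel Gaussian noise SD in intensity units
#' @slot nCells number of cells to place
#' @slot cellAxes named numeric: \code{majorMean}, \code{majorSd},
#'   \code{minorMean}, \code{minorSd} -- ellipse semi-axes in pixels
#' @slot ratioMu,ratioSigma log-normal parameters of the true
#'   cytoplasm/background chromatic-ratio quotient
#' @slot patchRadius radius (pixels) of the adjacent background disc
#' @slot patchMargin maximum centre-to-edge distance (pixels) between a cell
#'   and its background patch
#' @slot bitDepth output bit depth (8 or 16)
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", width = "integer", height = "integer",
                 backgroundBaseRgb = "numeric", gradient = "matrix",
                 noiseSd = "numeric", nCells = "integer", cellAxes = "numeric",
                 ratioMu = "numeric", ratioSigma = "numeric",
                 patchRadius = "numeric", patchMargin = "numeric",
                 bitDepth = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@width < 16L || object@height < 16L)
    return("image must be at least 16 x 16")
  if (length(object@backgroundBaseRgb) != 3L || any(object@backgroundBaseRgb < 0))
    return("backgroundBaseRgb must be three non-negative intensities")
  if (!all(dim(object@gradient) == c(2L, 3L)))
    return("gradient must be a 2 x 3 matrix (d/dx and d/dy per channel)")
  if (object@noiseSd < 0)
    return("noiseSd must be >= 0")
  if (object@nCells < 1L)
    return("nCells must be >= 1")
  need <- c("majorMean", "majorSd", "minorMean", "minorSd")
  if (!all(need %in% names(object@cellAxes)) || any(object@cellAxes[c(1, 3)] <= 0))
    return("cellAxes must name positive majorMean/minorMean and their SDs")
  if (object@ratioSigma < 0)
    return("ratioSigma must be >= 0")
  if (object@patchRadius <= 0 || object@patchMargin <= 0)
    return("patchRadius and patchMargin must be positive")
  if (!(object@bitDepth %in% c(8L, 16L)))
    return("bitDepth must be 8 or 16")
  TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults emulate an eosin-counterstained field: a red-dominated background
#' with chromatic ratio (G+B)/(R+G+B) = 0.2, so staining quotients up to ~5
#' stay below the ratio ceiling of 1; a mild illumination gradient can be
#' added via \code{gradient}. Cells are small ellipses (the defaults trade
#' realistic micrograph-scale cell areas for render speed; the ratio
#' statistic is area-free).
#'
#' @param seed RNG seed
#' @param width,height image size in pixels
#' @param backgroundBaseRgb base background (R, G, B)
#' @param gradient 2 x 3 linear illumination matrix (x-slope row, y-slope row)
#' @param noiseSd per-channel Gaussian noise SD
#' @param nCells number of cells
#' @param cellAxes ellipse semi-axis distribution
#'   (majorMean, majorSd, minorMean, minorSd)
#' @param ratioMu,ratioSigma log-normal quotient parameters
#' @param patchRadius background patch radius
#' @param patchMargin maximum cell-to-patch distance
#' @param bitDepth 8 or 16
#' @return a \linkS4class{SyntheticSpec}
#' @examples
#' sp <- syntheticSpec(seed = 1, nCells = 10, noiseSd = 0)
#' sc <- renderImage(sp)
#' length(sc$truth$rois)
#' @export
syntheticSpec <- function(seed = 1L, width = 256L, height = 256L,
                          backgroundBaseRgb = c(200, 25, 25),
                          gradient = matrix(0, 2, 3),
                          noiseSd = 2, nCells = 50L,
                          cellAxes = c(majorMean = 6, majorSd = 1,
                                       minorMean = 4.5, minorSd = 0.8),
                          ratioMu = 0, ratioSigma = 0.15,
                          patchRadius = 4, patchMargin = 20,
                          bitDepth = 8L) {
  new("SyntheticSpec", seed = as.integer(seed), width = as.integer(width),
      height = as.integer(height),
      backgroundBaseRgb = as.numeric(backgroundBaseRgb),
      gradient = gradient, noiseSd = as.numeric(noiseSd),
      nCells = as.integer(nCells), cellAxes = cellAxes,
      ratioMu = as.numeric(ratioMu), ratioSigma = as.numeric(ratioSigma),
      patchRadius = as.numeric(patchRadius),
      patchMargin = as.numeric(patchMargin), bitDepth = as.integer(bitDepth))
}
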
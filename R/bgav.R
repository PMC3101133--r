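#' Per-pixel chromatic staining ratio
#'
#' The blue-green chromatic fraction (G + B) / (R + G + B) of a pixel.
#' The X-gal reaction product is blue-green, so stained pixels shift this
#' ratio upwards; because the ratio is scale-free it is invariant under any
#' positive rescaling of all three channels (uniform illumination changes).
#' A pixel whose three channels are all zero has no defined ratio and is
#' returned as \code{NaN}; region-level code resolves these according to the
#' configured zero-pixel policy.
#'
#' @param r,g,b numeric vectors of channel intensities (recycled together)
#' @return numeric vector of ratios in [0, 1]; \code{NaN} for zero-sum pixels
#' @examples
#' chromaticRatio(255, 255, 255)  # 2/3
#' chromaticRatio(0, 0, 255)      # 1
#' @export
chromaticRatio <- function(r, g, b) {
  if (any(r < 0 | g < 0 | b < 0, na.rm = TRUE))
    stop("channel intensities must be non-negative")
  s <- r + g + b
  out <- (g + b) / s
  out[s == 0] <- NaN
  out
}

#' Mean chromatic ratio over a region
#'
#' Computes the staining intensity of one region: by default the arithmetic
#' mean of per-pixel chromatic ratios over all rasterized mask pixels (the
#' sum of per-pixel ratios divided by the region pixel area), which is the
#' CSI of a cytoplasm/tubule region or the BSI of a background patch.
#' With \code{csiMode = "sum_ratio"} the region intensity is instead the
#' ratio of channel sums, \code{sum(G+B) / sum(R+G+B)}, over the same pixels.
#'
#' Degenerate all-zero pixels are excluded from the mean and counted
#' (\code{zeroPixelPolicy = "exclude"}), or kept with \code{epsilon} added to
#' their denominator (\code{"epsilon"}; their ratio is then 0).
#'
#' @param image an \linkS4class{RGBImage}
#' @param roi a \linkS4class{RegionOfInterest} rasterizing inside the image
#' @param config a \linkS4class{QuantConfig}
#' @return list with \code{mean} (ratio in [0, 1]), \code{areaPx} (mask pixel
#'   count) and \code{excludedPixels} (zero-sum pixels skipped)
#' @examples
#' img <- RGBImage(array(128, dim = c(8, 8, 3)), 8, "flat")
#' roi <- ROI("r", "cytoplasm", cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)))
#' regionMeanRatio(img, roi, quantConfig())$mean  # 2/3
#' @export
regionMeanRatio <- function(image, roi, config = quantConfig()) {
  d <- dim(image@pixels)
  p <- roiPixelsChecked(roi, d[2], d[1])
  area <- nrow(p)
  hw <- d[1] * d[2]
  base <- p[, 1] * d[1] + p[, 2] + 1L     # linear index of channel 1
  px <- image@pixels
  r <- px[base]; g <- px[base + hw]; b <- px[base + 2L * hw]
  s <- r + g + b
  zero <- s == 0
  nzero <- sum(zero)
  if (config@csiMode == "sum_ratio") {
    if (config@zeroPixelPolicy == "exclude" && nzero == area)
      stop(sprintf("no measurable pixels in ROI '%s'", roi@label))
    denom <- sum(s)
    if (config@zeroPixelPolicy == "epsilon")
      denom <- denom + config@epsilon * nzero
    if (denom == 0)
      stop(sprintf("no measurable pixels in ROI '%s'", roi@label))
    m <- sum(g + b) / denom
    excl <- if (config@zeroPixelPolicy == "exclude") nzero else 0L
    return(list(mean = m, areaPx = area, excludedPixels = as.integer(excl)))
  }
  ratio <- (g + b) / s
  if (config@zeroPixelPolicy == "exclude") {
    if (nzero == area)
      stop(sprintf("no measurable pixels in ROI '%s'", roi@label))
    m <- sum(ratio[!zero]) / (area - nzero)
    excl <- nzero
  } else {
    ratio[zero] <- (g[zero] + b[zero]) / (s[zero] + config@epsilon)
    m <- sum(ratio) / area
    excl <- 0L
  }
  list(mean = m, areaPx = area, excludedPixels = as.integer(excl))
}

#' The BGAV statistic
#'
#' The beta-galactosidase activity value of a region:
#' \code{bgavScale * ln(CSI / BSI)}. Standardizing the cell staining
#' intensity by the adjacent background corrects uneven illumination and
#' staining background, and the log transform symmetrizes the ratio
#' (a cell staining k-fold above background scores the exact negative of a
#' cell staining k-fold below). BGAV is 0 exactly when CSI equals BSI.
#'
#' @param csi mean chromatic ratio of the cell/tubule region (> 0)
#' @param bsi mean chromatic ratio of the paired background (> 0)
#' @param config a \linkS4class{QuantConfig}; \code{bgavScale} defaults to 100
#' @return numeric BGAV (vectorized over \code{csi}/\code{bsi})
#' @examples
#' computeBGAV(0.9, 0.6)  # 100 * log(1.5) = 40.55
#' @export
computeBGAV <- function(csi, bsi, config = quantConfig()) {
  if (any(!is.finite(csi)) || any(!is.finite(bsi)) ||
      any(csi <= 0) || any(bsi <= 0))
    stop("non-positive intensity: CSI and BSI must both be > 0")
  config@bgavScale * log(csi / bsi)
}

emptyMeasurementTable <- function() {
  data.frame(image_id = character(0), region_label = character(0),
             kind = character(0), area_px = integer(0), csi = numeric(0),
             bsi = numeric(0), bgav = numeric(0),
             excluded_pixels = integer(0), condition_label = character(0),
             covariate = numeric(0), stringsAsFactors = FALSE)
}

#' Measure one cell or tubule against its background patch
#'
#' @param image an \linkS4class{RGBImage}
#' @param roi the measured region (kind \code{"cytoplasm"} or \code{"tubule"})
#' @param background the paired background patch (kind \code{"background"})
#' @param config a \linkS4class{QuantConfig}
#' @return a one-row measurement data.frame with columns \code{image_id},
#'   \code{region_label}, \code{kind}, \code{area_px}, \code{csi}, \code{bsi},
#'   \code{bgav}, \code{excluded_pixels}, \code{condition_label},
#'   \code{covariate}
#' @examples
#' px <- array(128, dim = c(16, 16, 3))
#' px[3:8, 3:8, 1] <- 0   # blue-green shifted block
#' img <- RGBImage(px, 8, "demo")
#' cell <- ROI("c1", "cytoplasm", cbind(c(2, 8, 8, 2), c(2, 2, 8, 8)))
#' bg <- ROI("b1", "background", cbind(c(10, 15, 15, 10), c(10, 10, 15, 15)))
#' measureRegion(img, cell, bg)$bgav  # 100 * log(1.5)
#' @export
measureRegion <- function(image, roi, background, config = quantConfig()) {
  if (!(roi@kind %in% c("cytoplasm", "tubule")))
    stop(sprintf("ROI '%s' has kind '%s'; only cytoplasm/tubule regions are measured",
                 roi@label, roi@kind))
  if (background@kind != "background")
    stop(sprintf("ROI '%s' is not a background region", background@label))
  cellStat <- withCallingHandlers(
    regionMeanRatio(image, roi, config),
    error = function(e) stop(sprintf("[%s] %s", roi@label, conditionMessage(e)),
                             call. = FALSE))
  bgStat <- withCallingHandlers(
    regionMeanRatio(image, background, config),
    error = function(e) stop(sprintf("[%s] %s", background@label,
                                     conditionMessage(e)), call. = FALSE))
  data.frame(image_id = image@id, region_label = roi@label, kind = roi@kind,
             area_px = cellStat$areaPx, csi = cellStat$mean, bsi = bgStat$mean,
             bgav = computeBGAV(cellStat$mean, bgStat$mean, config),
             excluded_pixels = cellStat$excludedPixels,
             condition_label = NA_character_, covariate = NA_real_,
             stringsAsFactors = FALSE)
}

resolveBackground <- function(roi, backgrounds) {
  if (!is.na(roi@pairedBackground)) {
    hit <- vapply(backgrounds, function(b) b@label == roi@pairedBackground,
                  logical(1))
    if (!any(hit))
      stop(sprintf("ROI '%s' pairs to background '%s', which does not exist in its image",
                   roi@label, roi@pairedBackground))
    return(backgrounds[[which(hit)[1]]])
  }
  if (length(backgrounds) == 0L)
    stop(sprintf("ROI '%s' has no background ROI available in its image",
                 roi@label))
  cen <- polygonCentroid(roi@polygon)
  d <- vapply(backgrounds, function(b) {
    bc <- polygonCentroid(b@polygon)
    sqrt(sum((bc - cen)^2))
  }, numeric(1))
  labs <- vapply(backgrounds, roiLabel, character(1))
  ord <- order(d, labs)        # ties broken by lexicographic label
  backgrounds[[ord[1]]]
}

#' Measure every cell/tubule ROI across a set of images
#'
#' Pairs each measurable ROI (cytoplasm or tubule) with its background: the
#' explicit \code{pairedBackground} label when present, otherwise the nearest
#' background-ROI centroid within the same image (ties broken by label).
#' Output rows are ordered deterministically by image id, then ROI label.
#' Per-ROI failures (unresolvable pairing, empty masks) are collected, not
#' fatal. A warning is recorded when fewer than \code{minCellsWarn}
#' measurements result.
#'
#' @param images an \linkS4class{RGBImage} or list of them
#' @param rois a list of \linkS4class{RegionOfInterest} (single image) or a
#'   list of such lists, parallel to \code{images}
#' @param config a \linkS4class{QuantConfig}
#' @return list with \code{measurements} (data.frame, one row per measured
#'   ROI), \code{warnings} (character) and \code{errors} (data.frame with
#'   \code{image_id}, \code{region_label}, \code{message})
#' @export
measureBatch <- function(images, rois, config = quantConfig()) {
  if (is(images, "RGBImage")) {
    images <- list(images)
    if (length(rois) == 0L || is(rois[[1]], "RegionOfInterest"))
      rois <- list(rois)
  }
  if (length(images) == 0L)
    stop("no images supplied")
  if (length(rois) != length(images))
    stop("rois must be a list parallel to images")
  if (sum(lengths(rois)) == 0L)
    stop("empty ROI set")
  ids <- vapply(images, imageId, character(1))
  ord <- order(ids)
  rows <- list(); errs <- list()
  for (i in ord) {
    img <- images[[i]]
    rset <- rois[[i]]
    kinds <- vapply(rset, roiKind, character(1))
    backgrounds <- rset[kinds == "background"]
    measurable <- rset[kinds %in% c("cytoplasm", "tubule")]
    labs <- vapply(measurable, roiLabel, character(1))
    for (j in order(labs)) {
      roi <- measurable[[j]]
      res <- tryCatch({
        bg <- resolveBackground(roi, backgrounds)
        measureRegion(img, roi, bg, config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errs[[length(errs) + 1L]] <- data.frame(
          image_id = img@id, region_label = roi@label,
          message = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else emptyMeasurementTable()
  warn <- character(0)
  if (nrow(out) < config@minCellsWarn)
    warn <- sprintf("only %d measurements; fewer than the recommended minimum of %d",
                    nrow(out), config@minCellsWarn)
  errdf <- if (length(errs)) do.call(rbind, errs) else
    data.frame(image_id = character(0), region_label = character(0),
               message = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(measurements = out, warnings = warn, errors = errdf)
}
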
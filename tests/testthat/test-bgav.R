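test_that("chromatic ratio handles pure and degenerate colours", {
  expect_equal(chromaticRatio(255, 255, 255), 2 / 3)
  expect_equal(chromaticRatio(0, 0, 255), 1)
  expect_equal(chromaticRatio(255, 0, 0), 0)
  expect_true(is.nan(chromaticRatio(0, 0, 0)))
  expect_error(chromaticRatio(-1, 0, 0), "non-negative")
})

test_that("chromatic ratio is invariant under positive channel scaling", {
  set.seed(7)
  r <- runif(200, 0, 255); g <- runif(200, 0, 255); b <- runif(200, 0, 255)
  for (k in c(0.25, 1.7, 12)) {
    expect_equal(chromaticRatio(k * r, k * g, k * b),
                 chromaticRatio(r, g, b), tolerance = 1e-14)
  }
})

test_that("region means reproduce uniform fields and tiny hand cases", {
  img <- uniformImage(8, 8, c(255, 255, 255))
  r <- regionMeanRatio(img, squareRoi("r", "cytoplasm", 0, 0, 5))
  expect_equal(r$mean, 2 / 3)
  expect_equal(r$areaPx, 25L)
  expect_equal(r$excludedPixels, 0L)

  # two-pixel region: pure blue + pure red -> mean 0.5
  px <- array(0, dim = c(1, 2, 3))
  px[1, 1, ] <- c(0, 0, 255)
  px[1, 2, ] <- c(255, 0, 0)
  img2 <- RGBImage(px, 8, "two")
  r2 <- regionMeanRatio(img2, ROI("p", "cytoplasm",
                                  cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))))
  expect_equal(r2$mean, 0.5)
  expect_equal(r2$areaPx, 2L)
})

test_that("region means match the per-pixel loop oracle to 1e-12", {
  set.seed(11)
  for (rep in 1:3) {
    px <- array(runif(64 * 64 * 3, 0, 255), dim = c(64, 64, 3))
    img <- RGBImage(px, 8, sprintf("noise%d", rep))
    roi <- ROI("r", "cytoplasm", starPolygon(32, 32, 8, 25, 9))
    got <- regionMeanRatio(img, roi)
    mask <- polygonMask(roiPolygon(roi), 64, 64)
    want <- loopRegionOracle(img, mask)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_identical(got$areaPx, want$areaPx)
  }
})

test_that("zero-sum pixels follow the configured policy", {
  px <- array(100, dim = c(4, 4, 3))
  px[1, 1, ] <- 0
  px[2, 2, ] <- 0
  img <- RGBImage(px, 8, "z")
  roi <- squareRoi("r", "cytoplasm", 0, 0, 4)
  ex <- regionMeanRatio(img, roi, quantConfig(zeroPixelPolicy = "exclude"))
  expect_equal(ex$excludedPixels, 2L)
  expect_equal(ex$areaPx, 16L)
  expect_equal(ex$mean, 2 / 3)
  ep <- regionMeanRatio(img, roi, quantConfig(zeroPixelPolicy = "epsilon"))
  expect_equal(ep$excludedPixels, 0L)
  expect_equal(ep$mean, (14 * 2 / 3) / 16)  # zero pixels contribute ratio 0

  allz <- RGBImage(array(0, dim = c(4, 4, 3)), 8, "black")
  expect_error(regionMeanRatio(allz, roi), "no measurable pixels")
})

test_that("sum-ratio mode equals the ratio of channel sums", {
  set.seed(13)
  px <- array(runif(16 * 16 * 3, 1, 255), dim = c(16, 16, 3))
  img <- RGBImage(px, 8, "s")
  roi <- squareRoi("r", "cytoplasm", 2, 3, 9)
  got <- regionMeanRatio(img, roi, quantConfig(csiMode = "sum_ratio"))
  mask <- polygonMask(roiPolygon(roi), 16, 16)
  idx <- which(mask)
  num <- sum(px[, , 2][idx]) + sum(px[, , 3][idx])
  den <- num + sum(px[, , 1][idx])
  expect_equal(got$mean, num / den, tolerance = 1e-12)
})

test_that("BGAV is the scaled log ratio with its closed-form values", {
  expect_equal(computeBGAV(0.5, 0.5), 0)
  expect_equal(computeBGAV(0.9, 0.6), 100 * log(1.5), tolerance = 1e-12)
  expect_equal(computeBGAV(0.6, 0.9), -100 * log(1.5), tolerance = 1e-12)
  expect_equal(computeBGAV(0.8, 0.2, quantConfig(bgavScale = 7)),
               7 * log(4), tolerance = 1e-12)
  expect_error(computeBGAV(0, 0.5), "non-positive")
  expect_error(computeBGAV(0.5, -1), "non-positive")
})

test_that("BGAV is antisymmetric and monotone in its arguments", {
  set.seed(17)
  a <- runif(50, 0.05, 1); b <- runif(50, 0.05, 1)
  expect_equal(computeBGAV(a, b), -computeBGAV(b, a), tolerance = 1e-12)
  expect_true(all(diff(computeBGAV(seq(0.1, 0.9, by = 0.1), 0.5)) > 0))
  expect_true(all(diff(computeBGAV(0.5, seq(0.1, 0.9, by = 0.1))) < 0))
})

test_that("measureRegion standardizes a cell against its background", {
  px <- array(0, dim = c(16, 16, 3))
  for (ch in 1:3) px[, , ch] <- 128            # gray background
  px[3:8, 3:8, 1] <- 0                          # teal cell block
  img <- RGBImage(px, 8, "demo")
  cell <- squareRoi("c1", "cytoplasm", 2, 2, 6)
  bg <- squareRoi("b1", "background", 10, 10, 5)
  m <- measureRegion(img, cell, bg)
  expect_equal(m$csi, 1)
  expect_equal(m$bsi, 2 / 3)
  expect_equal(m$bgav, 100 * log(1.5), tolerance = 1e-10)
  expect_equal(m$area_px, 36L)

  # identical cytoplasm and background colour -> BGAV 0 regardless of colour
  img2 <- uniformImage(16, 16, c(37, 91, 11))
  m2 <- measureRegion(img2, cell, bg)
  expect_equal(m2$bgav, 0)

  expect_error(measureRegion(img, bg, bg), "kind")
  expect_error(measureRegion(img, cell, cell), "not a background")
})

test_that("uniform illumination rescaling leaves measurements unchanged", {
  set.seed(19)
  px <- array(runif(24 * 24 * 3, 10, 140), dim = c(24, 24, 3))
  img <- RGBImage(px, 8, "base")
  img2 <- RGBImage(px * 1.7, 16, "scaled")   # stays in the 16-bit range
  cell <- squareRoi("c", "cytoplasm", 2, 2, 9)
  bg <- squareRoi("b", "background", 14, 14, 7)
  m1 <- measureRegion(img, cell, bg)
  m2 <- measureRegion(img2, cell, bg)
  expect_equal(m1$csi, m2$csi, tolerance = 1e-12)
  expect_equal(m1$bgav, m2$bgav, tolerance = 1e-12)
})

test_that("raising blue inside the cytoplasm strictly raises BGAV", {
  px <- array(80, dim = c(16, 16, 3))
  img0 <- RGBImage(px, 8, "b0")
  cell <- squareRoi("c", "cytoplasm", 1, 1, 6)
  bg <- squareRoi("b", "background", 9, 9, 5)
  bgavs <- vapply(c(0, 20, 50, 90), function(extra) {
    p <- px
    p[2:7, 2:7, 3] <- 80 + extra
    measureRegion(RGBImage(p, 8, "b"), cell, bg)$bgav
  }, numeric(1))
  expect_true(all(diff(bgavs) > 0))
  expect_equal(bgavs[1], 0)
})

test_that("batch measurement pairs, orders and warns deterministically", {
  img <- uniformImage(32, 32, c(120, 60, 60), id = "img1")
  rois <- list(
    squareRoi("cellB", "cytoplasm", 1, 1, 5, paired = "bgB"),
    squareRoi("cellA", "cytoplasm", 10, 1, 5, paired = "bgA"),
    squareRoi("cellC", "cytoplasm", 20, 1, 5, paired = "bgC"),
    squareRoi("bgA", "background", 10, 10, 4),
    squareRoi("bgB", "background", 1, 10, 4),
    squareRoi("bgC", "background", 20, 10, 4))
  res <- measureBatch(img, rois, quantConfig(minCellsWarn = 3))
  expect_equal(nrow(res$measurements), 3L)
  expect_equal(res$measurements$region_label, c("cellA", "cellB", "cellC"))
  expect_length(res$warnings, 0L)
  expect_equal(nrow(res$errors), 0L)

  # under-count warning fires below the threshold
  res2 <- measureBatch(img, rois, quantConfig(minCellsWarn = 250))
  expect_length(res2$warnings, 1L)
  expect_match(res2$warnings, "250")
})

test_that("implicit pairing picks the nearest background, ties by label", {
  img <- uniformImage(48, 32, c(120, 60, 60), id = "img1")
  cells <- lapply(1:10, function(i)
    squareRoi(sprintf("cell%02d", i), "cytoplasm", 4 * (i - 1) + 1, 2, 3))
  onebg <- squareRoi("bgOnly", "background", 20, 20, 6)
  res <- measureBatch(img, c(cells, list(onebg)), quantConfig(minCellsWarn = 1))
  expect_equal(nrow(res$measurements), 10L)
  # equals the per-cell measureRegion oracle against that single background
  for (i in seq_len(10)) {
    want <- measureRegion(img, cells[[i]], onebg)
    got <- res$measurements[res$measurements$region_label == roiLabel(cells[[i]]), ]
    expect_equal(got$bgav, want$bgav)
    expect_equal(got$csi, want$csi)
  }

  # equidistant backgrounds: lexicographically smaller label wins
  cell <- squareRoi("c", "cytoplasm", 10, 10, 4)
  bgL <- squareRoi("bgA", "background", 2, 10, 4)
  bgR <- squareRoi("bgB", "background", 18, 10, 4)
  got <- SABGquant:::resolveBackground(cell, list(bgR, bgL))
  expect_equal(roiLabel(got), "bgA")
})

test_that("per-ROI failures are reported while the batch continues", {
  img <- uniformImage(32, 32, c(120, 60, 60), id = "img1")
  rois <- list(
    squareRoi("good", "cytoplasm", 1, 1, 5, paired = "bg1"),
    squareRoi("dangling", "cytoplasm", 10, 1, 5, paired = "nope"),
    squareRoi("bg1", "background", 1, 10, 4))
  res <- measureBatch(img, rois, quantConfig(minCellsWarn = 1))
  expect_equal(res$measurements$region_label, "good")
  expect_equal(res$errors$region_label, "dangling")
  expect_match(res$errors$message, "nope")

  expect_error(measureBatch(img, list(), quantConfig()), "empty ROI set")
})
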
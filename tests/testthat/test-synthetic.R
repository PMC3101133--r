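test_that("rendering is bit-identical for a fixed spec and seed", {
  sp <- syntheticSpec(seed = 101, nCells = 8)
  a <- renderImage(sp)
  b <- renderImage(sp)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth$quotients, b$truth$quotients)
  expect_identical(lapply(a$truth$rois, roiPolygon),
                   lapply(b$truth$rois, roiPolygon))
  # a different seed changes the scene
  c <- renderImage(syntheticSpec(seed = 102, nCells = 8))
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("null staining (quotient 1, no noise, no gradient) gives BGAV 0", {
  sp <- syntheticSpec(seed = 5, nCells = 12, noiseSd = 0,
                      ratioMu = 0, ratioSigma = 0)
  sc <- renderImage(sp)
  ds <- measureLevel(list(renders = list(sc), label = "null", covariate = 0))
  expect_true(all(abs(measurements(ds)$bgav) < 1e-9))
})

test_that("noiseless renders recover designed quotients in closed form", {
  for (q in c(1.5, 1.93)) {
    sp <- syntheticSpec(seed = 9, nCells = 1, noiseSd = 0,
                        ratioMu = log(q), ratioSigma = 0)
    sc <- renderImage(sp)
    ds <- measureLevel(list(renders = list(sc), label = "q", covariate = 1))
    expect_equal(measurements(ds)$bgav, 100 * log(q), tolerance = 1e-6)
    expect_equal(sc$truth$trueBgav, 100 * log(q), tolerance = 1e-12)
  }
})

test_that("ground truth is internally consistent", {
  sc <- renderImage(syntheticSpec(seed = 71, nCells = 10))
  tr <- sc$truth
  expect_length(tr$rois, 20L)  # one background per cell
  kinds <- vapply(tr$rois, roiKind, character(1))
  expect_equal(sum(kinds == "cytoplasm"), 10L)
  expect_equal(sum(kinds == "background"), 10L)
  expect_equal(tr$trueBgav, 100 * log(tr$quotients), tolerance = 1e-12)
  # cytoplasm masks are pairwise disjoint and disjoint from the patches
  masks <- lapply(tr$rois, function(r) polygonMask(roiPolygon(r), 256, 256))
  overlap <- Reduce(`+`, masks)
  expect_true(all(overlap <= 1))
  # measured areas equal the recorded true areas
  ds <- measureLevel(list(renders = list(sc), label = "g", covariate = 1))
  m <- measurements(ds)
  expect_equal(m$area_px[order(m$region_label)],
               tr$trueAreaPx[order(vapply(tr$rois[kinds == "cytoplasm"],
                                          roiLabel, character(1)))])
})

test_that("infeasible placements are refused", {
  expect_error(renderImage(syntheticSpec(seed = 1, width = 48, height = 48,
                                         nCells = 400L)),
               "infeasible placement")
})

test_that("RS series designs a linear mu trend and growing cell areas", {
  sp <- syntheticSpec(seed = 3, nCells = 20L, noiseSd = 0, ratioSigma = 0)
  lv <- simulateRsSeries(sp, c(34, 45, 56), muSlope = 0.08 / 11,
                         sizeSlope = 0.02, nCellsPerLevel = 20L)
  expect_equal(vapply(lv, `[[`, numeric(1), "trueMu"), c(0, 0.08, 0.16),
               tolerance = 1e-12)
  ds <- lapply(lv, measureLevel)
  areas <- vapply(ds, function(d) mean(measurements(d)$area_px), numeric(1))
  expect_true(all(diff(areas) > 0))
  means <- vapply(ds, function(d) summarizeCondition(d)$meanBGAV, numeric(1))
  expect_equal(means, c(0, 8, 16), tolerance = 0.15)  # sigma = 0, noiseless

  # zero slope: every level shares the designed mean
  lv0 <- simulateRsSeries(sp, c(34, 45), muSlope = 0, nCellsPerLevel = 10L)
  expect_equal(lv0[[1]]$trueMu, lv0[[2]]$trueMu)
  expect_error(simulateRsSeries(sp, 34, muSlope = 0), "at least 2")
})

test_that("dose response saturates and marks lethal doses", {
  expect_equal(sipsDoseShift(0, 0.3, 10), 0)
  expect_equal(sipsDoseShift(10, 0.3, 10), 0.15)  # half dose -> half max
  expect_equal(sipsDoseShift(1e9, 0.3, 10), 0.3, tolerance = 1e-6)
  expect_error(sipsDoseShift(-5, 0.3, 10), "non-negative")

  sp <- syntheticSpec(seed = 13, nCells = 10L)
  lv <- simulateSipsDoseResponse(sp, c(0, 5, 15, 25, 100), muMax = 0.25,
                                 halfDose = 8, nCellsPerLevel = 10L)
  shifts <- vapply(lv[1:4], `[[`, numeric(1), "trueMu")
  expect_true(all(diff(shifts) > 0))
  expect_true(all(diff(diff(shifts)) < 0))    # saturating curvature
  expect_true(isTRUE(lv[[5]]$noCells))         # 100 uM is lethal
  expect_error(measureLevel(lv[[5]]), "no cells")
  expect_error(simulateSipsDoseResponse(sp, c(-1, 5), 0.25, 8),
               "non-negative")
})

test_that("pH series enforces strictly decreasing amplitudes", {
  sp <- syntheticSpec(seed = 17, nCells = 6L, noiseSd = 0, ratioSigma = 0)
  expect_error(simulatePhSeries(sp, c(4, 5), c(40, 40), nCellsPerLevel = 6L),
               "strictly decreasing")
  expect_error(simulatePhSeries(sp, c(4, 5, 6), c(80, 40, 45),
                                nCellsPerLevel = 6L), "strictly decreasing")

  lv <- simulatePhSeries(sp, c(4, 5, 6), c(80, 40, 5), nCellsPerLevel = 1L)
  ds <- lapply(lv, measureLevel)
  means <- vapply(ds, function(d) summarizeCondition(d)$meanBGAV, numeric(1))
  # noiseless sigma-0 single-cell renders reproduce each amplitude
  expect_equal(means, c(80, 40, 5), tolerance = 0.2)
})

test_that("designed means are recovered across a mu/sigma grid", {
  # spot-check two corners here; the full grid runs in the acceptance suite
  for (p in list(c(0, 0.05), c(0.3, 0.15))) {
    sp <- syntheticSpec(seed = 57, ratioMu = p[1], ratioSigma = p[2])
    lvl <- list(label = "g", covariate = 1,
                renders = SABGquant:::renderLevel(sp, 250, 570))
    m <- measurements(measureLevel(lvl))
    se <- sd(m$bgav) / sqrt(nrow(m))
    expect_lt(abs(mean(m$bgav) - 100 * p[1]), 3 * se)
  }
})
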
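test_that("condition summaries use the sample SD and mean area", {
  expect_equal(summarizeCondition(conditionDataset("z", c(0, 0, 0))),
               list(meanBGAV = 0, sdBGAV = 0, n = 3, meanAreaPx = NA_real_),
               tolerance = 1e-14)
  s <- summarizeCondition(conditionDataset("h", c(1, 2, 3)))
  expect_equal(s$meanBGAV, 2)
  expect_equal(s$sdBGAV, 1)
  expect_equal(s$n, 3)

  set.seed(23)
  b <- rnorm(500, 10, 20)
  s2 <- summarizeCondition(conditionDataset("big", b))
  # two-pass loop oracle
  m <- kahanMean(b)
  expect_equal(s2$meanBGAV, m, tolerance = 1e-10)
  expect_equal(s2$sdBGAV, sqrt(kahanMean((b - m)^2) * 500 / 499),
               tolerance = 1e-10)
})

test_that("Shapiro-Wilk W is affine-invariant and rewards the log transform", {
  set.seed(29)
  x <- rnorm(500)
  w <- shapiroWilkW(x)
  expect_equal(testName(w), "shapiro_wilk_w")
  expect_gt(statistic(w), 0.99)
  expect_equal(statistic(shapiroWilkW(3.7 * x - 11)), statistic(w),
               tolerance = 1e-10)

  ratios <- exp(rnorm(500))   # log-normal CSI/BSI ratios
  expect_gt(statistic(shapiroWilkW(log(ratios))),
            statistic(shapiroWilkW(ratios)))

  expect_error(shapiroWilkW(c(1, 1, 1)), "zero variance")
  expect_error(shapiroWilkW(c(1, 2)), "at least 3")
})

test_that("KS D matches trivial cases and the brute-force ECDF oracle", {
  expect_equal(statistic(ksTwoSample(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(statistic(ksTwoSample(c(1, 2), c(10, 20))), 1)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  r <- ksTwoSample(a, b)
  expect_equal(statistic(r), ksDOracle(a, b))
  expect_equal(statistic(r), statistic(ksTwoSample(b, a)))  # symmetry
  expect_true(pValue(r) >= 0 && pValue(r) <= 1)

  set.seed(31)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(statistic(ksTwoSample(x, y)), ksDOracle(x, y),
               tolerance = 1e-12)
  expect_error(ksTwoSample(numeric(0), 1), "non-empty")
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  r0 <- anovaOneWay(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(statistic(r0), 0)
  expect_equal(pValue(r0), 1)

  g <- list(c(1, 2, 3), c(2, 4, 6), c(5, 6, 10))
  means <- sapply(g, mean); gm <- mean(unlist(g))
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  fHand <- (ssb / 2) / (ssw / 6)
  r <- anovaOneWay(g)
  expect_equal(statistic(r), fHand, tolerance = 1e-12)
  # cross-check against the stock fit
  ref <- stats::oneway.test(y ~ grp, data.frame(y = unlist(g),
                                                grp = factor(rep(1:3, each = 3))),
                            var.equal = TRUE)
  expect_equal(statistic(r), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pValue(r), ref$p.value, tolerance = 1e-12)

  # location invariance
  r2 <- anovaOneWay(lapply(g, `+`, 17.3))
  expect_equal(statistic(r2), statistic(r), tolerance = 1e-9)

  expect_error(anovaOneWay(list(c(1, 2, 3))), "at least 2")
  expect_error(anovaOneWay(list(c(1, 2), c(3))), "at least 2 observations")
  expect_error(anovaOneWay(list(c(5, 5), c(5, 5))), "degenerate")
})

test_that("Pearson chi-square follows the margin formula", {
  r0 <- pearsonChiSquare(rbind(c(10, 10), c(10, 10)))
  expect_equal(statistic(r0), 0)
  expect_equal(pValue(r0), 1)

  r <- pearsonChiSquare(rbind(c(20, 0), c(0, 20)))
  expect_equal(statistic(r), 40)
  expect_equal(r@details$df, 1)

  tab <- fociContingency(c("control", "DM"),
                         rbind(c(80, 15, 4, 1), c(35, 30, 22, 13)))
  r1 <- pearsonChiSquare(tab)
  perm <- tab@counts[, c(3, 1, 4, 2)]
  expect_equal(statistic(pearsonChiSquare(perm)), statistic(r1),
               tolerance = 1e-12)

  expect_error(pearsonChiSquare(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("Pearson correlation hits the exact linear cases and the loop oracle", {
  x <- c(1, 3, 4, 8)
  expect_equal(statistic(pearsonCorrelation(x, 2 * x + 1)), 1)
  expect_equal(statistic(pearsonCorrelation(x, -x)), -1)
  set.seed(37)
  a <- rnorm(60); b <- 0.4 * a + rnorm(60)
  ma <- kahanMean(a); mb <- kahanMean(b)
  rOracle <- kahanMean((a - ma) * (b - mb)) /
    sqrt(kahanMean((a - ma)^2) * kahanMean((b - mb)^2))
  expect_equal(statistic(pearsonCorrelation(a, b)), rOracle, tolerance = 1e-12)
  expect_true(is.na(pValue(pearsonCorrelation(a, b))))
  expect_error(pearsonCorrelation(c(1, 1, 1), 1:3), "constant")
  expect_error(pearsonCorrelation(1:4, 1:3), "equal length")
})

test_that("positivity uses a strict threshold at the control mean", {
  r <- classifyPositive(c(5, 10, 15), c(8, 10))  # control mean 9
  expect_equal(r$labels, c(FALSE, TRUE, TRUE))
  expect_equal(r$fraction, 2 / 3)

  # ties with the control mean are negative
  expect_equal(classifyPositive(c(9, 9, 9), c(8, 10))$fraction, 0)

  # invariance under a common shift
  set.seed(43)
  tb <- rnorm(50, 5); cb <- rnorm(30)
  expect_equal(classifyPositive(tb + 100, cb + 100)$fraction,
               classifyPositive(tb, cb)$fraction)

  # brute-force labelling oracle at a designed shift
  lab <- vapply(tb, function(v) v > mean(cb), logical(1))
  expect_equal(classifyPositive(tb, cb)$labels, lab)
})

test_that("trend analysis orders by covariate and flags the mean direction", {
  mk <- function(lb, cov, vals) conditionDataset(lb, vals, covariate = cov)
  up <- list(mk("a", 1, c(0.9, 1, 1.1)), mk("c", 3, c(2.9, 3, 3.1)),
             mk("b", 2, c(1.9, 2, 2.1)))
  r <- trendAcrossConditions(up)
  expect_equal(r$summaries$condition_label, c("a", "b", "c"))
  expect_equal(r$monotonicity, "non-decreasing")
  expect_equal(nrow(r$consecutiveKS), 2L)

  same <- list(mk("x", 1, c(1, 2, 3)), mk("y", 2, c(1, 2, 3)))
  r2 <- trendAcrossConditions(same)
  expect_true(all(r2$consecutiveKS$D == 0))

  down <- list(mk("a", 4, c(5, 6)), mk("b", 5, c(3, 4)), mk("c", 6, c(1, 2)))
  expect_equal(trendAcrossConditions(down)$monotonicity, "non-increasing")
  mixed <- list(mk("a", 1, c(1, 1)), mk("b", 2, c(5, 5)), mk("c", 3, c(2, 2)))
  expect_equal(trendAcrossConditions(mixed)$monotonicity, "neither")

  noCov <- list(conditionDataset("a", 1:3), conditionDataset("b", 2:4))
  expect_error(trendAcrossConditions(noCov), "covariate")
})

test_that("time-course peak and plateau detection scans correctly", {
  r <- timecoursePlateau(c(8, 16, 24, 40, 48), c(0, 5, 2, 2, 2), 0.1)
  expect_equal(r$peakTime, 16)
  expect_equal(r$plateauStart, 24)
  expect_true(r$plateau)

  r2 <- timecoursePlateau(c(1, 2, 3, 4), c(1, 2, 3, 4), 0.1)
  expect_equal(r2$peakTime, 4)
  expect_false(r2$plateau)
  expect_true(is.na(r2$plateauStart))

  # parabola-then-flat series vs an exhaustive scan oracle
  tms <- seq(2, 40, by = 2)
  mns <- c(-(seq(-5, 5))^2 + 25, rep(0, 9)) / 3
  tol <- 0.5
  got <- timecoursePlateau(tms, mns, tol)
  ok <- vapply(seq_len(length(tms) - 1L), function(i)
    all(abs(diff(mns[i:length(mns)])) <= tol), logical(1))
  expect_equal(got$plateauStart, tms[which(ok)[1]])
  expect_equal(got$peakTime, tms[which.max(mns)])

  expect_error(timecoursePlateau(c(1, 2), c(1, 2), 0.1), "at least 3")
  expect_error(timecoursePlateau(c(1, 2, 2), c(1, 2, 3), 0.1),
               "strictly increasing")
})
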
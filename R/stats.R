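asBgav <- function(x) {
  if (is(x, "ConditionDataset")) x@measurements$bgav else as.numeric(x)
}

#' Summarize one condition
#'
#' Mean and sample SD (n - 1 denominator) of the BGAVs in a condition, plus
#' sample size and mean region area -- the per-condition summary reported
#' for population-doubling, dose, pH and tissue comparisons.
#'
#' @param ds a \linkS4class{ConditionDataset}
#' @return list with \code{meanBGAV}, \code{sdBGAV}, \code{n},
#'   \code{meanAreaPx}
#' @examples
#' summarizeCondition(conditionDataset("demo", c(1, 2, 3)))
#' @export
summarizeCondition <- function(ds) {
  b <- ds@measurements$bgav
  n <- length(b)
  list(meanBGAV = mean(b),
       sdBGAV = if (n > 1) sd(b) else 0,
       n = n,
       meanAreaPx = mean(as.numeric(ds@measurements$area_px)))
}

#' Shapiro-Wilk normality statistic
#'
#' W in (0, 1]; the closer to 1 the better the agreement of the sample with
#' a normal distribution. Used to compare how normally CSI/BSI ratios versus
#' their log transform (BGAV) are distributed. W is invariant under affine
#' transforms of the sample.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not all equal
#' @return a \linkS4class{ComparisonResult} with \code{testName}
#'   \code{"shapiro_wilk_w"}
#' @export
shapiroWilkW <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 3L)
    stop("Shapiro-Wilk needs at least 3 observations")
  if (length(sample) > 5000L)
    stop("Shapiro-Wilk supports at most 5000 observations")
  if (diff(range(sample)) == 0)
    stop("zero variance: all sample values are identical")
  t <- stats::shapiro.test(sample)
  comparisonResult("shapiro_wilk_w", unname(t$statistic), t$p.value,
                   length(sample))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The preferred
#' comparison for BGAV distributions, which typically fail normality even
#' after the log transform. The p-value is exact when \code{min(n) <= 25}
#' (and the data are tie-free), asymptotic otherwise.
#'
#' @param a,b numeric samples, each non-empty
#' @return a \linkS4class{ComparisonResult} with \code{testName}
#'   \code{"ks_two_sample"}
#' @examples
#' ksTwoSample(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
ksTwoSample <- function(a, b) {
  a <- asBgav(a); b <- asBgav(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty")
  exact <- min(length(a), length(b)) <= 25L && !anyDuplicated(c(a, b))
  t <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  comparisonResult("ks_two_sample", unname(t$statistic), t$p.value,
                   c(length(a), length(b)),
                   details = list(exact = exact))
}

#' One-way ANOVA across conditions
#'
#' F statistic and p-value of the one-way variance decomposition of BGAVs,
#' as used to ask whether cell plating density shifts the mean BGAV.
#'
#' @param groups list of \linkS4class{ConditionDataset} objects or numeric
#'   vectors, each with n >= 2
#' @return a \linkS4class{ComparisonResult} with \code{testName}
#'   \code{"anova_one_way"}
#' @export
anovaOneWay <- function(groups) {
  if (length(groups) < 2L)
    stop("ANOVA needs at least 2 groups")
  vals <- lapply(groups, asBgav)
  ns <- lengths(vals)
  if (any(ns < 2L))
    stop("every group needs at least 2 observations")
  y <- unlist(vals, use.names = FALSE)
  gm <- mean(y)
  means <- vapply(vals, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(unlist(mapply(function(v, m) (v - m)^2, vals, means,
                           SIMPLIFY = FALSE)))
  dfb <- length(vals) - 1L
  dfw <- length(y) - length(vals)
  if (ssw == 0 && ssb == 0)
    stop("degenerate ANOVA: zero within-group and between-group variance")
  f <- (ssb / dfb) / (ssw / dfw)
  comparisonResult("anova_one_way", f, stats::pf(f, dfb, dfw, lower.tail = FALSE),
                   ns, details = list(dfBetween = dfb, dfWithin = dfw))
}

#' Pearson chi-square on a foci contingency table
#'
#' Compares the distribution of gamma-H2AX foci counts per nucleus between
#' two tissue groups; expected counts come from the row/column margins and
#' no continuity correction is applied.
#'
#' @param table a \linkS4class{FociContingency} or a counts matrix
#' @return a \linkS4class{ComparisonResult} with \code{testName}
#'   \code{"pearson_chi_square"}
#' @examples
#' pearsonChiSquare(rbind(c(20, 0), c(0, 20)))  # chi-square 40, df 1
#' @export
pearsonChiSquare <- function(table) {
  ct <- if (is(table, "FociContingency")) table@counts else as.matrix(table)
  if (any(rowSums(ct) == 0) || any(colSums(ct) == 0))
    stop("degenerate table: a row or column margin is zero")
  t <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  comparisonResult("pearson_chi_square", unname(t$statistic), t$p.value,
                   rowSums(ct), details = list(df = unname(t$parameter)))
}

#' Pearson correlation coefficient
#'
#' r in [-1, 1] between two paired series -- e.g. the percentage of
#' gamma-H2AX-positive nuclei against the fraction of SABG-positive tubules
#' across samples. No p-value is attached.
#'
#' @param x,y numeric vectors of equal length n >= 3, both non-constant
#' @return a \linkS4class{ComparisonResult} with \code{testName}
#'   \code{"pearson_correlation"} and \code{pValue = NA}
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    stop("correlation needs at least 3 pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("constant input: correlation undefined")
  comparisonResult("pearson_correlation", stats::cor(x, y), NA_real_,
                   length(x))
}

#' Classify tubules as SABG-positive against a control condition
#'
#' A tubule is positive when its BGAV is strictly greater than the mean BGAV
#' of the corresponding control tubules; ties with the control mean score
#' negative. The positive fraction is invariant under adding any constant to
#' all BGAVs.
#'
#' @param tubules a \linkS4class{ConditionDataset} (or numeric BGAVs) to
#'   classify
#' @param control the control \linkS4class{ConditionDataset} (or numeric
#'   BGAVs)
#' @return list with \code{labels} (logical per tubule), \code{fraction}
#'   (positive fraction) and \code{controlMean}
#' @examples
#' classifyPositive(c(5, 10, 15), c(8, 10))$fraction  # 2/3
#' @export
classifyPositive <- function(tubules, control) {
  tb <- asBgav(tubules); cb <- asBgav(control)
  if (length(tb) < 1L || length(cb) < 1L)
    stop("tubule and control sets must be non-empty")
  m <- mean(cb)
  labels <- tb > m
  list(labels = labels, fraction = mean(labels), controlMean = m)
}

#' Summaries and consecutive-pair KS tests along an ordered condition axis
#'
#' Orders conditions by covariate (PD, dose, pH, week), summarizes each,
#' tests every consecutive pair with the two-sample KS test, and flags the
#' direction of the mean trend. The flag uses non-strict comparisons (ties
#' allowed) because sampled means are noisy: \code{"non-decreasing"},
#' \code{"non-increasing"} or \code{"neither"}; an all-constant series is
#' reported \code{"non-decreasing"}.
#'
#' @param datasets list of \linkS4class{ConditionDataset}, each with a
#'   finite covariate
#' @return list with \code{summaries} (data.frame ordered by covariate),
#'   \code{consecutiveKS} (data.frame: pair labels, D, p) and
#'   \code{monotonicity}
#' @export
trendAcrossConditions <- function(datasets) {
  if (length(datasets) < 2L)
    stop("need at least 2 conditions")
  cov <- vapply(datasets, covariate, numeric(1))
  if (anyNA(cov))
    stop("every condition needs a covariate for trend analysis")
  datasets <- datasets[order(cov)]
  cov <- sort(cov)
  sm <- lapply(datasets, summarizeCondition)
  summaries <- data.frame(
    condition_label = vapply(datasets, conditionLabel, character(1)),
    covariate = cov,
    mean_bgav = vapply(sm, `[[`, numeric(1), "meanBGAV"),
    sd_bgav = vapply(sm, `[[`, numeric(1), "sdBGAV"),
    n = vapply(sm, `[[`, numeric(1), "n"),
    mean_area_px = vapply(sm, `[[`, numeric(1), "meanAreaPx"),
    stringsAsFactors = FALSE)
  ks <- lapply(seq_len(length(datasets) - 1L), function(i) {
    r <- ksTwoSample(datasets[[i]], datasets[[i + 1L]])
    data.frame(from = conditionLabel(datasets[[i]]),
               to = conditionLabel(datasets[[i + 1L]]),
               D = r@statistic, p_value = r@pValue, stringsAsFactors = FALSE)
  })
  dm <- diff(summaries$mean_bgav)
  flag <- if (all(dm >= 0)) "non-decreasing"
          else if (all(dm <= 0)) "non-increasing" else "neither"
  list(summaries = summaries, consecutiveKS = do.call(rbind, ks),
       monotonicity = flag)
}

#' Locate the post-staining peak and plateau of mean BGAVs
#'
#' Mean BGAV measured at increasing times after the staining reaction is
#' stopped rises to a peak and then settles; measurements are most reliable
#' once the plateau is reached. The peak is the argmax of the means; the
#' plateau starts at the earliest time after which every successive absolute
#' difference is at most \code{tolerance}. A series that never settles
#' returns \code{plateauStart = NA} with \code{plateau = FALSE} (not an
#' error).
#'
#' @param times strictly increasing times (hours), n >= 3
#' @param meanBgavs mean BGAV at each time
#' @param tolerance maximum successive change within the plateau
#' @return list with \code{peakTime}, \code{plateauStart}, \code{plateau}
#' @examples
#' timecoursePlateau(c(8, 16, 24, 40, 48), c(0, 5, 2, 2, 2), 0.1)
#' @export
timecoursePlateau <- function(times, meanBgavs, tolerance) {
  if (length(times) < 3L)
    stop("need at least 3 time points")
  if (length(times) != length(meanBgavs))
    stop("times and meanBgavs must have equal length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  peak <- times[which.max(meanBgavs)]
  d <- abs(diff(meanBgavs))
  n <- length(times)
  start <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (all(d[i:(n - 1L)] <= tolerance)) { start <- times[i]; break }
  }
  list(peakTime = peak, plateauStart = start, plateau = !is.na(start))
}
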
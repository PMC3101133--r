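#' Assemble a batch run configuration
#'
#' @param manifest data.frame with one row per image: columns \code{image}
#'   (path), \code{rois} (path), \code{condition_label}; optional
#'   \code{covariate}, \code{material} (\code{"culture"} or \code{"tissue"};
#'   selects the 250-cell vs 50-tubule under-count warning),
#'   \code{dialect} (ROI dialect per row), \code{hours_post_stain}
#'   (recorded, not enforced)
#' @param quant a \linkS4class{QuantConfig}
#' @param ksPairs \code{"consecutive"} (by covariate order), \code{"all"},
#'   \code{"none"}, or a list of condition-label pairs
#' @param anova run one-way ANOVA across all conditions
#' @param controlLabel condition label of the control group; enables the
#'   tubule positivity classification of every other condition against it
#' @param trend run the ordered-condition trend analysis (needs covariates)
#' @param seed seed recorded in the report (simulation is the only
#'   stochastic stage; measurement is deterministic)
#' @return a \code{runConfig} list
#' @export
runConfig <- function(manifest, quant = quantConfig(),
                      ksPairs = "consecutive", anova = FALSE,
                      controlLabel = NULL, trend = TRUE, seed = 1L) {
  need <- c("image", "rois", "condition_label")
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("configuration error: empty manifest")
  if (!all(need %in% names(manifest)))
    stop(sprintf("configuration error: manifest lacks columns %s",
                 paste(setdiff(need, names(manifest)), collapse = ", ")))
  if (any(!nzchar(manifest$condition_label) | is.na(manifest$condition_label)))
    stop("configuration error: condition labels must be non-empty")
  for (col in c("image", "rois")) {
    miss <- !file.exists(manifest[[col]])
    if (any(miss))
      stop(sprintf("configuration error: %s file '%s' does not exist",
                   col, manifest[[col]][miss][1]))
  }
  if (!is.null(controlLabel) && !(controlLabel %in% manifest$condition_label))
    stop(sprintf("configuration error: control label '%s' names no condition",
                 controlLabel))
  if (is.null(manifest$covariate)) manifest$covariate <- NA_real_
  if (is.null(manifest$material)) manifest$material <- "culture"
  if (is.null(manifest$dialect)) manifest$dialect <- "auto"
  list(manifest = manifest, quant = quant, ksPairs = ksPairs, anova = anova,
       controlLabel = controlLabel, trend = trend, seed = as.integer(seed))
}

measureManifest <- function(manifest, quant) {
  conds <- unique(manifest$condition_label)
  datasets <- list(); warnings <- character(0); errors <- list()
  allMeasurements <- list()
  for (cond in conds) {
    rows <- manifest[manifest$condition_label == cond, , drop = FALSE]
    images <- lapply(rows$image, readRGBImage)
    rois <- lapply(seq_len(nrow(rows)),
                   function(i) readRois(rows$rois[i], rows$dialect[i]))
    material <- rows$material[1]
    qc <- quant
    qc@minCellsWarn <- if (identical(material, "tissue")) 50L
                       else quant@minCellsWarn
    res <- measureBatch(images, rois, qc)
    m <- res$measurements
    m$condition_label <- cond
    m$covariate <- rows$covariate[1]
    allMeasurements[[cond]] <- m
    if (nrow(m) > 0L)
      datasets[[cond]] <- conditionDataset(cond, m, covariate = rows$covariate[1])
    if (length(res$warnings))
      warnings <- c(warnings, sprintf("[%s] %s", cond, res$warnings))
    if (nrow(res$errors))
      errors[[cond]] <- res$errors
  }
  list(datasets = datasets,
       measurements = do.call(rbind, c(allMeasurements, list(make.row.names = FALSE))),
       warnings = warnings,
       errors = if (length(errors)) do.call(rbind, c(errors, list(make.row.names = FALSE)))
                else NULL)
}

comparisonRow <- function(test, groups, r) {
  data.frame(test = test, groups = groups, statistic = r@statistic,
             p_value = r@pValue, n = paste(r@nPerGroup, collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Compare a set of measured conditions
#'
#' The statistical layer of the pipeline, applied to already-measured
#' datasets: per-condition summaries, the requested pairwise KS tests,
#' optional one-way ANOVA, optional positivity classification against a
#' control condition, and the ordered trend analysis.
#'
#' @param datasets named list of \linkS4class{ConditionDataset}
#' @inheritParams runConfig
#' @return list with \code{summaries}, \code{comparisons}, \code{positivity},
#'   \code{trend}
#' @export
compareConditions <- function(datasets, ksPairs = "consecutive",
                              anova = FALSE, controlLabel = NULL,
                              trend = TRUE) {
  if (length(datasets) == 0L)
    stop("no datasets to compare")
  labs <- vapply(datasets, conditionLabel, character(1))
  names(datasets) <- labs
  sm <- lapply(datasets, summarizeCondition)
  summaries <- data.frame(
    condition_label = labs,
    covariate = vapply(datasets, covariate, numeric(1)),
    mean_bgav = vapply(sm, `[[`, numeric(1), "meanBGAV"),
    sd_bgav = vapply(sm, `[[`, numeric(1), "sdBGAV"),
    n = vapply(sm, `[[`, numeric(1), "n"),
    mean_area_px = vapply(sm, `[[`, numeric(1), "meanAreaPx"),
    row.names = NULL, stringsAsFactors = FALSE)

  pairs <- list()
  if (identical(ksPairs, "consecutive")) {
    ord <- order(summaries$covariate, summaries$condition_label)
    if (length(ord) >= 2L)
      pairs <- lapply(seq_len(length(ord) - 1L),
                      function(i) labs[ord[c(i, i + 1L)]])
  } else if (identical(ksPairs, "all")) {
    if (length(labs) >= 2L)
      pairs <- utils::combn(sort(labs), 2L, simplify = FALSE)
  } else if (is.list(ksPairs)) {
    pairs <- ksPairs
  }
  comparisons <- list()
  for (p in pairs) {
    if (!all(p %in% labs))
      stop(sprintf("KS pair (%s) names an unknown condition",
                   paste(p, collapse = ", ")))
    r <- ksTwoSample(datasets[[p[1]]], datasets[[p[2]]])
    comparisons[[length(comparisons) + 1L]] <-
      comparisonRow("ks_two_sample", paste(p, collapse = " vs "), r)
  }
  if (anova && length(datasets) >= 2L) {
    r <- anovaOneWay(datasets)
    comparisons[[length(comparisons) + 1L]] <-
      comparisonRow("anova_one_way", paste(sort(labs), collapse = " + "), r)
  }
  positivity <- NULL
  if (!is.null(controlLabel)) {
    if (!(controlLabel %in% labs))
      stop(sprintf("configuration error: control label '%s' names no condition",
                   controlLabel))
    others <- setdiff(labs, controlLabel)
    rows <- lapply(c(controlLabel, others), function(lb) {
      cl <- classifyPositive(datasets[[lb]], datasets[[controlLabel]])
      data.frame(condition_label = lb, fraction_positive = cl$fraction,
                 n = length(cl$labels), control_mean = cl$controlMean,
                 stringsAsFactors = FALSE)
    })
    positivity <- do.call(rbind, rows)
  }
  trendRes <- NULL
  if (trend && length(datasets) >= 2L &&
      !anyNA(vapply(datasets, covariate, numeric(1)))) {
    trendRes <- trendAcrossConditions(datasets)
  }
  list(summaries = summaries,
       comparisons = if (length(comparisons)) do.call(rbind, comparisons)
                     else NULL,
       positivity = positivity, trend = trendRes)
}

#' Run the full measure-summarize-compare pipeline
#'
#' Reads every image and ROI set in the manifest, measures all cytoplasm and
#' tubule regions against their paired backgrounds, summarizes each
#' condition, and runs the configured comparisons. Per-ROI failures are
#' reported in the result, not fatal; configuration problems abort before
#' any computation. For fixed input files the report is deterministic.
#'
#' @param config a \code{\link{runConfig}}
#' @return a run-report list: \code{summaries}, \code{comparisons},
#'   \code{positivity}, \code{trend}, \code{measurements}, \code{warnings},
#'   \code{errors}, \code{version}, \code{config} (echo)
#' @export
runPipeline <- function(config) {
  meas <- measureManifest(config$manifest, config$quant)
  cmp <- compareConditions(meas$datasets, ksPairs = config$ksPairs,
                           anova = config$anova,
                           controlLabel = config$controlLabel,
                           trend = config$trend)
  list(summaries = cmp$summaries, comparisons = cmp$comparisons,
       positivity = cmp$positivity, trend = cmp$trend,
       measurements = meas$measurements, warnings = meas$warnings,
       errors = meas$errors,
       version = as.character(utils::packageVersion("SABGquant")),
       config = list(bgavScale = config$quant@bgavScale,
                     zeroPixelPolicy = config$quant@zeroPixelPolicy,
                     csiMode = config$quant@csiMode,
                     ksPairs = config$ksPairs, anova = config$anova,
                     controlLabel = config$controlLabel,
                     trend = config$trend, seed = config$seed))
}

#' Serialize a run report
#'
#' Writes \code{measurements.csv}, \code{summary.csv}, \code{comparisons.csv}
#' (when present) and \code{report.json} into a directory. Output is
#' byte-deterministic for a fixed report (no timestamps).
#'
#' @param report as returned by \code{\link{runPipeline}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$measurements) && nrow(report$measurements))
    writeMeasurements(report$measurements, file.path(dir, "measurements.csv"))
  utils::write.csv(report$summaries, file.path(dir, "summary.csv"),
                   row.names = FALSE, eol = "\n")
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE, eol = "\n")
  json <- report[c("summaries", "comparisons", "positivity", "warnings",
                   "version", "config")]
  if (!is.null(report$trend))
    json$trend <- list(monotonicity = report$trend$monotonicity,
                       consecutiveKS = report$trend$consecutiveKS)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
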
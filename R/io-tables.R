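MEASUREMENT_COLUMNS <- c("image_id", "region_label", "kind", "area_px",
                         "csi", "bsi", "bgav", "excluded_pixels",
                         "condition_label", "covariate")

#' Write a measurement table
#'
#' RFC-4180 CSV, UTF-8, '.' decimal separator, LF line endings; numeric
#' fields are written with 17 significant digits so a read-back reproduces
#' every double bit-exactly. The column set and order are fixed:
#' \code{image_id, region_label, kind, area_px, csi, bsi, bgav,
#' excluded_pixels, condition_label, covariate}.
#'
#' @param measurements data.frame as produced by \code{\link{measureBatch}}
#' @param path destination .csv path
#' @return \code{path}, invisibly
#' @export
writeMeasurements <- function(measurements, path) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(measurements))
  if (length(missing))
    stop(sprintf("measurement table lacks columns: %s",
                 paste(missing, collapse = ", ")))
  df <- measurements[MEASUREMENT_COLUMNS]
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out <- data.frame(image_id = df$image_id, region_label = df$region_label,
                    kind = df$kind, area_px = as.integer(df$area_px),
                    csi = fmt(df$csi), bsi = fmt(df$bsi),
                    bgav = fmt(df$bgav),
                    excluded_pixels = as.integer(df$excluded_pixels),
                    condition_label = df$condition_label,
                    covariate = fmt(df$covariate), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "", eol = "\n",
                   quote = which(names(out) %in%
                                   c("image_id", "region_label", "kind",
                                     "condition_label")))
  invisible(path)
}

#' Read a measurement table
#'
#' Inverse of \code{\link{writeMeasurements}}; rejects files that do not
#' carry the fixed column set.
#'
#' @param path .csv path
#' @return data.frame with the fixed measurement columns
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read measurements: file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(image_id = "character",
                                       region_label = "character",
                                       kind = "character",
                                       area_px = "integer",
                                       csi = "numeric", bsi = "numeric",
                                       bgav = "numeric",
                                       excluded_pixels = "integer",
                                       condition_label = "character",
                                       covariate = "numeric"))
  if (!identical(names(df), MEASUREMENT_COLUMNS))
    stop(sprintf("'%s' is not a measurement table (expected columns: %s)",
                 path, paste(MEASUREMENT_COLUMNS, collapse = ", ")))
  bad <- !is.finite(df$bgav) | !is.finite(df$csi) | !is.finite(df$bsi)
  if (any(bad))
    stop(sprintf("'%s' line %d: non-finite measurement values", path,
                 which(bad)[1] + 1L))
  df
}

#' Read a gamma-H2AX foci contingency table
#'
#' Two-row CSV: a \code{group} column followed by foci-count category
#' columns \code{foci_0}, \code{foci_1}, ..., \code{foci_k} holding nuclei
#' counts.
#'
#' @param path .csv path
#' @return a \linkS4class{FociContingency}
#' @export
readFociContingency <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read contingency table: '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "group" || nrow(df) != 2L)
    stop(sprintf("'%s' must have a 'group' column and exactly two rows", path))
  cat_cols <- grep("^foci_[0-9]+$", names(df), value = TRUE)
  if (length(cat_cols) < 2L)
    stop(sprintf("'%s' needs at least two foci_<k> columns", path))
  cat_cols <- cat_cols[order(as.integer(sub("foci_", "", cat_cols)))]
  counts <- as.matrix(df[cat_cols])
  if (any(is.na(counts)) || any(counts != round(counts)) || any(counts < 0))
    stop(sprintf("'%s': foci counts must be non-negative integers", path))
  fociContingency(df$group, counts)
}

#' Write a gamma-H2AX foci contingency table
#'
#' @param table a \linkS4class{FociContingency}
#' @param path destination .csv path
#' @return \code{path}, invisibly
#' @export
writeFociContingency <- function(table, path) {
  df <- data.frame(group = table@groups, table@counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, eol = "\n", quote = 1L)
  invisible(path)
}
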
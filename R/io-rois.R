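# ---- CSV polygon dialect ---------------------------------------------------
# Columns: region_label, kind, paired_background, vertex_index, x, y
# One row per vertex; vertices of one region contiguous and ordered by
# vertex_index; 0-based pixel-centre coordinates.

#' Read a region-of-interest set
#'
#' Supported dialects: \code{"csv_polygon"} (the package's documented CSV,
#' one row per vertex with columns \code{region_label}, \code{kind},
#' \code{paired_background}, \code{vertex_index}, \code{x}, \code{y});
#' \code{"imagej_roi"} (a single binary ImageJ .roi file);
#' \code{"imagej_roi_zip"} (an ImageJ RoiSet zip). \code{"auto"} picks by
#' file extension.
#'
#' ImageJ files carry no kind/pairing metadata: the kind is inferred from
#' the ROI name (\code{bg}/\code{back} prefix = background, \code{tub} =
#' tubule, \code{nuc} = nucleus, anything else = cytoplasm) and pairing is
#' left to the nearest-centroid rule. ImageJ integer vertices address pixel
#' corners and are shifted by -0.5 on import to the pixel-centre
#' convention; polygon, freehand, traced, rectangle and oval ROIs are
#' supported (ovals become 64-gons).
#'
#' @param path file path
#' @param dialect \code{"auto"}, \code{"csv_polygon"}, \code{"imagej_roi"}
#'   or \code{"imagej_roi_zip"}
#' @return list of \linkS4class{RegionOfInterest}
#' @export
readRois <- function(path, dialect = c("auto", "csv_polygon", "imagej_roi",
                                       "imagej_roi_zip")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("cannot read ROIs: file '%s' does not exist", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv_polygon", roi = "imagej_roi",
                      zip = "imagej_roi_zip",
                      stop(sprintf("cannot infer ROI dialect from '%s'", path)))
  }
  switch(dialect,
         csv_polygon = readRoisCsv(path),
         imagej_roi = list(readImageJRoi(path)),
         imagej_roi_zip = readImageJRoiZip(path))
}

#' Write a region-of-interest set
#'
#' @param rois list of \linkS4class{RegionOfInterest}
#' @param path destination path
#' @param dialect \code{"csv_polygon"}, \code{"imagej_roi_zip"}, or
#'   \code{"auto"} (by extension). ImageJ output stores each polygon under
#'   its label; kind and explicit pairing are not representable there (see
#'   \code{\link{readRois}}).
#' @return \code{path}, invisibly
#' @export
writeRois <- function(rois, path, dialect = c("auto", "csv_polygon",
                                              "imagej_roi_zip")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv_polygon", zip = "imagej_roi_zip",
                      stop(sprintf("cannot infer ROI dialect from '%s'", path)))
  }
  if (dialect == "csv_polygon") writeRoisCsv(rois, path)
  else writeImageJRoiZip(rois, path)
  invisible(path)
}

readRoisCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_label = "character",
                                       kind = "character",
                                       paired_background = "character",
                                       vertex_index = "integer",
                                       x = "numeric", y = "numeric"),
                        na.strings = "")
  need <- c("region_label", "kind", "paired_background", "vertex_index",
            "x", "y")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' is not csv_polygon: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  # regions must be contiguous blocks
  runs <- rle(df$region_label)
  if (anyDuplicated(runs$values))
    stop(sprintf("'%s': vertices of region '%s' are not contiguous", path,
                 runs$values[duplicated(runs$values)][1]))
  idx <- split(seq_len(nrow(df)), factor(df$region_label,
                                         levels = runs$values))
  labels <- runs$values
  rois <- lapply(seq_along(idx), function(i) {
    rows <- df[idx[[i]], ]
    first <- idx[[i]][1]
    if (is.unsorted(rows$vertex_index, strictly = TRUE))
      stop(sprintf("'%s' line %d: vertex_index of region '%s' is not strictly increasing",
                   path, first + 1L, labels[i]))
    if (length(unique(rows$kind)) != 1L || !(rows$kind[1] %in% ROI_KINDS))
      stop(sprintf("'%s' line %d: region '%s' has an unknown or inconsistent kind",
                   path, first + 1L, labels[i]))
    if (nrow(rows) < 3L)
      stop(sprintf("'%s' line %d: region '%s' has fewer than 3 vertices",
                   path, first + 1L, labels[i]))
    pb <- unique(rows$paired_background)
    if (length(pb) != 1L)
      stop(sprintf("'%s' line %d: region '%s' has inconsistent paired_background",
                   path, first + 1L, labels[i]))
    ROI(labels[i], rows$kind[1], cbind(rows$x, rows$y), pb)
  })
  # dangling pairings
  labset <- vapply(rois, roiLabel, character(1))
  for (r in rois) {
    if (!is.na(r@pairedBackground) && !(r@pairedBackground %in% labset))
      stop(sprintf("'%s': region '%s' pairs to unknown background '%s'",
                   path, r@label, r@pairedBackground))
  }
  rois
}

writeRoisCsv <- function(rois, path) {
  rows <- lapply(rois, function(r) {
    n <- nrow(r@polygon)
    data.frame(region_label = rep(r@label, n), kind = rep(r@kind, n),
               paired_background = rep(r@pairedBackground, n),
               vertex_index = seq_len(n) - 1L,
               x = sprintf("%.17g", r@polygon[, 1]),
               y = sprintf("%.17g", r@polygon[, 2]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = 1:3,
                   eol = "\n")
  invisible(path)
}

# ---- ImageJ binary .roi ----------------------------------------------------
# Big-endian; 64-byte header, coordinates as shorts relative to the bounding
# box, optional 64-byte second header pointing at a UTF-16 name.

IJ_TYPE <- c(polygon = 0L, rect = 1L, oval = 2L, freehand = 7L, traced = 8L)

readImageJRoi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  decodeImageJRoi(raw, label = sub("\\.roi$", "", basename(path),
                                   ignore.case = TRUE))
}

int16be <- function(raw, off) {  # 0-based offset, unsigned short
  as.integer(raw[off + 1L]) * 256L + as.integer(raw[off + 2L])
}
int32be <- function(raw, off) {
  sum(as.integer(raw[off + 1:4]) * c(16777216, 65536, 256, 1))
}

decodeImageJRoi <- function(raw, label) {
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop(sprintf("'%s' is not an ImageJ ROI file", label))
  type <- as.integer(raw[7L])
  top <- int16be(raw, 8L); left <- int16be(raw, 10L)
  bottom <- int16be(raw, 12L); right <- int16be(raw, 14L)
  n <- int16be(raw, 16L)
  hdr2 <- int32be(raw, 60L)
  name <- label
  if (hdr2 > 0L && hdr2 + 64L <= length(raw)) {
    nameOff <- int32be(raw, hdr2 + 16L)
    nameLen <- int32be(raw, hdr2 + 20L)
    if (nameOff > 0L && nameLen > 0L && nameOff + 2L * nameLen <= length(raw)) {
      chars <- vapply(seq_len(nameLen),
                      function(i) int16be(raw, nameOff + 2L * (i - 1L)),
                      integer(1))
      name <- intToUtf8(chars)
    }
  }
  if (type %in% c(IJ_TYPE[["polygon"]], IJ_TYPE[["freehand"]],
                  IJ_TYPE[["traced"]])) {
    if (n < 3L)
      stop(sprintf("ImageJ ROI '%s' has fewer than 3 vertices", name))
    xs <- vapply(seq_len(n), function(i) int16be(raw, 64L + 2L * (i - 1L)),
                 integer(1))
    ys <- vapply(seq_len(n), function(i) int16be(raw, 64L + 2L * (n + i - 1L)),
                 integer(1))
    poly <- cbind(left + xs - 0.5, top + ys - 0.5)
  } else if (type == IJ_TYPE[["rect"]]) {
    poly <- cbind(c(left, right, right, left) - 0.5,
                  c(top, top, bottom, bottom) - 0.5)
  } else if (type == IJ_TYPE[["oval"]]) {
    a <- (right - left) / 2; b <- (bottom - top) / 2
    poly <- ellipsePolygon(left + a - 0.5, top + b - 0.5, a, b)
  } else {
    stop(sprintf("unsupported ImageJ ROI type %d in '%s'", type, name))
  }
  ROI(name, kindFromName(name), poly)
}

kindFromName <- function(name) {
  low <- tolower(name)
  if (grepl("^(bg|back)", low)) "background"
  else if (grepl("^tub", low)) "tubule"
  else if (grepl("^nuc", low)) "nucleus"
  else "cytoplasm"
}

raw16be <- function(x) {
  x <- as.integer(round(x)) %% 65536L
  as.raw(as.vector(rbind(x %/% 256L, x %% 256L)))
}
raw32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

encodeImageJRoi <- function(roi) {
  # ImageJ corner coordinates = pixel-centre coordinates + 0.5
  xs <- round(roi@polygon[, 1] + 0.5)
  ys <- round(roi@polygon[, 2] + 0.5)
  left <- min(xs); top <- min(ys)
  n <- length(xs)
  name <- roi@label
  hdr <- raw(64L)
  hdr[1:4] <- charToRaw("Iout")
  hdr[5:6] <- raw16be(228L)
  hdr[7L] <- as.raw(IJ_TYPE[["polygon"]])
  hdr[9:10] <- raw16be(top)
  hdr[11:12] <- raw16be(left)
  hdr[13:14] <- raw16be(max(ys))
  hdr[15:16] <- raw16be(max(xs))
  hdr[17:18] <- raw16be(n)
  hdr2off <- 64L + 4L * n
  hdr[61:64] <- raw32be(hdr2off)
  coords <- c(raw16be(xs - left), raw16be(ys - top))
  hdr2 <- raw(64L)
  nameOff <- hdr2off + 64L
  hdr2[17:20] <- raw32be(nameOff)
  hdr2[21:24] <- raw32be(nchar(name))
  c(hdr, coords, hdr2, raw16be(utf8ToInt(name)))
}

writeImageJRoi <- function(roi, path) {
  writeBin(encodeImageJRoi(roi), path)
  invisible(path)
}

readImageJRoiZip <- function(path) {
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
  if (length(files) == 0L)
    stop(sprintf("'%s' contains no .roi entries", path))
  lapply(files, readImageJRoi)
}

writeImageJRoiZip <- function(rois, path) {
  entries <- lapply(rois, function(r)
    list(name = paste0(r@label, ".roi"), data = encodeImageJRoi(r)))
  writeStoredZip(entries, path)
  invisible(path)
}

# ---- minimal stored-entry ZIP writer ---------------------------------------

crc32Table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320
      else bitwShiftR(c, 1)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   crc32Table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

raw32le <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           x %/% 16777216))
}
raw16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))

writeStoredZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crc <- crc32(e$data)
    crcU <- if (crc < 0) crc + 4294967296 else crc
    local <- c(charToRaw("PK"), as.raw(c(3, 4)), raw16le(20L), raw16le(0L),
               raw16le(0L), raw16le(0L), raw16le(0x21), raw32le(crcU),
               raw32le(length(e$data)), raw32le(length(e$data)),
               raw16le(length(nm)), raw16le(0L), nm, e$data)
    offsets[i] <- pos
    writeBin(local, con)
    pos <- pos + length(local)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crc <- crc32(e$data)
    crcU <- if (crc < 0) crc + 4294967296 else crc
    central <- c(charToRaw("PK"), as.raw(c(1, 2)), raw16le(20L), raw16le(20L),
                 raw16le(0L), raw16le(0L), raw16le(0L), raw16le(0x21),
                 raw32le(crcU), raw32le(length(e$data)),
                 raw32le(length(e$data)), raw16le(length(nm)), raw16le(0L),
                 raw16le(0L), raw16le(0L), raw16le(0L), raw32le(0),
                 raw32le(offsets[i]), nm)
    writeBin(central, con)
    pos <- pos + length(central)
  }
  eocd <- c(charToRaw("PK"), as.raw(c(5, 6)), raw16le(0L), raw16le(0L),
            raw16le(length(entries)), raw16le(length(entries)),
            raw32le(pos - cdStart), raw32le(cdStart), raw16le(0L))
  writeBin(eocd, con)
  invisible(path)
}
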
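#' Read an RGB micrograph
#'
#' Reads TIFF, PNG or JPEG into an \linkS4class{RGBImage} with the bit depth
#' inferred from the file (8 or 16). Grayscale files are rejected; an alpha
#' channel is dropped with a warning. JPEG input is accepted but always
#' triggers a lossy-compression warning, since chroma subsampling perturbs
#' exactly the colour ratios this analysis measures.
#'
#' @param path file path (.tif/.tiff, .png, .jpg/.jpeg)
#' @return an \linkS4class{RGBImage} with \code{id} set to the file name
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e)
                      stop(sprintf("format error in '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    vals <- round(arr * (2^depth - 1))
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e)
                      stop(sprintf("format error in '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
    depth <- pngBitDepth(path)
    vals <- round(arr * (2^depth - 1))
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- tryCatch(jpeg::readJPEG(path),
                    error = function(e)
                      stop(sprintf("format error in '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
    warning(sprintf("'%s' is JPEG: lossy compression perturbs chromatic ratios",
                    basename(path)))
    depth <- 8L
    vals <- round(arr * 255)
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
  d <- dim(vals)
  if (length(d) != 3L || d[3] < 3L)
    stop(sprintf("format error in '%s': need 3 colour channels, found %s",
                 path, if (length(d) == 2L) "a grayscale image" else d[3]))
  if (d[3] > 3L) {
    warning(sprintf("'%s': alpha channel dropped", basename(path)))
    vals <- vals[, , 1:3, drop = FALSE]
  }
  vals <- array(as.numeric(vals), dim = dim(vals))
  RGBImage(vals, bitDepth = as.integer(depth), id = basename(path))
}

# bit depth from the PNG IHDR chunk (byte 25 of the file)
pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])
}

#' Write an RGBImage to disk
#'
#' PNG (8-bit) or TIFF (8- or 16-bit, matching the image's bit depth).
#' Pixel values are rounded to integers on write; round-trips are lossless
#' for integer-valued images. JPEG output is refused (lossy).
#'
#' @param image an \linkS4class{RGBImage}
#' @param path destination (.png or .tif/.tiff)
#' @return \code{path}, invisibly
#' @export
writeRGBImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  maxval <- 2^image@bitDepth - 1
  arr <- round(image@pixels) / maxval
  if (ext == "png") {
    if (image@bitDepth != 8L)
      stop("PNG output is 8-bit; write 16-bit images as TIFF")
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = image@bitDepth)
  } else {
    stop(sprintf("unsupported output format '%s' (use png or tiff)", ext))
  }
  invisible(path)
}
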
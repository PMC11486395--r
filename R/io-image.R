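#' Read a microscopy image
#'
#' Reads a PNG or JPEG into an \linkS4class{ImageRaster}. The pixel size is
#' always user-supplied; image metadata is never trusted for it.
#'
#' @param path PNG or JPEG file.
#' @param pixelSize micrometres per pixel of the raw image (> 0).
#' @param name source label (defaults to the file name).
#' @return An \linkS4class{ImageRaster} with intensities in [0, 1].
#' @export
readImage <- function(path, pixelSize, name = basename(path)) {
  if (!is.numeric(pixelSize) || length(pixelSize) != 1L || pixelSize <= 0)
    stop("validation error: pixelSize must be a single positive number")
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg"))
    stop("format error: unsupported image format '.", ext,
         "' (accepted: .png, .jpeg)")
  img <- EBImage::readImage(path)
  ImageRaster(as.array(img), pixelSize, name)
}

# JPEG re-encode at quality 95 for bundle export.
.writeImageJpeg <- function(image, path, quality = 95) {
  px <- image@pixels
  img <- EBImage::Image(px, colormode = if (length(dim(px)) == 3L)
    "Color" else "Grayscale")
  EBImage::writeImage(img, path, type = "jpeg", quality = quality)
  invisible(path)
}

#' Convert an image to grayscale intensities
#'
#' Channel mean for colour images; identity for grayscale.
#'
#' @param image an \linkS4class{ImageRaster}.
#' @return numeric matrix (x by y) of intensities.
#' @export
grayscale <- function(image) {
  stopifnot(is(image, "ImageRaster"))
  px <- image@pixels
  if (length(dim(px)) == 3L) {
    out <- px[, , 1]
    for (k in seq_len(dim(px)[3])[-1]) out <- out + px[, , k]
    out / dim(px)[3]
  } else {
    px
  }
}
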
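#' Derive a binary tissue mask from a histology image
#'
#' Grayscale conversion, automatic global (Otsu) threshold with the darker
#' side taken as tissue (stains such as H&E are darker than the slide
#' background), then retention of the largest connected component and hole
#' filling. The mask construction is a documented reconstruction of a step
#' the overlap metric needs but that has no canonical definition; the
#' threshold rule is recorded in the returned object. Set
#' `darkTissue = FALSE` for polarity-inverted images (e.g. fluorescence):
#' the mask of an inverted image with the flag flipped is identical.
#'
#' A blank image (a single intensity everywhere) yields an empty mask with
#' a warning.
#'
#' @param image an \linkS4class{ImageRaster} with intensities in [0, 1].
#' @param darkTissue logical; take the darker (TRUE) or brighter side as
#'   tissue.
#' @return A \linkS4class{TissueMask} aligned to the image grid.
#' @export
tissueMask <- function(image, darkTissue = TRUE) {
  stopifnot(is(image, "ImageRaster"))
  gray <- grayscale(image)
  if (diff(range(gray)) == 0) {
    warning("degenerate mask: image has a single intensity")
    return(new("TissueMask",
               mask = matrix(FALSE, nrow(gray), ncol(gray)),
               threshold = NA_real_, darkTissue = darkTissue))
  }
  if (!darkTissue) gray <- 1 - gray
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labArr <- as.array(lab)
  sizes <- tabulate(labArr[labArr > 0])
  if (length(sizes)) {
    mask <- labArr == which.max(sizes)
    mask <- as.array(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  new("TissueMask", mask = mask, threshold = as.numeric(thr),
      darkTissue = darkTissue)
}

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask: %d x %d px, %.1f%% tissue (threshold %s)\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask),
              if (is.na(object@threshold)) "NA" else
                sprintf("%.3f", object@threshold)))
  invisible(NULL)
})

#' Percent overlap of data points with a tissue mask
#'
#' Fraction (in percent) of points whose display coordinates fall on a
#' tissue pixel of the mask, plus the identifiers of the non-overlapping
#' points for flagging. Points and mask must share the display space: a
#' point at `(x, y)` (display pixels, y-up with row 1 of the image at the
#' top edge) falls on image column `floor(x) + 1` and row
#' `height - floor(y)`. Points outside the image bounds count as
#' non-overlapping (not an error).
#'
#' @param points a \linkS4class{PointSet} in display coordinates.
#' @param mask a \linkS4class{TissueMask} on the registered image grid.
#' @return List with `percent` (0..100) and `nonOverlappingIds`.
#' @export
overlapPercent <- function(points, mask) {
  stopifnot(is(points, "PointSet"), is(mask, "TissueMask"))
  W <- nrow(mask@mask)
  H <- ncol(mask@mask)
  i <- floor(points@coords[, 1]) + 1
  j <- H - floor(points@coords[, 2])
  inside <- i >= 1 & i <= W & j >= 1 & j <= H
  on <- logical(nPoints(points))
  on[inside] <- mask@mask[cbind(i[inside], j[inside])]
  list(percent = 100 * mean(on),
       nonOverlappingIds = points@ids[!on])
}
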
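# Rigid-transform primitives. All angles are degrees, counterclockwise
# positive in a y-up Cartesian display frame; cospi/sinpi keep the cardinal
# angles exact.

.rotateAbout <- function(xy, thetaDeg, center) {
  cs <- cospi(thetaDeg / 180)
  sn <- sinpi(thetaDeg / 180)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  cbind(x = dx * cs - dy * sn + center[1],
        y = dx * sn + dy * cs + center[2])
}

.mirrorAbout <- function(xy, axis, center) {
  if (axis == "vertical") {
    xy[, 1] <- center[1] + (center[1] - xy[, 1])
  } else {
    xy[, 2] <- center[2] + (center[2] - xy[, 2])
  }
  xy
}

#' Rigid transforms and scaling
#'
#' `computeCenter` returns the centre of the axis-aligned bounding box of
#' all points (visible and invisible alike); it is the fixed rotation/flip
#' pivot of a registration session. `scalePoints` converts raw coordinates
#' to display pixels by `coord * dataScale / displayScale`, so that one
#' display pixel spans `displayScale` micrometres and physical extents in
#' micrometres are conserved. `scaleImage` applies the same
#' micrometre-conserving rule to the image width/height and resamples the
#' pixel content.
#'
#' @param points a \linkS4class{PointSet} (or a coordinate matrix for
#'   `computeCenter`).
#' @return `computeCenter`: numeric length-2 `(x, y)`.
#' @name transforms
#' @examples
#' ps <- PointSet(c(0, 2, 0), c(0, 0, 4))
#' computeCenter(ps)              # c(1, 2)
#' spec <- ScaleSpec(dataScale = 2, displayScale = 1)
#' coords(scalePoints(ps, spec)) # doubled
NULL

#' @rdname transforms
setMethod("computeCenter", "PointSet", function(points)
  computeCenter(points@coords))

#' @rdname transforms
setMethod("computeCenter", "matrix", function(points) {
  if (nrow(points) == 0L) stop("no data loaded: cannot compute center")
  c(x = (min(points[, 1]) + max(points[, 1])) / 2,
    y = (min(points[, 2]) + max(points[, 2])) / 2)
})

#' @rdname transforms
#' @param spec a \linkS4class{ScaleSpec}.
#' @export
scalePoints <- function(points, spec) {
  stopifnot(is(points, "PointSet"), is(spec, "ScaleSpec"))
  validObject(spec)
  f <- spec@dataScale / spec@displayScale
  coords(points) <- points@coords * f
  points
}

#' @rdname transforms
#' @param image an \linkS4class{ImageRaster}.
#' @export
scaleImage <- function(image, spec) {
  stopifnot(is(image, "ImageRaster"), is(spec, "ScaleSpec"))
  validObject(spec)
  f <- spec@imageScale / spec@displayScale
  newW <- max(1L, as.integer(round(imageWidth(image) * f)))
  newH <- max(1L, as.integer(round(imageHeight(image) * f)))
  if (newW == imageWidth(image) && newH == imageHeight(image)) {
    image@pixelSize <- spec@displayScale
    return(image)
  }
  img <- EBImage::Image(image@pixels,
                        colormode = if (length(dim(image@pixels)) == 3L)
                          "Color" else "Grayscale")
  res <- EBImage::resize(img, w = newW, h = newH)
  px <- as.array(res)
  px[px < 0] <- 0
  px[px > 1] <- 1
  ImageRaster(px, spec@displayScale, image@name)
}
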
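#' Construct a PointSet
#'
#' @param x,y numeric coordinate vectors of equal length.
#' @param ids character identifiers; defaults to the row index as character.
#' @param annotation optional categorical labels (character/factor); `NA`
#'   marks unannotated observations.
#' @param counts optional genes-by-observations numeric matrix; column names
#'   are set to `ids` when absent.
#' @return A \linkS4class{PointSet} with all points visible and in the
#'   `idle` interaction state.
#' @examples
#' ps <- PointSet(x = c(0, 2, 0), y = c(0, 0, 4),
#'                annotation = c("a", "a", "b"))
#' computeCenter(ps)
#' @export
PointSet <- function(x, y, ids = NULL, annotation = NULL, counts = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n == 0L) stop("no data loaded: point set is empty")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (is.null(annotation)) annotation <- rep(NA_character_, n)
  annotation <- as.character(annotation)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts))) colnames(counts) <- ids
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  new("PointSet",
      ids = ids,
      coords = cbind(x = x, y = y),
      annotation = annotation,
      visible = rep(TRUE, n),
      state = rep("idle", n),
      counts = counts)
}

#' PointSet accessors
#'
#' @param object a \linkS4class{PointSet}.
#' @param value replacement coordinate matrix (n x 2).
#' @name PointSet-accessors
NULL

#' @rdname PointSet-accessors
setMethod("ids", "PointSet", function(object) object@ids)

#' @rdname PointSet-accessors
setMethod("nPoints", "PointSet", function(object) length(object@ids))

#' @rdname PointSet-accessors
setMethod("coords", "PointSet", function(object) object@coords)

#' @rdname PointSet-accessors
setMethod("coords<-", "PointSet", function(object, value) {
  value <- as.matrix(value)
  colnames(value) <- c("x", "y")
  object@coords <- value
  validObject(object)
  object
})

#' @rdname PointSet-accessors
setMethod("annotation", "PointSet", function(object) object@annotation)

#' @rdname PointSet-accessors
setMethod("hasAnnotation", "PointSet", function(object)
  any(!is.na(object@annotation)))

#' @rdname PointSet-accessors
setMethod("pointStates", "PointSet", function(object)
  stats::setNames(object@state, object@ids))

#' @rdname PointSet-accessors
setMethod("visiblePoints", "PointSet", function(object)
  stats::setNames(object@visible, object@ids))

#' @rdname PointSet-accessors
setMethod("countsMatrix", "PointSet", function(object) object@counts)

#' Subset a PointSet by observation
#'
#' Subsets every per-observation field and, when present, the columns of the
#' count matrix.
#'
#' @param x a \linkS4class{PointSet}.
#' @param i integer, logical or character (id) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("PointSet",
      ids = x@ids[i],
      coords = x@coords[i, , drop = FALSE],
      annotation = x@annotation[i],
      visible = x@visible[i],
      state = x@state[i],
      counts = if (is.null(x@counts)) NULL else x@counts[, i, drop = FALSE])
})

setMethod("show", "PointSet", function(object) {
  n <- nPoints(object)
  cat("PointSet with", n, "observations\n")
  rng <- apply(object@coords, 2, range)
  cat(sprintf("  x: [%.4g, %.4g]  y: [%.4g, %.4g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
  if (hasAnnotation(object)) {
    labs <- unique(object@annotation[!is.na(object@annotation)])
    cat("  annotation:", length(labs), "levels\n")
  }
  if (!is.null(object@counts))
    cat("  counts:", nrow(object@counts), "genes\n")
  st <- table(factor(object@state, levels = .POINT_STATES))
  if (any(st[c("draggable", "locked")] > 0))
    cat(sprintf("  states: %d draggable, %d locked\n",
                st[["draggable"]], st[["locked"]]))
  invisible(NULL)
})

#' Construct an ImageRaster
#'
#' @param pixels numeric array in EBImage orientation (x, y[, channel]),
#'   intensities in [0, 1].
#' @param pixelSize micrometres per pixel (user-supplied, never inferred
#'   from metadata).
#' @param name source label.
#' @export
ImageRaster <- function(pixels, pixelSize, name = "image") {
  pixels <- as.array(pixels)
  new("ImageRaster", pixels = pixels, pixelSize = as.numeric(pixelSize),
      name = as.character(name))
}

#' ImageRaster accessors
#' @param object an \linkS4class{ImageRaster}.
#' @name ImageRaster-accessors
NULL

#' @rdname ImageRaster-accessors
setMethod("imageWidth", "ImageRaster", function(object) dim(object@pixels)[1])

#' @rdname ImageRaster-accessors
setMethod("imageHeight", "ImageRaster", function(object) dim(object@pixels)[2])

#' @rdname ImageRaster-accessors
setMethod("pixelSize", "ImageRaster", function(object) object@pixelSize)

setMethod("show", "ImageRaster", function(object) {
  cat(sprintf("ImageRaster '%s': %d x %d px at %g um/px\n", object@name,
              imageWidth(object), imageHeight(object), object@pixelSize))
  invisible(NULL)
})

#' Construct a ScaleSpec
#'
#' @param dataScale um/pixel of the raw coordinates.
#' @param imageScale um/pixel of the raw image.
#' @param displayScale um/pixel of the common display space.
#' @export
ScaleSpec <- function(dataScale, imageScale = dataScale, displayScale = 1) {
  new("ScaleSpec", dataScale = as.numeric(dataScale),
      imageScale = as.numeric(imageScale),
      displayScale = as.numeric(displayScale))
}

setMethod("show", "ScaleSpec", function(object) {
  cat(sprintf("ScaleSpec: data %g, image %g, display %g um/px\n",
              object@dataScale, object@imageScale, object@displayScale))
  invisible(NULL)
})

setMethod("show", "RigidState", function(object) {
  cat(sprintf(
    "RigidState: theta %.4g deg, t (%.4g, %.4g), center (%.4g, %.4g), flips h%d v%d\n",
    object@thetaDeg, object@tx, object@ty, object@center[1], object@center[2],
    object@flipsH, object@flipsV))
  invisible(NULL)
})

setMethod("show", "TransformLog", function(object) {
  cat(sprintf("TransformLog: %d entries, cursor at %d\n",
              length(object@entries), object@cursor))
  invisible(NULL)
})
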
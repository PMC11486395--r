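#' @import methods
NULL

.POINT_STATES <- c("idle", "draggable", "locked")

#' Annotated 2-D point set
#'
#' Holds per-observation x/y coordinates in display units (micrometres at the
#' chosen display scale), an optional categorical annotation (cluster or cell
#' type), a visibility mask driven by cluster selection, a three-state
#' interaction state per point (\code{idle}, \code{draggable}, \code{locked}),
#' and an optional genes-by-observations count matrix sharing the same
#' observation identifiers.
#'
#' @slot ids character, unique observation identifiers.
#' @slot coords numeric matrix with columns \code{x}, \code{y}.
#' @slot annotation character, categorical label per observation
#'   (\code{NA} when absent).
#' @slot visible logical, cluster-selection mask.
#' @slot state character, one of \code{idle}, \code{draggable}, \code{locked}.
#' @slot counts genes-by-observations numeric matrix with column names equal
#'   to \code{ids}, or \code{NULL}.
#' @exportClass PointSet
setClass("PointSet",
  representation(
    ids = "character",
    coords = "matrix",
    annotation = "character",
    visible = "logical",
    state = "character",
    counts = "ANY"
  )
)

setValidity("PointSet", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "point set must contain at least one observation")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L ||
      nrow(object@coords) != n)
    msg <- c(msg, "coords must be a numeric n x 2 matrix")
  if (length(object@annotation) != n) msg <- c(msg, "annotation length mismatch")
  if (length(object@visible) != n) msg <- c(msg, "visible length mismatch")
  if (length(object@state) != n) msg <- c(msg, "state length mismatch")
  if (!all(object@state %in% .POINT_STATES))
    msg <- c(msg, "state must be one of idle/draggable/locked")
  if (!is.null(object@counts)) {
    if (ncol(object@counts) != n)
      msg <- c(msg, "counts must have one column per observation")
    else if (!identical(colnames(object@counts), object@ids))
      msg <- c(msg, "counts column names must equal ids")
  }
  if (length(msg)) msg else TRUE
})

#' Microscopy image raster
#'
#' A 2-D (grayscale) or 2-D-by-channels intensity array in EBImage
#' orientation (first dimension = x/width, second = y/height, row 1 = top
#' edge of the image), together with the user-supplied pixel size.
#'
#' @slot pixels numeric array, intensities in [0, 1].
#' @slot pixelSize numeric, micrometres per pixel (strictly positive).
#' @slot name character source label.
#' @exportClass ImageRaster
setClass("ImageRaster",
  representation(pixels = "array", pixelSize = "numeric", name = "character")
)

setValidity("ImageRaster", function(object) {
  d <- dim(object@pixels)
  msg <- character(0)
  if (!(length(d) %in% c(2L, 3L))) msg <- c(msg, "pixels must be 2-D or 2-D x channels")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Scale specification
#'
#' The three micrometre-per-pixel scales involved in bringing data and image
#' to a common display space.
#'
#' @slot dataScale numeric, um/pixel of the raw coordinates.
#' @slot imageScale numeric, um/pixel of the raw image.
#' @slot displayScale numeric, um/pixel of the common display space.
#' @exportClass ScaleSpec
setClass("ScaleSpec",
  representation(dataScale = "numeric", imageScale = "numeric",
                 displayScale = "numeric")
)

setValidity("ScaleSpec", function(object) {
  v <- c(object@dataScale, object@imageScale, object@displayScale)
  if (length(v) != 3L || !all(is.finite(v)) || any(v <= 0))
    "all scales must be single, finite, strictly positive numbers"
  else TRUE
})

#' Cumulative rigid-transform state
#'
#' Tracks the rotation angle a registration widget would display, the
#' cumulative translation, the fixed rotation/flip pivot, and flip counters.
#' The pivot is computed once at load and never mutated afterwards, so
#' logged operations replay exactly. Every flip negates \code{thetaDeg}
#' (the widget reflects the rotation in the opposite direction).
#'
#' @slot thetaDeg numeric, cumulative displayed rotation angle in degrees
#'   (counterclockwise positive, y-up frame).
#' @slot tx,ty numeric, cumulative translation in display units.
#' @slot center numeric length-2 pivot (x, y) in display units.
#' @slot flipsH,flipsV integer flip counters.
#' @exportClass RigidState
setClass("RigidState",
  representation(thetaDeg = "numeric", tx = "numeric", ty = "numeric",
                 center = "numeric", flipsH = "integer", flipsV = "integer")
)

setValidity("RigidState", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    "center must be a finite length-2 numeric"
  else TRUE
})

#' Replayable log of linear manipulations
#'
#' Ordered entries with an undo/redo cursor: entries before the cursor
#' reproduce the current linear state when replayed onto the original scaled
#' coordinates; entries at or beyond the cursor are redoable and are
#' discarded by any new operation.
#'
#' @slot entries list of \code{list(seq, op, ...)} records.
#' @slot cursor integer, number of applied entries.
#' @exportClass TransformLog
setClass("TransformLog",
  representation(entries = "list", cursor = "integer")
)

setValidity("TransformLog", function(object) {
  if (object@cursor < 0L || object@cursor > length(object@entries))
    "cursor out of range"
  else TRUE
})

#' One elastic drag manipulation
#'
#' Records the dragged anchor point, its position at drag start, the applied
#' displacement, the influence threshold, and the set of points locked at
#' event time. Replaying the event on any point set evaluates the same
#' displacement field: points within distance D < threshold of the anchor
#' move by the displacement scaled by (threshold - D) / threshold; locked
#' points and points at D >= threshold stay put.
#'
#' @slot anchorId character identifier of the dragged point.
#' @slot anchorXY numeric length-2 anchor position at drag start.
#' @slot dx,dy numeric anchor displacement in display units.
#' @slot threshold numeric influence radius in display pixels.
#' @slot lockedIds character identifiers locked at event time.
#' @exportClass DragEvent
setClass("DragEvent",
  representation(anchorId = "character", anchorXY = "numeric",
                 dx = "numeric", dy = "numeric", threshold = "numeric",
                 lockedIds = "character")
)

setValidity("DragEvent", function(object) {
  msg <- character(0)
  if (length(object@threshold) != 1L || object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive number")
  if (object@anchorId %in% object@lockedIds)
    msg <- c(msg, "anchor must not be locked")
  if (length(object@anchorXY) != 2L) msg <- c(msg, "anchorXY must have length 2")
  if (length(msg)) msg else TRUE
})

#' A registration session
#'
#' Bundles the full raw data, the downsampled display set, the scale
#' specification, the optional image, the rigid state, the manipulation log
#' and the drag record. All manipulation verbs take and return a session.
#'
#' @slot display \linkS4class{PointSet} currently displayed (downsampled)
#'   points with live coordinates.
#' @slot scaledOrig numeric matrix, the display points' original scaled
#'   coordinates (replay origin).
#' @slot fullRaw \linkS4class{PointSet} all observations in raw coordinates.
#' @slot displayIdx integer indices of displayed observations in
#'   \code{fullRaw}.
#' @slot scales \linkS4class{ScaleSpec} used at load.
#' @slot image \linkS4class{ImageRaster} scaled to display space, or NULL.
#' @slot rigid \linkS4class{RigidState}.
#' @slot log \linkS4class{TransformLog}.
#' @slot drags list of \linkS4class{DragEvent}.
#' @slot dsSpec downsampling record (list) or NULL.
#' @slot linearClosed logical; elastic edits only allowed once TRUE.
#' @exportClass RegSession
setClass("RegSession",
  representation(
    display = "PointSet",
    scaledOrig = "matrix",
    fullRaw = "PointSet",
    displayIdx = "integer",
    scales = "ScaleSpec",
    image = "ANY",
    rigid = "RigidState",
    log = "TransformLog",
    drags = "list",
    dsSpec = "ANY",
    linearClosed = "logical"
  )
)

#' Per-gene raw-count sums over a square spatial grid
#'
#' @slot binSize numeric bin edge length in micrometres.
#' @slot origin numeric length-2 position of bin (0, 0)'s lower-left corner.
#' @slot bins integer matrix (bins x 2) of (i, j) bin indices.
#' @slot counts genes-by-bins matrix of raw-count sums; column names are
#'   \code{"i_j"} keys.
#' @exportClass BinnedExpression
setClass("BinnedExpression",
  representation(binSize = "numeric", origin = "numeric", bins = "matrix",
                 counts = "matrix")
)

setValidity("BinnedExpression", function(object) {
  msg <- character(0)
  if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (ncol(object@counts) != nrow(object@bins))
    msg <- c(msg, "one count column per occupied bin required")
  if (length(msg)) msg else TRUE
})

#' Binary tissue mask aligned to an image grid
#'
#' @slot mask logical matrix in image orientation (x by y).
#' @slot threshold numeric grayscale threshold used (NA for degenerate input).
#' @slot darkTissue logical, whether the darker side was taken as tissue.
#' @exportClass TissueMask
setClass("TissueMask",
  representation(mask = "matrix", threshold = "numeric", darkTissue = "logical")
)

#' Synthetic fixture specification
#'
#' Parameters of the synthetic section generator: clustered points inside an
#' elliptical tissue, Poisson counts with cluster- and gradient-dependent
#' rates, and a rendered tissue image.
#'
#' @slot nPoints,nClusters,nGenes integer counts.
#' @slot imageShape integer length-2 (width, height) in pixels.
#' @slot pixelSize numeric um per image pixel.
#' @slot ellipse numeric length-4 (cx, cy, rx, ry) in micrometres.
#' @slot clusterWeights numeric mixing weights (sum to 1).
#' @slot seed integer RNG seed (mandatory).
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(nPoints = "integer", nClusters = "integer",
                 nGenes = "integer", imageShape = "integer",
                 pixelSize = "numeric", ellipse = "numeric",
                 clusterWeights = "numeric", seed = "integer")
)

setValidity("FixtureSpec", function(object) {
  msg <- character(0)
  if (any(c(object@nPoints, object@nClusters, object@nGenes) < 1L))
    msg <- c(msg, "all counts must be positive")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two pixel counts >= 8")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  e <- object@ellipse
  w <- object@imageShape[1] * object@pixelSize
  h <- object@imageShape[2] * object@pixelSize
  if (length(e) != 4L || e[3] <= 0 || e[4] <= 0 ||
      e[1] - e[3] < 0 || e[1] + e[3] > w || e[2] - e[4] < 0 || e[2] + e[4] > h)
    msg <- c(msg, "degenerate tissue geometry: ellipse must fit inside the image")
  if (length(object@clusterWeights) != object@nClusters ||
      any(object@clusterWeights <= 0))
    msg <- c(msg, "clusterWeights must be positive, one per cluster")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
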
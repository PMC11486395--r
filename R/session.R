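#' Open a registration session
#'
#' Scales the raw coordinates (and image, when given) to the common display
#' scale, fixes the rotation/flip pivot at the bounding-box centre of the
#' scaled full point set, and downsamples the displayed set when the data
#' exceed `displayN` observations: stratified by annotation when one is
#' present, uniformly at random otherwise. The downsampling only governs
#' what is displayed and manipulated interactively; [replayFull()] always
#' exports every original observation.
#'
#' @param points \linkS4class{PointSet} in raw coordinates.
#' @param scales \linkS4class{ScaleSpec}.
#' @param image optional \linkS4class{ImageRaster} in raw resolution.
#' @param displayN maximum number of displayed points (default 10000).
#' @param seed RNG seed for downsampling; mandatory when the data must be
#'   downsampled.
#' @param center optional explicit pivot, e.g. to reuse a recorded one when
#'   replaying a registration; defaults to the bounding-box centre of the
#'   scaled points.
#' @return A \linkS4class{RegSession}.
#' @seealso [rotateData()], [translateData()], [flipData()],
#'   [rescaleData()], [undoLast()], [redoLast()], [applyDrag()],
#'   [replayFull()], [writeRegistrationBundle()]
#' @export
newSession <- function(points, scales, image = NULL, displayN = 10000L,
                       seed = NULL, center = NULL) {
  stopifnot(is(points, "PointSet"), is(scales, "ScaleSpec"))
  validObject(points)
  validObject(scales)
  scaled <- scalePoints(points, scales)
  n <- nPoints(scaled)
  dsSpec <- NULL
  if (n > displayN) {
    if (is.null(seed))
      stop("seed is required when downsampling ", n, " -> ", displayN, " points")
    if (hasAnnotation(scaled)) {
      ds <- stratifiedDownsample(scaled, displayN, seed)
      idx <- ds$indices
      dsSpec <- ds$spec
    } else {
      idx <- randomDownsample(scaled, displayN, seed)
      dsSpec <- list(totalT = n, targetN = as.integer(displayN),
                     perCluster = NULL, seed = as.integer(seed))
    }
  } else {
    idx <- seq_len(n)
  }
  display <- scaled[idx]
  if (is.null(center)) center <- computeCenter(scaled) else
    center <- stats::setNames(as.numeric(center), c("x", "y"))
  if (!is.null(image)) image <- scaleImage(image, scales)
  new("RegSession",
      display = display,
      scaledOrig = coords(display),
      fullRaw = points,
      displayIdx = as.integer(idx),
      scales = scales,
      image = image,
      rigid = new("RigidState", thetaDeg = 0, tx = 0, ty = 0, center = center,
                  flipsH = 0L, flipsV = 0L),
      log = new("TransformLog", entries = list(), cursor = 0L),
      drags = list(),
      dsSpec = dsSpec,
      linearClosed = FALSE)
}

# Replay linear log entries onto original scaled coordinates, tracking the
# widget state. This is the single code path used by live operations,
# undo/redo and full-data export, so all of them agree bit for bit.
.replayLinear <- function(entries, xy, center, displayScale0) {
  theta <- 0
  tx <- 0
  ty <- 0
  fh <- 0L
  fv <- 0L
  sc <- displayScale0
  for (e in entries) {
    switch(e$op,
      rotate = {
        xy <- .rotateAbout(xy, e$theta, center)
        theta <- theta + e$theta
      },
      translate = {
        xy[, 1] <- xy[, 1] + e$tx
        xy[, 2] <- xy[, 2] + e$ty
        tx <- tx + e$tx
        ty <- ty + e$ty
      },
      flip = {
        # the three-operation rotation-compensated mirror: undo the
        # accumulated rotation, mirror about the pivot axis, rotate by the
        # negated angle again; the widget angle ends up at -theta
        xy <- .rotateAbout(xy, -theta, center)
        xy <- .mirrorAbout(xy, e$axis, center)
        xy <- .rotateAbout(xy, -theta, center)
        theta <- -theta
        if (e$axis == "vertical") fv <- fv + 1L else fh <- fh + 1L
      },
      rescale = {
        f <- sc / e$displayScale
        xy <- xy * f
        sc <- e$displayScale
      },
      stop("unknown operation in log: ", e$op)
    )
  }
  list(coords = xy, thetaDeg = theta, tx = tx, ty = ty,
       flipsH = fh, flipsV = fv, displayScale = sc)
}

.appendEntry <- function(session, entry) {
  lg <- session@log
  if (session@linearClosed)
    stop("linear phase is closed: no further linear manipulations")
  kept <- lg@entries[seq_len(lg@cursor)]  # new op discards redoable tail
  entry$seq <- lg@cursor + 1L
  lg@entries <- c(kept, list(entry))
  lg@cursor <- lg@cursor + 1L
  session@log <- lg
  .syncLinear(session)
}

.syncLinear <- function(session) {
  lg <- session@log
  r <- .replayLinear(lg@entries[seq_len(lg@cursor)], session@scaledOrig,
                     session@rigid@center, session@scales@displayScale)
  session@display@coords <- r$coords
  session@rigid@thetaDeg <- r$thetaDeg
  session@rigid@tx <- r$tx
  session@rigid@ty <- r$ty
  session@rigid@flipsH <- r$flipsH
  session@rigid@flipsV <- r$flipsV
  session
}

# current display scale after any rescale entries before the cursor
.currentDisplayScale <- function(session) {
  sc <- session@scales@displayScale
  lg <- session@log
  for (e in lg@entries[seq_len(lg@cursor)])
    if (e$op == "rescale") sc <- e$displayScale
  sc
}

#' Linear manipulations of a session
#'
#' Each verb commits one entry to the manipulation log (discarding any
#' redoable entries), recomputes the display coordinates by replaying the
#' log from the original scaled coordinates, and updates the rigid state.
#'
#' `rotateData` rotates all points by `thetaDeg` degrees (counterclockwise
#' positive) about the fixed pivot. `translateData` shifts by `(tx, ty)`
#' display units. `flipData` mirrors about the vertical or horizontal plane
#' through the pivot using the rotation-compensated three-step procedure
#' (rotate by the negated accumulated angle, mirror, rotate by the negated
#' angle again); the displayed angle is negated afterwards. `rescaleData`
#' changes the common display scale, multiplying all coordinates by
#' `old / new`.
#'
#' @param session a \linkS4class{RegSession}.
#' @param thetaDeg rotation angle, degrees.
#' @return The updated session.
#' @name linear-ops
NULL

#' @rdname linear-ops
#' @export
rotateData <- function(session, thetaDeg) {
  stopifnot(is(session, "RegSession"), is.finite(thetaDeg))
  .appendEntry(session, list(op = "rotate", theta = as.numeric(thetaDeg)))
}

#' @rdname linear-ops
#' @param tx,ty translation in display units.
#' @export
translateData <- function(session, tx, ty) {
  stopifnot(is(session, "RegSession"), is.finite(tx), is.finite(ty))
  .appendEntry(session, list(op = "translate", tx = as.numeric(tx),
                             ty = as.numeric(ty)))
}

#' @rdname linear-ops
#' @param axis `"vertical"` (mirror x about the pivot) or `"horizontal"`
#'   (mirror y).
#' @export
flipData <- function(session, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  stopifnot(is(session, "RegSession"))
  .appendEntry(session, list(op = "flip", axis = axis))
}

#' @rdname linear-ops
#' @param displayScale new display scale, um/pixel.
#' @export
rescaleData <- function(session, displayScale) {
  stopifnot(is(session, "RegSession"), is.finite(displayScale),
            displayScale > 0)
  .appendEntry(session, list(op = "rescale",
                             displayScale = as.numeric(displayScale)))
}

#' Undo / redo linear manipulations
#'
#' `undoLast` steps the log cursor back one committed operation and
#' `redoLast` re-applies the next undone one; both recompute the display
#' coordinates by replaying the log prefix onto the original scaled
#' coordinates. Undoing at the start (or redoing at the end) of the log
#' warns and leaves the session unchanged. A new manipulation after an undo
#' discards the redoable entries.
#'
#' @param session a \linkS4class{RegSession}.
#' @return The updated session.
#' @export
undoLast <- function(session) {
  stopifnot(is(session, "RegSession"))
  if (session@linearClosed)
    stop("linear phase is closed: undo is unavailable")
  if (session@log@cursor == 0L) {
    warning("nothing to undo")
    return(session)
  }
  session@log@cursor <- session@log@cursor - 1L
  .syncLinear(session)
}

#' @rdname undoLast
#' @export
redoLast <- function(session) {
  stopifnot(is(session, "RegSession"))
  if (session@linearClosed)
    stop("linear phase is closed: redo is unavailable")
  if (session@log@cursor == length(session@log@entries)) {
    warning("nothing to redo")
    return(session)
  }
  session@log@cursor <- session@log@cursor + 1L
  .syncLinear(session)
}

#' Close the linear phase
#'
#' Elastic (non-linear) manipulations are intended for fine adjustments and
#' can only be applied once linear alignment is complete; this flips the
#' session's mode flag. Linear verbs and undo/redo refuse to run afterwards,
#' which keeps the exported replay order (log first, then drags) exact.
#'
#' @param session a \linkS4class{RegSession}.
#' @export
closeLinearPhase <- function(session) {
  stopifnot(is(session, "RegSession"))
  session@linearClosed <- TRUE
  session
}

#' Cluster selection
#'
#' Marks the display points whose annotation is in `labels` visible and all
#' others invisible. Selection affects display only: every manipulation is
#' applied to visible and invisible points alike, and export always includes
#' all observations.
#'
#' @param session a \linkS4class{RegSession}.
#' @param labels annotation labels to keep visible.
#' @export
selectClusters <- function(session, labels) {
  stopifnot(is(session, "RegSession"))
  session@display@visible <- session@display@annotation %in% labels
  session
}

#' Session accessors
#'
#' @param session a \linkS4class{RegSession}.
#' @name session-accessors
NULL

#' @rdname session-accessors
setMethod("displayPoints", "RegSession", function(session) session@display)

#' @rdname session-accessors
setMethod("rigidState", "RegSession", function(session) session@rigid)

#' @rdname session-accessors
setMethod("transformLog", "RegSession", function(session) session@log)

#' @rdname session-accessors
setMethod("dragRecord", "RegSession", function(session) session@drags)

#' @rdname session-accessors
setMethod("sessionImage", "RegSession", function(session) session@image)

setMethod("show", "RegSession", function(object) {
  cat("RegSession\n")
  cat("  displayed:", nPoints(object@display), "of",
      nPoints(object@fullRaw), "observations\n")
  cat(sprintf("  log: %d entries (cursor %d), %d drag events\n",
              length(object@log@entries), object@log@cursor,
              length(object@drags)))
  cat("  phase:", if (object@linearClosed) "elastic" else "linear", "\n")
  show(object@rigid)
  invisible(NULL)
})
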
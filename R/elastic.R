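# The elastic displacement field shared by the live path and full-data
# replay. Strict D < threshold receives displacement; at D = threshold the
# falloff factor is zero anyway, but the strict comparison is documented for
# bitwise reproducibility. Locked points never move.
.applyDragField <- function(xy, locked, anchorXY, dx, dy, threshold) {
  d <- sqrt((xy[, 1] - anchorXY[1])^2 + (xy[, 2] - anchorXY[2])^2)
  f <- numeric(nrow(xy))
  hit <- !locked & d < threshold
  f[hit] <- (threshold - d[hit]) / threshold
  xy[, 1] <- xy[, 1] + dx * f
  xy[, 2] <- xy[, 2] + dy * f
  xy
}

#' Cycle a point's interaction state
#'
#' Data points have three states switched cyclically: `idle` (not selected)
#' -> `draggable` (one click: can be dragged) -> `locked` (two clicks: stays
#' in place even when a nearby point is dragged) -> `idle` again. Cycling
#' one point never alters another point's state.
#'
#' @param session a \linkS4class{RegSession}.
#' @param id identifier of a displayed point.
#' @return The updated session.
#' @export
cycleState <- function(session, id) {
  stopifnot(is(session, "RegSession"))
  idx <- match(id, session@display@ids)
  if (is.na(idx)) stop("unknown point id: ", id)
  cur <- session@display@state[idx]
  session@display@state[idx] <-
    .POINT_STATES[match(cur, .POINT_STATES) %% 3L + 1L]
  session
}

#' Apply an elastic drag
#'
#' Moves a draggable anchor point by `(dx, dy)` and every other unlocked
#' point at distance `D < threshold` from the anchor's pre-drag position by
#' `(dx, dy) * (threshold - D) / threshold`, so the displacement diminishes
#' linearly with distance and vanishes at the threshold. Locked points and
#' points at `D >= threshold` are untouched. The event (anchor identity and
#' pre-drag position, displacement, threshold, lock snapshot) is appended to
#' the drag record, which makes replay on the full data set well defined.
#'
#' Drags are only allowed after [closeLinearPhase()]; the anchor must be in
#' the `draggable` state (see [cycleState()]).
#'
#' @param session a \linkS4class{RegSession}.
#' @param id identifier of the anchor point.
#' @param dx,dy anchor displacement, display units.
#' @param threshold influence radius in display pixels (default 1000).
#' @return The updated session.
#' @export
applyDrag <- function(session, id, dx, dy, threshold = 1000) {
  stopifnot(is(session, "RegSession"))
  if (!session@linearClosed)
    stop("mode error: elastic manipulations require the linear phase ",
         "to be closed first (see closeLinearPhase)")
  idx <- match(id, session@display@ids)
  if (is.na(idx)) stop("unknown point id: ", id)
  st <- session@display@state[idx]
  if (st == "locked") stop("state error: anchor point is locked")
  if (st != "draggable")
    stop("state error: anchor point must be draggable (one click)")
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  anchorXY <- session@display@coords[idx, ]
  lockedMask <- session@display@state == "locked"
  ev <- new("DragEvent", anchorId = as.character(id),
            anchorXY = as.numeric(anchorXY),
            dx = as.numeric(dx), dy = as.numeric(dy),
            threshold = as.numeric(threshold),
            lockedIds = session@display@ids[lockedMask])
  validObject(ev)
  session@display@coords <- .applyDragField(
    session@display@coords, lockedMask, ev@anchorXY, ev@dx, ev@dy,
    ev@threshold)
  session@drags <- c(session@drags, list(ev))
  session
}

#' Reset all elastic manipulations
#'
#' Restores the displayed points to their pure-linear positions (the replay
#' of the committed log entries onto the original scaled coordinates),
#' clears the drag record, and resets all interaction states to `idle`.
#' Linear transformations are retained. There is no per-drag undo; the
#' global reset is the only way back, mirroring the split between the
#' undo/redo log (linear) and the reset (elastic).
#'
#' @param session a \linkS4class{RegSession}.
#' @return The updated session.
#' @export
resetElastic <- function(session) {
  stopifnot(is(session, "RegSession"))
  session <- .syncLinear(session)
  session@drags <- list()
  session@display@state <- rep("idle", nPoints(session@display))
  session
}
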
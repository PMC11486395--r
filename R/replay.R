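#' Replay all recorded manipulations on the full data set
#'
#' Applies, in order, the initial scaling, the committed linear log entries
#' and the recorded drag events to every original observation (not just the
#' displayed subset), yielding the full-resolution registered coordinates
#' for export. Each drag event's displacement field is evaluated over all
#' points using the event's recorded anchor position, threshold and lock
#' snapshot, so points that were not displayed land exactly where the same
#' maps put the displayed ones.
#'
#' @param session a \linkS4class{RegSession}.
#' @param points optional \linkS4class{PointSet} in raw coordinates to
#'   replay onto (defaults to the session's full data). Must share the raw
#'   coordinate space the session was opened with.
#' @return A \linkS4class{PointSet} with registered coordinates, one row per
#'   observation of `points`, annotations and counts carried through.
#' @export
replayFull <- function(session, points = NULL) {
  stopifnot(is(session, "RegSession"))
  if (is.null(points)) points <- session@fullRaw
  stopifnot(is(points, "PointSet"))
  scaled <- scalePoints(points, session@scales)
  r <- .replayLinear(session@log@entries[seq_len(session@log@cursor)],
                     coords(scaled), session@rigid@center,
                     session@scales@displayScale)
  xy <- r$coords
  for (ev in session@drags) {
    locked <- scaled@ids %in% ev@lockedIds
    xy <- .applyDragField(xy, locked, ev@anchorXY, ev@dx, ev@dy, ev@threshold)
  }
  out <- points
  out@coords <- xy
  out@state <- rep("idle", nPoints(out))
  out@visible <- rep(TRUE, nPoints(out))
  out
}
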
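.RECORD_KEYS <- c("data_scale_um_per_px", "image_scale_um_per_px",
                  "display_scale_um_per_px", "theta_deg", "tx", "ty",
                  "flips_h", "flips_v", "center_x", "center_y", "image_name")

.fmt <- function(x) sprintf("%.17g", x)

#' Export a registration bundle
#'
#' Writes everything needed to reproduce the registration with no session
#' state:
#' \itemize{
#'   \item `<base>_coordinates.csv` — registered coordinates of \emph{all}
#'     original observations (display downsampling never drops rows on
#'     export), via [replayFull()];
#'   \item `<base>_image.jpeg` — the display-scaled image, re-encoded as
#'     JPEG at quality 95 (only when the session holds an image);
#'   \item `<base>_record.txt` — newline-separated `key=value` registration
#'     parameters (scales in um/px, final widget angle, cumulative
#'     translation, flip counters, pivot, image name); the stored
#'     `display_scale_um_per_px` is the scale the raw coordinates were
#'     scaled by at load, mid-session rescales live in the log;
#'   \item `<base>_log.csv` — the committed linear manipulations with
#'     header `sequence,op,param1,param2,param3`;
#'   \item `<base>_drags.csv` — the drag record with header
#'     `sequence,anchor_id,anchor_x,anchor_y,dx,dy,threshold,locked_ids`
#'     (locked ids semicolon-separated; needed so lock snapshots replay).
#' }
#'
#' @param session a \linkS4class{RegSession}.
#' @param outDir output directory (created if missing).
#' @param baseName file name prefix.
#' @return Named character vector of written paths, invisibly.
#' @seealso [replayBundle()] to reconstruct registered coordinates from a
#'   bundle plus the raw inputs.
#' @export
writeRegistrationBundle <- function(session, outDir,
                                    baseName = "registered") {
  stopifnot(is(session, "RegSession"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("I/O error: cannot create ", outDir)
  p <- function(suffix) file.path(outDir, paste0(baseName, suffix))
  paths <- c(coordinates = p("_coordinates.csv"),
             record = p("_record.txt"),
             log = p("_log.csv"),
             drags = p("_drags.csv"))
  writeCoordinates(replayFull(session), paths[["coordinates"]])

  rg <- session@rigid
  sc <- session@scales
  rec <- c(.fmt(sc@dataScale), .fmt(sc@imageScale), .fmt(sc@displayScale),
           .fmt(rg@thetaDeg), .fmt(rg@tx), .fmt(rg@ty),
           as.character(rg@flipsH), as.character(rg@flipsV),
           .fmt(rg@center[1]), .fmt(rg@center[2]),
           if (is.null(session@image)) "none" else session@image@name)
  writeLines(paste0(.RECORD_KEYS, "=", rec), paths[["record"]])

  entries <- session@log@entries[seq_len(session@log@cursor)]
  logDf <- data.frame(
    sequence = vapply(entries, function(e) e$seq, integer(1)),
    op = vapply(entries, function(e) e$op, character(1)),
    param1 = vapply(entries, function(e) switch(e$op,
      rotate = .fmt(e$theta), translate = .fmt(e$tx), flip = e$axis,
      rescale = .fmt(e$displayScale)), character(1)),
    param2 = vapply(entries, function(e)
      if (e$op == "translate") .fmt(e$ty) else "", character(1)),
    param3 = rep("", length(entries)),
    stringsAsFactors = FALSE)
  if (!length(entries))
    logDf <- data.frame(sequence = integer(0), op = character(0),
                        param1 = character(0), param2 = character(0),
                        param3 = character(0))
  data.table::fwrite(logDf, paths[["log"]])

  drags <- session@drags
  dragDf <- data.frame(
    sequence = seq_along(drags),
    anchor_id = vapply(drags, function(e) e@anchorId, character(1)),
    anchor_x = vapply(drags, function(e) .fmt(e@anchorXY[1]), character(1)),
    anchor_y = vapply(drags, function(e) .fmt(e@anchorXY[2]), character(1)),
    dx = vapply(drags, function(e) .fmt(e@dx), character(1)),
    dy = vapply(drags, function(e) .fmt(e@dy), character(1)),
    threshold = vapply(drags, function(e) .fmt(e@threshold), character(1)),
    locked_ids = vapply(drags, function(e)
      paste(e@lockedIds, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  if (!length(drags))
    dragDf <- dragDf[0, , drop = FALSE]
  data.table::fwrite(dragDf, paths[["drags"]])

  if (!is.null(session@image)) {
    paths <- c(paths, image = p("_image.jpeg"))
    .writeImageJpeg(session@image, paths[["image"]])
  }
  invisible(paths)
}

#' Read a registration record
#'
#' Parses the plain-text `key=value` record written by
#' [writeRegistrationBundle()] and reconstructs the scales and the rigid
#' state.
#'
#' @param path the `_record.txt` file.
#' @return A list with elements `scales` (\linkS4class{ScaleSpec}), `rigid`
#'   (\linkS4class{RigidState}) and `imageName`.
#' @export
readRegistrationRecord <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing record file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  names(vals) <- keys
  missing <- setdiff(.RECORD_KEYS, keys)
  if (length(missing))
    stop("record is missing required key(s): ",
         paste(missing, collapse = ", "))
  num <- function(k) as.numeric(vals[[k]])
  list(
    scales = ScaleSpec(num("data_scale_um_per_px"),
                       num("image_scale_um_per_px"),
                       num("display_scale_um_per_px")),
    rigid = new("RigidState",
                thetaDeg = num("theta_deg"), tx = num("tx"), ty = num("ty"),
                center = c(x = num("center_x"), y = num("center_y")),
                flipsH = as.integer(num("flips_h")),
                flipsV = as.integer(num("flips_v"))),
    imageName = vals[["image_name"]])
}

.readTransformLog <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing log file: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE,
                                        colClasses = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    op <- df$op[i]
    e <- switch(op,
      rotate = list(op = op, theta = as.numeric(df$param1[i])),
      translate = list(op = op, tx = as.numeric(df$param1[i]),
                       ty = as.numeric(df$param2[i])),
      flip = list(op = op, axis = df$param1[i]),
      rescale = list(op = op, displayScale = as.numeric(df$param1[i])),
      stop("unknown operation in log: ", op))
    e$seq <- as.integer(df$sequence[i])
    e
  })
}

.readDragRecord <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing drag record: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE,
                                        colClasses = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    locked <- df$locked_ids[i]
    locked <- if (is.na(locked) || !nzchar(locked)) character(0) else
      strsplit(locked, ";", fixed = TRUE)[[1]]
    new("DragEvent", anchorId = df$anchor_id[i],
        anchorXY = c(as.numeric(df$anchor_x[i]), as.numeric(df$anchor_y[i])),
        dx = as.numeric(df$dx[i]), dy = as.numeric(df$dy[i]),
        threshold = as.numeric(df$threshold[i]), lockedIds = locked)
  })
}

#' Replay a registration bundle onto raw coordinates
#'
#' Reconstructs the registration from a bundle directory (record, log and
#' drag record) alone — no session state — and applies it to raw
#' coordinates: scale by the recorded data/display scales, replay the
#' logged linear operations in order, then the drag events in order. The
#' raw points may be a superset of the originally registered ones; shared
#' observations receive identical maps.
#'
#' @param bundleDir directory written by [writeRegistrationBundle()].
#' @param rawPoints a \linkS4class{PointSet} in raw coordinates, or a path
#'   accepted by [readCoordinates()].
#' @param baseName the bundle's file name prefix.
#' @param clusterKey annotation column name when `rawPoints` is a path.
#' @return A \linkS4class{PointSet} with registered coordinates.
#' @export
replayBundle <- function(bundleDir, rawPoints, baseName = "registered",
                         clusterKey = "cluster") {
  p <- function(suffix) file.path(bundleDir, paste0(baseName, suffix))
  rec <- readRegistrationRecord(p("_record.txt"))
  entries <- .readTransformLog(p("_log.csv"))
  drags <- .readDragRecord(p("_drags.csv"))
  if (is.character(rawPoints))
    rawPoints <- readCoordinates(rawPoints, clusterKey = clusterKey)
  stopifnot(is(rawPoints, "PointSet"))
  scaled <- scalePoints(rawPoints, rec$scales)
  r <- .replayLinear(entries, coords(scaled), rec$rigid@center,
                     rec$scales@displayScale)
  xy <- r$coords
  for (ev in drags) {
    locked <- scaled@ids %in% ev@lockedIds
    xy <- .applyDragField(xy, locked, ev@anchorXY, ev@dx, ev@dy,
                          ev@threshold)
  }
  out <- rawPoints
  out@coords <- xy
  out
}
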
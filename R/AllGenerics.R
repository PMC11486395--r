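#' @rdname PointSet-accessors
#' @export
setGeneric("ids", function(object) standardGeneric("ids"))

#' @rdname PointSet-accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname PointSet-accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname PointSet-accessors
#' @export
setGeneric("coords<-", function(object, value) standardGeneric("coords<-"))

#' @rdname PointSet-accessors
#' @export
setGeneric("annotation", function(object) standardGeneric("annotation"))

#' @rdname PointSet-accessors
#' @export
setGeneric("hasAnnotation", function(object) standardGeneric("hasAnnotation"))

#' @rdname PointSet-accessors
#' @export
setGeneric("pointStates", function(object) standardGeneric("pointStates"))

#' @rdname PointSet-accessors
#' @export
setGeneric("visiblePoints", function(object) standardGeneric("visiblePoints"))

#' @rdname PointSet-accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname ImageRaster-accessors
#' @export
setGeneric("imageWidth", function(object) standardGeneric("imageWidth"))

#' @rdname ImageRaster-accessors
#' @export
setGeneric("imageHeight", function(object) standardGeneric("imageHeight"))

#' @rdname ImageRaster-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname transforms
#' @export
setGeneric("computeCenter", function(points) standardGeneric("computeCenter"))

#' @rdname session-accessors
#' @export
setGeneric("displayPoints", function(session) standardGeneric("displayPoints"))

#' @rdname session-accessors
#' @export
setGeneric("rigidState", function(session) standardGeneric("rigidState"))

#' @rdname session-accessors
#' @export
setGeneric("transformLog", function(session) standardGeneric("transformLog"))

#' @rdname session-accessors
#' @export
setGeneric("dragRecord", function(session) standardGeneric("dragRecord"))

#' @rdname session-accessors
#' @export
setGeneric("sessionImage", function(session) standardGeneric("sessionImage"))
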
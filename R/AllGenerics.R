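#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the image-side S4 classes.
#'
#' @param x An object.
#' @param ... Further arguments passed to methods.
#' @return The slot content the accessor names (see the method pages).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("windowPx", function(x) standardGeneric("windowPx"))

#' @rdname accessors
#' @export
setGeneric("radiusPx", function(x) standardGeneric("radiusPx"))

#' @rdname accessors
#' @export
setGeneric("seedCoords", function(x) standardGeneric("seedCoords"))

#' @rdname accessors
#' @export
setGeneric("regionAreas", function(x) standardGeneric("regionAreas"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname accessors
#' @export
setGeneric("regionPolygons", function(x) standardGeneric("regionPolygons"))

#' @rdname accessors
#' @export
setGeneric("vesselPolygons", function(x) standardGeneric("vesselPolygons"))

#' @rdname accessors
#' @export
setGeneric("measurementRows", function(x) standardGeneric("measurementRows"))
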
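#' @name stimCoherence-accessors
#' @title Accessors for stimCoherence data classes
#' @description Accessor generics for \linkS4class{SessionBundle},
#'   \linkS4class{EpochSet}, \linkS4class{PairBandTable} and
#'   \linkS4class{RegionPairDelta}.
#' @param x an object of one of the package's data classes.
#' @param ... further arguments passed to methods.
NULL

#' @rdname stimCoherence-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("epochArray", function(x, condition) standardGeneric("epochArray"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("keepMask", function(x, condition) standardGeneric("keepMask"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("pairValues",
           function(x, condition, band, pooled = FALSE)
             standardGeneric("pairValues"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))

#' @rdname stimCoherence-accessors
#' @export
setGeneric("deltaMatrix",
           function(x, condition, band) standardGeneric("deltaMatrix"))
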
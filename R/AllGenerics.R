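#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the data containers: node identifiers,
#' node metadata, signal and motion matrices, repetition time, correlation and
#' weight matrices, weight semantics and threshold provenance.
#'
#' @param x an object.
#' @return The slot contents documented on each class page.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("motionTrace", function(x) standardGeneric("motionTrace"))

#' @rdname accessors
#' @export
setGeneric("nuisanceSignals", function(x) standardGeneric("nuisanceSignals"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("weightKind", function(x) standardGeneric("weightKind"))

#' @rdname accessors
#' @export
setGeneric("thresholdR", function(x) standardGeneric("thresholdR"))
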
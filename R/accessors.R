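#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("nodeIds", "NetworkDefinition", function(x) x@nodes$id)

#' @rdname accessors
#' @export
setMethod("nodeTable", "NetworkDefinition", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("networkName", "NetworkDefinition", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("hemisphere", "NetworkDefinition", function(x) {
  stats::setNames(x@nodes$hemisphere, x@nodes$id)
})

#' @rdname accessors
#' @export
setMethod("length", "NetworkDefinition", function(x) nrow(x@nodes))

#' @rdname accessors
#' @export
setMethod("nodeIds", "SubjectTimeSeries", function(x) colnames(x@signals))

#' @rdname accessors
#' @export
setMethod("signalMatrix", "SubjectTimeSeries", function(x) x@signals)

#' @rdname accessors
#' @export
setMethod("motionTrace", "SubjectTimeSeries", function(x) x@motion)

#' @rdname accessors
#' @export
setMethod("nuisanceSignals", "SubjectTimeSeries", function(x) x@nuisance)

#' @rdname accessors
#' @export
setMethod("trSeconds", "SubjectTimeSeries", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("nVolumes", "SubjectTimeSeries", function(x) nrow(x@signals))

#' @rdname accessors
#' @export
setMethod("nodeIds", "ConnectivityMatrix", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("corMatrix", "ConnectivityMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "ConnectivityMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("weightKind", "ConnectivityMatrix", function(x) x@weightKind)

#' @rdname accessors
#' @export
setMethod("thresholdR", "ConnectivityMatrix", function(x) x@thresholdR)
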
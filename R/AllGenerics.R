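#' @rdname MediatorDataset-class
#' @export
setGeneric("mediators", function(x) standardGeneric("mediators"))

#' @rdname MediatorDataset-class
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname MediatorDataset-class
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @rdname MediatorDataset-class
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' @rdname MediatorDataset-class
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname intervalScheme
#' @export
setGeneric("intervalScheme", function(x) standardGeneric("intervalScheme"))

#' @rdname networkComplexity
#' @export
setGeneric("networkComplexity", function(x, ...) standardGeneric("networkComplexity"))

#' @rdname networkComplexity
#' @export
setGeneric("totalConnections", function(x) standardGeneric("totalConnections"))

#' @rdname mediatorConnectivity
#' @export
setGeneric("mediatorConnectivity", function(x, mediator, ...) standardGeneric("mediatorConnectivity"))

#' @rdname DynamicNetworkSet-class
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname DybnPosterior-class
#' @export
setGeneric("edgeProbabilities", function(x) standardGeneric("edgeProbabilities"))

#' @rdname consensusGraph
#' @export
setGeneric("consensusGraph", function(x, ...) standardGeneric("consensusGraph"))

#' @rdname ConsensusGraph-class
#' @export
setGeneric("selfFeedback", function(x) standardGeneric("selfFeedback"))

#' @rdname ConsensusGraph-class
#' @export
setGeneric("centralNodes", function(x) standardGeneric("centralNodes"))
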
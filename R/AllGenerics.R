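#' @rdname TCRPanel-accessors
#' @export
setGeneric("panelGroups", function(x) standardGeneric("panelGroups"))

#' @rdname TCRPanel-accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname TCRPanel-accessors
#' @export
setGeneric("panelCoverage", function(x) standardGeneric("panelCoverage"))

#' @rdname TCRPanel-accessors
#' @export
setGeneric("panelVersion", function(x) standardGeneric("panelVersion"))

#' @rdname TCRPanel-accessors
#' @export
setGeneric("geneToGroup", function(x) standardGeneric("geneToGroup"))

#' @rdname TCRExperiment-accessors
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))

#' @rdname TCRExperiment-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname TCRExperiment-accessors
#' @export
setGeneric("cellLabels<-", function(x, value) standardGeneric("cellLabels<-"))

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))
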
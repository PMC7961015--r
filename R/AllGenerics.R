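#' @rdname MxifCellSet-class
#' @param x an object.
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' @rdname ClusterModel-class
#' @param x an object.
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname ConsensusResult-class
#' @param x an object.
#' @export
setGeneric("pacValues", function(x) standardGeneric("pacValues"))

#' @rdname ConsensusResult-class
#' @param k number of clusters whose consensus matrix to extract.
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname FilterAudit-class
#' @param x an object.
#' @export
setGeneric("auditStages", function(x) standardGeneric("auditStages"))

#' @rdname FilterAudit-class
#' @export
setGeneric("auditRules", function(x) standardGeneric("auditRules"))
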
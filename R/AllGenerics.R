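#' @rdname ExpressionDataset-class
#' @param x an object
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @rdname ModeratedStats-class
#' @param x an object
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))

#' @rdname ModeratedStats-class
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @rdname ModeratedStats-class
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))

#' @rdname MetaDEResult-class
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname MirTargetSet-class
#' @param x an object
#' @export
setGeneric("interactionEdges", function(x) standardGeneric("interactionEdges"))

#' @rdname TripartiteNetwork-class
#' @param x an object
#' @export
setGeneric("circNodes", function(x) standardGeneric("circNodes"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("mirnaNodes", function(x) standardGeneric("mirnaNodes"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("mrnaNodes", function(x) standardGeneric("mrnaNodes"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneSetCollection-class
#' @param x an object
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
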
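#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of log2 expression, features x samples, with
#'   unique rownames (feature ids).
#' @param condition character or factor of length \code{ncol(values)} with
#'   values \code{"case"} / \code{"control"}.
#' @param datasetTag single string naming the study unit (e.g. a brain
#'   region x accession combination).
#' @return an \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' ed <- ExpressionDataset(m, c("case", "case", "control", "control"), "hippocampus")
#' datasetTag(ed)
#' @export
ExpressionDataset <- function(values, condition, datasetTag = "dataset1") {
    stopifnot(is.matrix(values), length(condition) == ncol(values),
              is.character(datasetTag), length(datasetTag) == 1L)
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("sample_%02d", seq_len(ncol(values)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(condition = as.character(condition),
                                       row.names = colnames(values)))
    S4Vectors::metadata(se)$datasetTag <- datasetTag
    new("ExpressionDataset", se)
}

#' @rdname ExpressionDataset-class
#' @export
setMethod("exprsValues", "ExpressionDataset", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleConditions", "ExpressionDataset", function(x)
    as.character(SummarizedExperiment::colData(x)$condition))

#' @rdname ExpressionDataset-class
#' @export
setMethod("datasetTag", "ExpressionDataset", function(x)
    S4Vectors::metadata(x)$datasetTag)

setMethod("show", "ExpressionDataset", function(object) {
    cond <- sampleConditions(object)
    cat("ExpressionDataset '", datasetTag(object), "': ",
        nrow(object), " features, ",
        sum(cond == "case"), " case / ", sum(cond == "control"),
        " control samples\n", sep = "")
})

#' @rdname ModeratedStats-class
#' @export
setMethod("statsTable", "ModeratedStats", function(x) x@table)

#' @rdname ModeratedStats-class
#' @export
setMethod("priorDf", "ModeratedStats", function(x) x@d0)

#' @rdname ModeratedStats-class
#' @export
setMethod("priorVar", "ModeratedStats", function(x) x@s0Sq)

setMethod("show", "ModeratedStats", function(object) {
    cat("ModeratedStats '", object@datasetTag, "': ",
        nrow(object@table), " features (", object@nCase, " case vs ",
        object@nControl, " control)\n",
        "  prior: d0 = ", format(object@d0, digits = 4),
        ", s0^2 = ", format(object@s0Sq, digits = 4), "\n", sep = "")
})

#' @rdname MetaDEResult-class
#' @export
setMethod("resultTable", "MetaDEResult", function(x) x@table)

setMethod("show", "MetaDEResult", function(object) {
    cat("MetaDEResult: ", nrow(object@table), " features combined over ",
        object@nDatasets, " dataset(s)\n", sep = "")
})

#' Construct a MirTargetSet from edge vectors
#'
#' @param mirna,target,targetClass character vectors of equal length;
#'   \code{targetClass} values are \code{"circRNA"} or \code{"mRNA"}.
#' @return a \linkS4class{MirTargetSet}; duplicate (miRNA, target) rows are
#'   collapsed silently (use [readInteractions()] for logged deduplication).
#' @export
MirTargetSet <- function(mirna = character(), target = character(),
                         targetClass = character()) {
    ed <- unique(data.frame(mirna = as.character(mirna),
                            target = as.character(target),
                            targetClass = as.character(targetClass),
                            stringsAsFactors = FALSE))
    rownames(ed) <- NULL
    new("MirTargetSet", edges = ed)
}

#' @rdname MirTargetSet-class
#' @export
setMethod("interactionEdges", "MirTargetSet", function(x) x@edges)

setMethod("show", "MirTargetSet", function(object) {
    ed <- object@edges
    cat("MirTargetSet: ", nrow(ed), " edges (",
        sum(ed$targetClass == "circRNA"), " miRNA-circRNA, ",
        sum(ed$targetClass == "mRNA"), " miRNA-mRNA); ",
        length(unique(ed$mirna)), " miRNAs\n", sep = "")
})

#' @rdname TripartiteNetwork-class
#' @export
setMethod("circNodes", "TripartiteNetwork", function(x) x@circNodes)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("mirnaNodes", "TripartiteNetwork", function(x) x@mirnaNodes)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("mrnaNodes", "TripartiteNetwork", function(x) x@mrnaNodes)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("networkEdges", "TripartiteNetwork", function(x) x@edges)

setMethod("show", "TripartiteNetwork", function(object) {
    cat("TripartiteNetwork: ",
        length(object@circNodes) + length(object@mirnaNodes) +
            length(object@mrnaNodes), " nodes (",
        length(object@circNodes), " circRNAs, ",
        length(object@mirnaNodes), " miRNAs, ",
        length(object@mrnaNodes), " mRNAs), ",
        nrow(object@edges), " edges\n", sep = "")
})

#' Construct a DiseaseAnnotation
#'
#' @param cdegSet,demirSet,knownGenes,knownMirs character id vectors (may be
#'   empty).
#' @return a \linkS4class{DiseaseAnnotation}.
#' @export
DiseaseAnnotation <- function(cdegSet = character(), demirSet = character(),
                              knownGenes = character(),
                              knownMirs = character()) {
    new("DiseaseAnnotation",
        cdegSet = unique(as.character(cdegSet)),
        demirSet = unique(as.character(demirSet)),
        knownGenes = unique(as.character(knownGenes)),
        knownMirs = unique(as.character(knownMirs)))
}

setMethod("show", "DiseaseAnnotation", function(object) {
    cat("DiseaseAnnotation: ", length(object@cdegSet), " CDEGs, ",
        length(object@demirSet), " DEmiRs, ",
        length(object@knownGenes), " known genes, ",
        length(object@knownMirs), " known miRNAs\n", sep = "")
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (term id -> gene ids).
#' @param descriptions optional named character of term descriptions;
#'   defaults to the term ids.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(descriptions))
        descriptions <- stats::setNames(names(sets), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)])
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

setMethod("show", "GeneSetCollection", function(object) {
    sz <- lengths(object@sets)
    cat("GeneSetCollection: ", length(sz), " sets, sizes ",
        if (length(sz)) paste0(min(sz), "-", max(sz)) else "NA", "\n",
        sep = "")
})

setMethod("show", "PowerLawFit", function(object) {
    cat("PowerLawFit (", object@method, " MLE): alpha = ",
        format(object@alpha, digits = 4), ", xmin = ", object@xmin,
        ", n = ", object@nTail, "\n  log-log slope = ",
        format(object@loglogSlope, digits = 4), ", R^2 = ",
        format(object@loglogR2, digits = 4), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig (seed ", object@seed, "): ",
        object@nDatasets, " dataset(s) x ", object@nFeatures, " features (",
        object@nCase, "+", object@nControl, " samples), fracDE = ",
        object@fracDE, "\n  network: ", object@nCirc, " circRNAs, ",
        object@nMir, " miRNAs, ", object@nMrna, " mRNAs; ",
        object@nPlantedPairs, " planted pairs sharing ", object@sharedPool,
        " miRNAs\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: ", length(object@deFeatures), " DE features, ",
        length(object@deMirs), " DE miRNAs, ",
        nrow(object@plantedTriples), " planted triples, risk circRNA '",
        object@plantedRiskCirc, "'\n", sep = "")
})
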
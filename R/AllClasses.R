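#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionDataset: a two-condition log2 expression matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' normalized, log2-scale expression matrix (features x samples) together
#' with a case/control sample annotation and a dataset tag identifying the
#' study unit (for brain-region microarray data, one tag per region x
#' accession).
#'
#' Validity requires a single assay named \code{"exprs"} with finite values,
#' unique feature ids, a \code{condition} column in \code{colData} taking
#' values in \code{c("case", "control")}, and at least two samples per
#' condition (otherwise a pooled within-group variance is undefined).
#'
#' @seealso [ExpressionDataset()] for the constructor, [moderatedT()] for
#'   the differential-expression statistic computed from this class.
#' @name ExpressionDataset-class
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, "assay 'exprs' must be numeric and finite")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'condition' column")
    else {
        cond <- as.character(cd$condition)
        if (!all(cond %in% c("case", "control")))
            msg <- c(msg, "condition values must be 'case' or 'control'")
        else if (sum(cond == "case") < 2L || sum(cond == "control") < 2L)
            msg <- c(msg, "need >= 2 samples per condition")
    }
    if (length(msg)) msg else TRUE
})

#' ModeratedStats: per-feature empirical-Bayes moderated t results
#'
#' Holds, for one \linkS4class{ExpressionDataset}, the per-feature effect
#' (mean(case) - mean(control), log2 units), pooled sample variance, residual
#' degrees of freedom, posterior (moderated) variance, moderated t and
#' two-sided p-value, plus the dataset-level prior hyperparameters
#' \code{d0} (prior degrees of freedom, possibly \code{Inf}) and \code{s0Sq}
#' (prior variance).
#'
#' @slot table data.frame with columns \code{feature}, \code{effect},
#'   \code{sSq}, \code{dg}, \code{sTildeSq}, \code{tMod}, \code{pTwo}.
#' @slot d0,s0Sq numeric(1) prior hyperparameters.
#' @slot nCase,nControl integer(1) group sizes.
#' @slot datasetTag character(1).
#' @name ModeratedStats-class
#' @exportClass ModeratedStats
setClass("ModeratedStats",
    representation(table = "data.frame", d0 = "numeric", s0Sq = "numeric",
                   nCase = "integer", nControl = "integer",
                   datasetTag = "character"))

setValidity("ModeratedStats", function(object) {
    tab <- object@table
    need <- c("feature", "effect", "sSq", "dg", "sTildeSq", "tMod", "pTwo")
    msg <- character()
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, paste("table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(tab$pTwo < 0 | tab$pTwo > 1, na.rm = TRUE))
            msg <- c(msg, "pTwo must lie in [0, 1]")
        d0 <- object@d0
        if (is.finite(d0) && d0 > 0) {
            lo <- pmin(tab$sSq, object@s0Sq); hi <- pmax(tab$sSq, object@s0Sq)
            bad <- tab$sTildeSq < lo - 1e-12 | tab$sTildeSq > hi + 1e-12
            if (any(bad))
                msg <- c(msg, "sTildeSq must lie between sSq and s0Sq")
        }
    }
    if (length(object@d0) != 1L || object@d0 < 0)
        msg <- c(msg, "d0 must be a single non-negative number (or Inf)")
    if (length(msg)) msg else TRUE
})

#' MetaDEResult: combined differential-expression evidence across datasets
#'
#' Per-feature signed combined z (weighted Stouffer), two-sided meta p-value,
#' Benjamini-Hochberg adjusted p-value, direction (sign of the combined z),
#' and the number of datasets where the feature was observed.
#'
#' @slot table data.frame with columns \code{feature}, \code{zMeta},
#'   \code{pTwo}, \code{fdr}, \code{direction}, \code{nDatasetsObserved}.
#' @slot nDatasets integer(1) number of datasets combined.
#' @name MetaDEResult-class
#' @exportClass MetaDEResult
setClass("MetaDEResult",
    representation(table = "data.frame", nDatasets = "integer"))

setValidity("MetaDEResult", function(object) {
    tab <- object@table
    need <- c("feature", "zMeta", "pTwo", "fdr", "direction",
              "nDatasetsObserved")
    if (!all(need %in% colnames(tab)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (any(tab$fdr < tab$pTwo - 1e-12))
        return("fdr must be >= pTwo for every feature")
    if (any(tab$fdr < 0 | tab$fdr > 1))
        return("fdr must lie in [0, 1]")
    TRUE
})

#' MirTargetSet: typed miRNA-target interaction edges
#'
#' A deduplicated set of (miRNA, target) edges where each target is either a
#' circRNA or an mRNA. This is the raw material from which the ceRNA network
#' is built; a target id must carry exactly one class.
#'
#' @slot edges data.frame with columns \code{mirna}, \code{target},
#'   \code{targetClass} (values \code{"circRNA"} or \code{"mRNA"}).
#' @seealso [readInteractions()], [buildCirceNet()]
#' @name MirTargetSet-class
#' @exportClass MirTargetSet
setClass("MirTargetSet", representation(edges = "data.frame"))

setValidity("MirTargetSet", function(object) {
    ed <- object@edges
    need <- c("mirna", "target", "targetClass")
    msg <- character()
    if (!all(need %in% colnames(ed)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (!all(ed$targetClass %in% c("circRNA", "mRNA")))
        msg <- c(msg, "targetClass must be 'circRNA' or 'mRNA'")
    if (anyDuplicated(ed[, c("mirna", "target")]))
        msg <- c(msg, "duplicate (mirna, target) pairs are not allowed")
    cls <- unique(ed[, c("target", "targetClass")])
    if (anyDuplicated(cls$target))
        msg <- c(msg, "a target id must have exactly one class")
    if (length(msg)) msg else TRUE
})

#' TripartiteNetwork: a circRNA-miRNA-mRNA competitive network
#'
#' Node sets for the three RNA classes plus typed (miRNA, target) edges.
#' Instances include the global ceRNA network built by [buildCirceNet()] and
#' the disease-specific subnetwork from [extractDiseaseNetwork()]. Every edge
#' endpoint belongs to exactly one node set and every node has degree >= 1
#' (nodes exist only through retained crosstalk edges).
#'
#' @slot circNodes,mirnaNodes,mrnaNodes character vectors of node ids.
#' @slot edges data.frame with columns \code{mirna}, \code{target},
#'   \code{targetClass}.
#' @name TripartiteNetwork-class
#' @exportClass TripartiteNetwork
setClass("TripartiteNetwork",
    representation(circNodes = "character", mirnaNodes = "character",
                   mrnaNodes = "character", edges = "data.frame"))

setValidity("TripartiteNetwork", function(object) {
    ed <- object@edges
    msg <- character()
    if (!all(c("mirna", "target", "targetClass") %in% colnames(ed)))
        return("edges must have columns mirna, target, targetClass")
    all3 <- c(object@circNodes, object@mirnaNodes, object@mrnaNodes)
    if (anyDuplicated(all3))
        msg <- c(msg, "node sets must be disjoint")
    if (nrow(ed)) {
        if (!all(ed$mirna %in% object@mirnaNodes))
            msg <- c(msg, "every edge mirna must be a miRNA node")
        tgt <- ifelse(ed$targetClass == "circRNA",
                      ed$target %in% object@circNodes,
                      ed$target %in% object@mrnaNodes)
        if (!all(tgt))
            msg <- c(msg, "every edge target must be a node of its class")
        touched <- unique(c(ed$mirna, ed$target))
        if (!all(all3 %in% touched))
            msg <- c(msg, "every node must have degree >= 1")
    } else if (length(all3)) {
        msg <- c(msg, "non-empty node sets require edges")
    }
    if (length(msg)) msg else TRUE
})

#' DiseaseAnnotation: DE and curated-disease id sets
#'
#' The four id sets that drive disease subnetwork extraction and risk
#' flagging: consistently differentially expressed genes (CDEGs),
#' differentially expressed miRNAs (DEmiRs), and curated known disease genes
#' and miRNAs. Sets may be empty and may overlap the network only partially.
#'
#' @slot cdegSet,demirSet,knownGenes,knownMirs character vectors.
#' @seealso [extractDiseaseNetwork()], [flagRiskTriples()]
#' @name DiseaseAnnotation-class
#' @exportClass DiseaseAnnotation
setClass("DiseaseAnnotation",
    representation(cdegSet = "character", demirSet = "character",
                   knownGenes = "character", knownMirs = "character"))

#' GeneSetCollection: named gene sets for over-representation analysis
#'
#' @slot sets named list of character vectors (term id -> gene ids); no
#'   empty sets, unique term ids.
#' @slot descriptions named character vector of term descriptions.
#' @seealso [readGMT()], [runORA()]
#' @name GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    msg <- character()
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
        msg <- c(msg, "sets must have unique non-empty names")
    if (any(lengths(s) == 0L))
        msg <- c(msg, "empty gene sets are not allowed")
    if (!all(names(s) %in% names(object@descriptions)))
        msg <- c(msg, "every term needs a description entry")
    if (length(msg)) msg else TRUE
})

#' PowerLawFit: degree-distribution power-law fit
#'
#' @slot alpha numeric(1) fitted exponent (method given by \code{method}).
#' @slot method character(1), \code{"discrete"} (zeta-function MLE) or
#'   \code{"continuous"} (continuous-MLE approximation).
#' @slot xmin numeric(1) lower cutoff.
#' @slot nTail integer(1) number of degrees >= xmin used.
#' @slot loglogSlope,loglogR2 numeric(1) least-squares fit of log frequency
#'   on log degree over nonzero histogram bins.
#' @seealso [fitPowerLaw()]
#' @name PowerLawFit-class
#' @exportClass PowerLawFit
setClass("PowerLawFit",
    representation(alpha = "numeric", method = "character", xmin = "numeric",
                   nTail = "integer", loglogSlope = "numeric",
                   loglogR2 = "numeric"))

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (object@nTail >= 2L && object@alpha <= 1)
        msg <- c(msg, "alpha must exceed 1 for a normalizable tail")
    if (!is.na(object@loglogR2) &&
        (object@loglogR2 < 0 || object@loglogR2 > 1))
        msg <- c(msg, "loglogR2 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Encodes every tunable of the synthetic study: expression design (number of
#' features, group sizes, number of datasets), differential-expression
#' structure (fraction DE, log2 effect-size distribution), the variance prior
#' (scaled inverse chi-square with \code{d0} prior degrees of freedom and
#' \code{s0Sq} prior variance, matching the moderated-t model), interaction
#' network structure (node counts, planted circRNA-mRNA pairs each sharing
#' \code{sharedPool} miRNAs, background edge probability), curated known-list
#' sizes, and gene-set collection shape. A single integer seed makes every
#' generator deterministic; each generator draws from its own derived stream.
#'
#' @seealso [simulationConfig()] for the constructor with documented
#'   defaults, [simulateStudy()] for the orchestrated generator.
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        seed = "integer",
        nFeatures = "integer", nCase = "integer", nControl = "integer",
        nDatasets = "integer", fracDE = "numeric",
        effectMean = "numeric", effectSd = "numeric",
        d0 = "numeric", s0Sq = "numeric",
        nCirc = "integer", nMir = "integer", nMrna = "integer",
        nPlantedPairs = "integer", riskPairs = "integer",
        sharedPool = "integer", backgroundEdgeProb = "numeric",
        nKnownGenes = "integer", nKnownMirs = "integer",
        nCaseMir = "integer", nControlMir = "integer", fracDEMir = "numeric",
        nGeneSets = "integer", geneSetMin = "integer", geneSetMax = "integer",
        baselineMean = "numeric", baselineSd = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    num <- c(fracDE = object@fracDE, effectMean = object@effectMean,
             effectSd = object@effectSd, s0Sq = object@s0Sq,
             backgroundEdgeProb = object@backgroundEdgeProb,
             fracDEMir = object@fracDEMir,
             baselineMean = object@baselineMean,
             baselineSd = object@baselineSd)
    if (any(!is.finite(num)))
        msg <- c(msg, paste("non-finite parameter(s):",
                            paste(names(num)[!is.finite(num)], collapse = ", ")))
    if (is.na(object@d0) || object@d0 <= 0)  # Inf allowed
        msg <- c(msg, "d0 must be positive (Inf allowed)")
    if (object@s0Sq <= 0) msg <- c(msg, "s0Sq must be positive")
    for (p in c("fracDE", "backgroundEdgeProb", "fracDEMir")) {
        v <- slot(object, p)
        if (v < 0 || v > 1) msg <- c(msg, paste(p, "must lie in [0, 1]"))
    }
    cnt <- c(nFeatures = object@nFeatures, nCase = object@nCase,
             nControl = object@nControl, nDatasets = object@nDatasets,
             nCirc = object@nCirc, nMir = object@nMir, nMrna = object@nMrna,
             nPlantedPairs = object@nPlantedPairs,
             riskPairs = object@riskPairs, sharedPool = object@sharedPool,
             nCaseMir = object@nCaseMir, nControlMir = object@nControlMir,
             nGeneSets = object@nGeneSets, geneSetMin = object@geneSetMin,
             geneSetMax = object@geneSetMax)
    if (any(is.na(cnt) | cnt < 1L))
        msg <- c(msg, paste("counts must be >= 1:",
                            paste(names(cnt)[is.na(cnt) | cnt < 1L],
                                  collapse = ", ")))
    if (object@nKnownGenes < 0L || object@nKnownMirs < 0L)
        msg <- c(msg, "known-list sizes must be >= 0")
    if (object@nMrna > object@nFeatures)
        msg <- c(msg, "nMrna (network mRNA nodes) cannot exceed nFeatures")
    if (object@sharedPool > object@nMir)
        msg <- c(msg, "sharedPool cannot exceed nMir")
    if (object@riskPairs > object@nPlantedPairs)
        msg <- c(msg, "riskPairs cannot exceed nPlantedPairs")
    if (object@nPlantedPairs - object@riskPairs + 1L > object@nCirc)
        msg <- c(msg, "not enough circRNAs for the planted pairs")
    if (object@nPlantedPairs > object@nMrna)
        msg <- c(msg, "not enough mRNA nodes for distinct planted partners")
    if (object@geneSetMin > object@geneSetMax)
        msg <- c(msg, "geneSetMin must be <= geneSetMax")
    if (object@geneSetMax > object@nMrna)
        msg <- c(msg, "gene-set sizes cannot exceed the mRNA universe")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic study
#'
#' @slot deFeatures,deMirs ids planted as differentially expressed.
#' @slot deSigns named numeric (+1/-1) direction per DE feature.
#' @slot plantedTriples data.frame(circ, mirna, mrna, sharedCount).
#' @slot plantedRiskCirc character(1) the circRNA planted to dominate the
#'   risk-crosstalk ranking.
#' @slot knownGenes,knownMirs curated known-disease id sets.
#' @slot enrichedTerm character(1) id of the planted enriched gene set.
#' @name GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(deFeatures = "character", deMirs = "character",
                   deSigns = "numeric", plantedTriples = "data.frame",
                   plantedRiskCirc = "character", knownGenes = "character",
                   knownMirs = "character", enrichedTerm = "character"))
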
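#' Extract the disease-specific ceRNA subnetwork
#'
#' A miRNA-mediated ceRNA crosstalk triple is retained when it contains
#' differential-expression evidence: its mRNA is a consistently
#' differentially expressed gene (CDEG) or its mediating miRNA is a
#' differentially expressed miRNA (DEmiR). The subnetwork is rebuilt from
#' the retained triples with the same edge-closure rule as
#' [buildCirceNet()]. circRNAs themselves are never tested (no circRNA
#' expression is measured on the platforms this models).
#'
#' @param triples data.frame of crosstalk triples from [buildCirceNet()].
#' @param annotation a \linkS4class{DiseaseAnnotation}.
#' @return list with elements \code{network} and \code{triples} (the
#'   retained subset).
#' @export
extractDiseaseNetwork <- function(triples, annotation) {
    stopifnot(is.data.frame(triples), is(annotation, "DiseaseAnnotation"))
    if (length(annotation@cdegSet) == 0L && length(annotation@demirSet) == 0L)
        warning("both DE sets are empty; disease network will be empty")
    keep <- triples$mrna %in% annotation@cdegSet |
            triples$mirna %in% annotation@demirSet
    sub <- triples[keep, , drop = FALSE]
    rownames(sub) <- NULL
    list(network = networkFromTriples(sub), triples = sub)
}

#' Flag risk crosstalks by known-disease coverage
#'
#' Within the disease subnetwork, a crosstalk triple is a risk crosstalk when
#' it contains at least one curated known disease id: its mRNA is a known
#' disease gene or its mediating miRNA is a known disease miRNA.
#'
#' @param diseaseTriples data.frame of triples from
#'   [extractDiseaseNetwork()].
#' @param annotation a \linkS4class{DiseaseAnnotation}.
#' @return data.frame of flagged triples (subset of the input).
#' @export
flagRiskTriples <- function(diseaseTriples, annotation) {
    stopifnot(is.data.frame(diseaseTriples),
              is(annotation, "DiseaseAnnotation"))
    keep <- diseaseTriples$mrna %in% annotation@knownGenes |
            diseaseTriples$mirna %in% annotation@knownMirs
    out <- diseaseTriples[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rank circRNAs by risk-crosstalk frequency
#'
#' circRNAs are ordered by how many risk crosstalks they participate in
#' (descending), ties broken by ascending id so runs are reproducible. When
#' the full triple set is supplied, a normalized coverage column (risk
#' triples / total triples per circRNA) is added as auxiliary information;
#' the ranking always uses the raw count.
#'
#' @param riskTriples data.frame from [flagRiskTriples()].
#' @param allTriples optional data.frame of all (disease) triples, used only
#'   for the \code{totalCount} and \code{coverage} columns.
#' @return data.frame with columns \code{circ}, \code{riskTripleCount},
#'   optionally \code{totalCount} and \code{coverage}, and \code{rank}
#'   (1-based). Empty input yields an empty ranking.
#' @export
rankCircRNAs <- function(riskTriples, allTriples = NULL) {
    stopifnot(is.data.frame(riskTriples))
    if (nrow(riskTriples) == 0L) {
        out <- data.frame(circ = character(), riskTripleCount = integer(),
                          rank = integer(), stringsAsFactors = FALSE)
        return(out)
    }
    cnt <- as.data.frame(table(circ = riskTriples$circ),
                         stringsAsFactors = FALSE)
    names(cnt) <- c("circ", "riskTripleCount")
    cnt <- cnt[cnt$riskTripleCount > 0L, , drop = FALSE]
    cnt <- cnt[order(-cnt$riskTripleCount, cnt$circ), , drop = FALSE]
    if (!is.null(allTriples)) {
        tot <- table(allTriples$circ)
        cnt$totalCount <- as.integer(tot[cnt$circ])
        cnt$coverage <- cnt$riskTripleCount / cnt$totalCount
    }
    cnt$rank <- seq_len(nrow(cnt))
    rownames(cnt) <- NULL
    cnt
}

#' Neighborhood of one circRNA in the disease network
#'
#' The subnetwork induced by all triples containing the given circRNA,
#' together with a per-node partner summary (role, and known/DE flags when an
#' annotation is supplied) — the unit used to characterize a prioritized
#' circRNA's ceRNA context.
#'
#' @param circId single circRNA id present in \code{triples}.
#' @param triples data.frame of (disease) triples.
#' @param annotation optional \linkS4class{DiseaseAnnotation} for the flags.
#' @return list with \code{network} (a \linkS4class{TripartiteNetwork}),
#'   \code{triples}, and \code{summary} (data.frame \code{id}, \code{role},
#'   \code{isKnown}, \code{isDE}).
#' @export
circNeighborhood <- function(circId, triples, annotation = NULL) {
    stopifnot(is.character(circId), length(circId) == 1L,
              is.data.frame(triples))
    present <- unique(triples$circ)
    if (!circId %in% present) {
        d <- utils::adist(circId, present)
        near <- present[order(d)][seq_len(min(3L, length(present)))]
        stop("circRNA '", circId, "' not present; nearest ids: ",
             paste(near, collapse = ", "))
    }
    sub <- triples[triples$circ == circId, , drop = FALSE]
    rownames(sub) <- NULL
    mirs <- sort(unique(sub$mirna)); genes <- sort(unique(sub$mrna))
    summ <- data.frame(
        id = c(circId, mirs, genes),
        role = c("circRNA", rep("miRNA", length(mirs)),
                 rep("mRNA", length(genes))),
        stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
        stopifnot(is(annotation, "DiseaseAnnotation"))
        summ$isKnown <- (summ$role == "mRNA" &
                             summ$id %in% annotation@knownGenes) |
                        (summ$role == "miRNA" &
                             summ$id %in% annotation@knownMirs)
        summ$isDE <- (summ$role == "mRNA" & summ$id %in% annotation@cdegSet) |
                     (summ$role == "miRNA" & summ$id %in% annotation@demirSet)
    }
    list(network = networkFromTriples(sub), triples = sub, summary = summ)
}
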
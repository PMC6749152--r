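#' Combine moderated-t evidence across datasets (weighted Stouffer)
#'
#' Each dataset contributes, per feature, a signed z-score
#' \eqn{z_i = \mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1 - p_i/2)} from its
#' two-sided moderated-t p-value. Evidence is combined over the datasets in
#' which a feature is observed:
#' \deqn{z_{meta} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}, \qquad
#'       p = 2\{1 - \Phi(|z_{meta}|)\},}
#' with weights defaulting to the square root of each dataset's total sample
#' size. Benjamini-Hochberg adjusted p-values ([bhAdjust()]) and the sign of
#' \eqn{z_{meta}} (direction) are attached. Features observed in only some
#' datasets are combined over those datasets, with the count recorded in
#' \code{nDatasetsObserved}; a feature observed nowhere cannot occur by
#' construction (the union of dataset features is used).
#'
#' @param statsList list of \linkS4class{ModeratedStats}, one per dataset.
#' @param weights optional numeric vector, one per dataset; default
#'   \code{sqrt(nCase + nControl)} per dataset.
#' @return a \linkS4class{MetaDEResult}.
#' @seealso [moderatedT()], [selectDE()]
#' @export
combineDatasets <- function(statsList, weights = NULL) {
    stopifnot(is.list(statsList), length(statsList) >= 1L,
              all(vapply(statsList, is, logical(1), "ModeratedStats")))
    if (is.null(weights))
        weights <- vapply(statsList,
                          function(s) sqrt(s@nCase + s@nControl), numeric(1))
    stopifnot(length(weights) == length(statsList), all(weights > 0))
    weights <- unname(weights)

    perDataset <- lapply(seq_along(statsList), function(i) {
        tab <- statsTable(statsList[[i]])
        p <- pmax(tab$pTwo, 1e-300)
        z <- sign(tab$effect) * stats::qnorm(p / 2, lower.tail = FALSE)
        data.frame(feature = tab$feature, z = z, w = weights[i],
                   stringsAsFactors = FALSE)
    })
    all <- data.table::rbindlist(perDataset)
    feature <- z <- w <- NULL  # appease R CMD check
    comb <- all[, list(zMeta = sum(w * z) / sqrt(sum(w^2)),
                       nDatasetsObserved = .N), by = feature]
    comb <- as.data.frame(comb)
    comb <- comb[order(comb$feature), , drop = FALSE]
    rownames(comb) <- NULL
    comb$pTwo <- 2 * stats::pnorm(-abs(comb$zMeta))
    comb$fdr <- bhAdjust(comb$pTwo, features = comb$feature)
    comb$direction <- sign(comb$zMeta)
    tab <- comb[, c("feature", "zMeta", "pTwo", "fdr", "direction",
                    "nDatasetsObserved")]
    new("MetaDEResult", table = tab, nDatasets = length(statsList))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic step-up adjustment with monotonicity enforcement:
#' \eqn{\tilde{p}_{(i)} = \min_{j \ge i} \min(1, m\, p_{(j)} / j)}.
#' Shared by the differential-expression and enrichment modules so both use
#' bit-identical arithmetic.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @param features optional ids used to name offenders in error messages.
#' @return numeric vector of adjusted p-values, same order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p, features = NULL) {
    if (any(is.na(p))) {
        bad <- which(is.na(p))
        lab <- if (!is.null(features)) paste(features[bad], collapse = ", ")
               else paste(bad, collapse = ", ")
        stop("NA/NaN p-values for: ", lab)
    }
    stopifnot(all(p >= 0 & p <= 1))
    m <- length(p)
    if (m == 0L) return(numeric(0))
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    adj
}

#' Select differentially expressed features at an FDR threshold
#'
#' Features with BH-adjusted p strictly below the threshold are returned
#' together with their direction of change. Conventional thresholds are 0.01
#' for the cross-dataset gene analysis and 0.05 for the single-dataset miRNA
#' analysis.
#'
#' @param result a \linkS4class{MetaDEResult}.
#' @param fdrThreshold single value in (0, 1].
#' @return data.frame with columns \code{feature}, \code{direction},
#'   \code{fdr}, ordered by \code{fdr}.
#' @export
selectDE <- function(result, fdrThreshold = 0.05) {
    stopifnot(is(result, "MetaDEResult"))
    if (!is.numeric(fdrThreshold) || length(fdrThreshold) != 1L ||
        is.na(fdrThreshold) || fdrThreshold <= 0 || fdrThreshold > 1)
        stop("fdrThreshold must lie in (0, 1]")
    tab <- resultTable(result)
    sel <- tab[tab$fdr < fdrThreshold, c("feature", "direction", "fdr")]
    sel <- sel[order(sel$fdr, sel$feature), , drop = FALSE]
    rownames(sel) <- NULL
    sel
}

#' Single-dataset empirical-Bayes differential expression
#'
#' Convenience wrapper for the miRNA analysis: moderated t on one dataset,
#' wrapped as a one-dataset \linkS4class{MetaDEResult} (the combined z then
#' equals the dataset's own signed z) so that [selectDE()] applies uniformly.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param ... passed to [moderatedT()].
#' @return a \linkS4class{MetaDEResult}.
#' @export
singleDatasetDE <- function(dataset, ...) {
    combineDatasets(list(moderatedT(dataset, ...)))
}
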
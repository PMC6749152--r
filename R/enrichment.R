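#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N} universe genes,
#' \eqn{K} annotated, \eqn{n} drawn) — the over-representation p-value for
#' observing \code{k} query genes inside a term. Delegates to
#' \code{stats::phyper} with \code{lower.tail = FALSE}, which accumulates the
#' tail stably; bounds are validated and violations reported with the
#' offending quadruple.
#'
#' @param k observed overlap (vectorized).
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return numeric vector of upper-tail probabilities.
#' @examples
#' hypergeomUpper(5, 5, 5, 10)  # 1/choose(10,5) = 0.003968...
#' @export
hypergeomUpper <- function(k, K, n, N) {
    len <- max(length(k), length(K), length(n), length(N))
    k <- rep_len(k, len); K <- rep_len(K, len)
    n <- rep_len(n, len); N <- rep_len(N, len)
    bad <- which(K < 0 | n < 0 | K > N | n > N | k < 0 | k > pmin(K, n))
    if (length(bad))
        stop("invalid hypergeometric quadruple (k, K, n, N) = (",
             k[bad[1]], ", ", K[bad[1]], ", ", n[bad[1]], ", ", N[bad[1]],
             ")")
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Hypergeometric test of a query gene list against every term of a gene-set
#' collection, within an explicit background universe, with
#' Benjamini-Hochberg correction ([bhAdjust()], shared bit-for-bit with the
#' differential-expression module). Query genes outside the universe are
#' dropped with a logged count; terms are intersected with the universe and
#' only terms with at least one universe gene are tested. Results are sorted
#' by p-value, ties by term id.
#'
#' The background universe dominates ORA results and must therefore be
#' chosen deliberately; a natural default for ceRNA work is the mRNA node
#' set of the analyzed network.
#'
#' @param query character vector of gene ids.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background gene ids.
#' @return data.frame with columns \code{term}, \code{description},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{fdr}.
#' @export
runORA <- function(query, collection, universe) {
    stopifnot(is(collection, "GeneSetCollection"))
    universe <- unique(as.character(universe))
    if (length(universe) == 0L) stop("universe must be non-empty")
    query <- unique(as.character(query))
    dropped <- sum(!query %in% universe)
    if (dropped > 0L)
        message(dropped, " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0L)
        stop("no query genes remain after intersecting with the universe")
    sets <- lapply(geneSets(collection), intersect, universe)
    keep <- lengths(sets) >= 1L
    sets <- sets[keep]
    if (length(sets) == 0L) stop("no term overlaps the universe")
    N <- length(universe); n <- length(query)
    K <- lengths(sets)
    k <- vapply(sets, function(g) length(intersect(g, query)), integer(1))
    p <- hypergeomUpper(k, K, n, N)
    res <- data.frame(term = names(sets),
                      description = unname(
                          setDescriptions(collection)[names(sets)]),
                      k = unname(k), K = unname(K), n = n, N = N,
                      p = unname(p), stringsAsFactors = FALSE)
    res$fdr <- bhAdjust(res$p, features = res$term)
    res <- res[order(res$p, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as term id, description,
#' then gene ids.
#'
#' @param path file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("GMT file is empty: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop("GMT line ", short[1], " has fewer than 3 fields")
    ids <- vapply(parts, `[`, character(1), 1L)
    desc <- vapply(parts, `[`, character(1), 2L)
    sets <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(sets) <- ids
    GeneSetCollection(sets, stats::setNames(desc, ids))
}

#' Write a GMT gene-set file
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    sets <- geneSets(collection)
    desc <- setDescriptions(collection)
    lines <- vapply(names(sets), function(id) {
        paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
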
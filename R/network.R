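#' Read a miRNA-target interaction table
#'
#' Expects a TSV with header columns \code{mirna}, \code{target},
#' \code{target_class} (class values \code{circRNA} / \code{mRNA}).
#' Duplicate (miRNA, target) rows are dropped with a logged count; a target
#' id appearing with both classes is a hard error naming the offender; an
#' unknown class token is an error naming the row.
#'
#' @param path TSV file path.
#' @return a \linkS4class{MirTargetSet}.
#' @seealso [writeInteractions()] for the inverse.
#' @export
readInteractions <- function(path) {
    if (!file.exists(path)) stop("interaction file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE)
    need <- c("mirna", "target", "target_class")
    if (!all(need %in% colnames(dt)))
        stop("interaction TSV must have columns: ",
             paste(need, collapse = ", "))
    if (nrow(dt) == 0L) {
        warning("empty interaction table: ", path)
        return(new("MirTargetSet",
                   edges = data.frame(mirna = character(),
                                      target = character(),
                                      targetClass = character())))
    }
    bad <- which(!dt$target_class %in% c("circRNA", "mRNA"))
    if (length(bad))
        stop("unknown target_class '", dt$target_class[bad[1]],
             "' in row ", bad[1], " of ", path)
    dup <- duplicated(dt[, c("mirna", "target")])
    if (any(dup))
        message(sum(dup), " duplicate interaction row(s) dropped")
    dt <- dt[!dup, , drop = FALSE]
    conf <- unique(dt[, c("target", "target_class")])
    confTargets <- conf$target[duplicated(conf$target)]
    if (length(confTargets))
        stop("target(s) annotated with both classes: ",
             paste(unique(confTargets), collapse = ", "))
    ed <- data.frame(mirna = dt$mirna, target = dt$target,
                     targetClass = dt$target_class, stringsAsFactors = FALSE)
    rownames(ed) <- NULL
    new("MirTargetSet", edges = ed)
}

#' Shared-miRNA counts for every circRNA-mRNA pair
#'
#' The size of the intersection of the miRNA-regulator sets of each circRNA
#' and mRNA that share at least one miRNA — the quantity the competitive
#' regulation (ceRNA) filter thresholds. Computed through an inverted index
#' on the miRNA (a join of the miRNA-circRNA and miRNA-mRNA edge lists on
#' the miRNA key, then a pair count), never by an all-pairs scan.
#'
#' @param interactions a \linkS4class{MirTargetSet}.
#' @return data.frame with columns \code{circ}, \code{mrna},
#'   \code{sharedCount}; pairs with zero overlap are absent.
#' @export
sharedMirnaCounts <- function(interactions) {
    stopifnot(is(interactions, "MirTargetSet"))
    joined <- jointTriples(interactions)
    if (nrow(joined) == 0L)
        return(data.frame(circ = character(), mrna = character(),
                          sharedCount = integer()))
    circ <- mrna <- NULL
    cnt <- joined[, list(sharedCount = .N), by = list(circ, mrna)]
    cnt <- as.data.frame(cnt)
    cnt <- cnt[order(cnt$circ, cnt$mrna), , drop = FALSE]
    rownames(cnt) <- NULL
    cnt
}

# Inverted-index join: all (circ, mirna, mrna) with the miRNA targeting both.
jointTriples <- function(interactions) {
    ed <- data.table::as.data.table(interactionEdges(interactions))
    targetClass <- mirna <- target <- NULL
    circE <- ed[targetClass == "circRNA", list(mirna = mirna, circ = target)]
    mrnaE <- ed[targetClass == "mRNA", list(mirna = mirna, mrna = target)]
    if (nrow(circE) == 0L || nrow(mrnaE) == 0L)
        return(data.table::data.table(circ = character(),
                                      mirna = character(),
                                      mrna = character()))
    merge(circE, mrnaE, by = "mirna", allow.cartesian = TRUE)
}

#' Build the circRNA-miRNA-mRNA competitive network (ceRNA network)
#'
#' A circRNA-mRNA pair qualifies for competitive (ceRNA) regulation when the
#' two RNAs share at least \code{minShared} miRNA regulators. Every
#' (circRNA, miRNA, mRNA) combination with a qualifying pair and the miRNA in
#' their shared regulator set is one miRNA-mediated ceRNA crosstalk triple.
#' The network retains exactly those miRNA-circRNA and miRNA-mRNA
#' interactions that participate in at least one triple; nodes are the
#' endpoints of retained edges (so every node has degree >= 1).
#'
#' @param interactions a \linkS4class{MirTargetSet}.
#' @param minShared minimum number of shared miRNAs for a circRNA-mRNA pair
#'   (default 5).
#' @return list with elements \code{network} (a
#'   \linkS4class{TripartiteNetwork}) and \code{triples} (data.frame
#'   \code{circ}, \code{mirna}, \code{mrna}, \code{sharedCount}).
#' @examples
#' x <- MirTargetSet(mirna = rep(paste0("m", 1:5), 2),
#'                   target = rep(c("c1", "g1"), each = 5),
#'                   targetClass = rep(c("circRNA", "mRNA"), each = 5))
#' net <- buildCirceNet(x, minShared = 5)
#' net$network
#' @export
buildCirceNet <- function(interactions, minShared = 5L) {
    stopifnot(is(interactions, "MirTargetSet"))
    if (!is.numeric(minShared) || length(minShared) != 1L ||
        is.na(minShared) || minShared < 1)
        stop("minShared must be a single number >= 1")
    joined <- jointTriples(interactions)
    circ <- mrna <- sharedCount <- NULL
    if (nrow(joined) == 0L)
        return(list(network = emptyNetwork(), triples = emptyTriples()))
    cnt <- joined[, list(sharedCount = .N), by = list(circ, mrna)]
    qual <- cnt[sharedCount >= minShared]
    triples <- merge(joined, qual, by = c("circ", "mrna"))
    triples <- as.data.frame(triples)[, c("circ", "mirna", "mrna",
                                          "sharedCount")]
    triples <- triples[order(triples$circ, triples$mirna, triples$mrna), ,
                       drop = FALSE]
    rownames(triples) <- NULL
    list(network = networkFromTriples(triples), triples = triples)
}

emptyTriples <- function() {
    data.frame(circ = character(), mirna = character(), mrna = character(),
               sharedCount = integer(), stringsAsFactors = FALSE)
}

emptyNetwork <- function() {
    new("TripartiteNetwork", circNodes = character(),
        mirnaNodes = character(), mrnaNodes = character(),
        edges = data.frame(mirna = character(), target = character(),
                           targetClass = character(),
                           stringsAsFactors = FALSE))
}

#' Rebuild a tripartite network from a set of crosstalk triples
#'
#' Applies the edge-closure rule shared by the global and disease-specific
#' networks: edges are exactly the (miRNA, circRNA) and (miRNA, mRNA)
#' interactions occurring in at least one triple, nodes are their endpoints.
#'
#' @param triples data.frame with columns \code{circ}, \code{mirna},
#'   \code{mrna}.
#' @return a \linkS4class{TripartiteNetwork}.
#' @export
networkFromTriples <- function(triples) {
    if (nrow(triples) == 0L) return(emptyNetwork())
    circEdges <- unique(data.frame(mirna = triples$mirna,
                                   target = triples$circ,
                                   targetClass = "circRNA",
                                   stringsAsFactors = FALSE))
    mrnaEdges <- unique(data.frame(mirna = triples$mirna,
                                   target = triples$mrna,
                                   targetClass = "mRNA",
                                   stringsAsFactors = FALSE))
    edges <- rbind(circEdges, mrnaEdges)
    edges <- edges[order(edges$targetClass, edges$mirna, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    new("TripartiteNetwork",
        circNodes = sort(unique(triples$circ)),
        mirnaNodes = sort(unique(triples$mirna)),
        mrnaNodes = sort(unique(triples$mrna)),
        edges = edges)
}
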
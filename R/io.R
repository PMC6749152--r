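#' Write / read an expression dataset as TSV
#'
#' The expression TSV has the feature id in the first column (header
#' \code{feature}) and one column per sample; the companion annotation TSV
#' has columns \code{sample}, \code{condition}, \code{dataset}. Numeric
#' values are written at full round-trip precision, so
#' \code{readExpressionDataset()} restores an object equal to the one
#' written.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param exprsPath,annotPath output / input file paths.
#' @return \code{writeExpressionDataset}: invisibly, \code{exprsPath};
#'   \code{readExpressionDataset}: an \linkS4class{ExpressionDataset}.
#' @export
writeExpressionDataset <- function(dataset, exprsPath, annotPath) {
    stopifnot(is(dataset, "ExpressionDataset"))
    v <- exprsValues(dataset)
    df <- data.frame(feature = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, exprsPath, sep = "\t")
    ann <- data.frame(sample = colnames(v),
                      condition = sampleConditions(dataset),
                      dataset = datasetTag(dataset),
                      stringsAsFactors = FALSE)
    data.table::fwrite(ann, annotPath, sep = "\t")
    invisible(exprsPath)
}

#' @rdname writeExpressionDataset
#' @export
readExpressionDataset <- function(exprsPath, annotPath) {
    for (p in c(exprsPath, annotPath))
        if (!file.exists(p)) stop("file not found: ", p)
    df <- data.table::fread(exprsPath, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (colnames(df)[1] != "feature")
        stop("expression TSV must have 'feature' as its first column")
    v <- as.matrix(df[, -1, drop = FALSE])
    rownames(v) <- df$feature
    ann <- data.table::fread(annotPath, sep = "\t", header = TRUE,
                             data.table = FALSE)
    need <- c("sample", "condition", "dataset")
    if (!all(need %in% colnames(ann)))
        stop("annotation TSV must have columns: ",
             paste(need, collapse = ", "))
    ann <- ann[match(colnames(v), ann$sample), , drop = FALSE]
    if (any(is.na(ann$sample)))
        stop("annotation is missing some expression samples")
    ExpressionDataset(v, ann$condition, datasetTag = ann$dataset[1])
}

#' Write a miRNA-target interaction table as TSV
#'
#' Inverse of [readInteractions()]; columns \code{mirna}, \code{target},
#' \code{target_class}.
#'
#' @param interactions a \linkS4class{MirTargetSet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeInteractions <- function(interactions, path) {
    stopifnot(is(interactions, "MirTargetSet"))
    ed <- interactionEdges(interactions)
    out <- data.frame(mirna = ed$mirna, target = ed$target,
                      target_class = ed$targetClass,
                      stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}

#' Write / read a crosstalk triples table as TSV
#'
#' Columns \code{circ}, \code{mirna}, \code{mrna}, \code{sharedCount}.
#'
#' @param triples data.frame of crosstalk triples.
#' @param path file path.
#' @return \code{writeTriples}: invisibly, \code{path}; \code{readTriples}:
#'   the data.frame.
#' @export
writeTriples <- function(triples, path) {
    data.table::fwrite(triples, path, sep = "\t")
    invisible(path)
}

#' @rdname writeTriples
#' @export
readTriples <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE,
                            colClasses = list(character = c("circ", "mirna",
                                                            "mrna")))
    need <- c("circ", "mirna", "mrna", "sharedCount")
    if (!all(need %in% colnames(df)))
        stop("triples TSV must have columns: ", paste(need, collapse = ", "))
    df$sharedCount <- as.integer(df$sharedCount)
    df
}

#' Write / read an id list (one id per line)
#'
#' @param ids character vector.
#' @param path file path.
#' @return \code{writeIdList}: invisibly, \code{path}; \code{readIdList}:
#'   character vector (empty file gives \code{character(0)}).
#' @export
writeIdList <- function(ids, path) {
    writeLines(as.character(ids), path)
    invisible(path)
}

#' @rdname writeIdList
#' @export
readIdList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ids <- readLines(path)
    ids[nzchar(ids)]
}

#' Export / import a tripartite network
#'
#' \code{writeNetworkTSV} writes the typed edge list (columns \code{mirna},
#' \code{target}, \code{target_class}); \code{readNetworkTSV} rebuilds the
#' \linkS4class{TripartiteNetwork} from it. \code{writeNetworkGraphML}
#' exports a GraphML file via igraph with a \code{nodeClass} vertex
#' attribute; \code{readNetworkGraphML} restores the network from it.
#'
#' @param network a \linkS4class{TripartiteNetwork}.
#' @param path file path.
#' @return writers return \code{path} invisibly; readers return a
#'   \linkS4class{TripartiteNetwork}.
#' @export
writeNetworkTSV <- function(network, path) {
    stopifnot(is(network, "TripartiteNetwork"))
    ed <- networkEdges(network)
    out <- data.frame(mirna = ed$mirna, target = ed$target,
                      target_class = ed$targetClass,
                      stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
readNetworkTSV <- function(path) {
    x <- readInteractions(path)
    ed <- interactionEdges(x)
    new("TripartiteNetwork",
        circNodes = sort(unique(ed$target[ed$targetClass == "circRNA"])),
        mirnaNodes = sort(unique(ed$mirna)),
        mrnaNodes = sort(unique(ed$target[ed$targetClass == "mRNA"])),
        edges = ed)
}

#' @rdname writeNetworkTSV
#' @export
writeNetworkGraphML <- function(network, path) {
    stopifnot(is(network, "TripartiteNetwork"))
    g <- asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
readNetworkGraphML <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    g <- igraph::read_graph(path, format = "graphml")
    cls <- igraph::V(g)$nodeClass
    nm <- igraph::V(g)$name
    ends <- igraph::as_edgelist(g)
    # order each edge as (mirna, target) using the node classes
    isMir1 <- cls[match(ends[, 1], nm)] == "miRNA"
    mirna <- ifelse(isMir1, ends[, 1], ends[, 2])
    target <- ifelse(isMir1, ends[, 2], ends[, 1])
    targetClass <- cls[match(target, nm)]
    targetClass <- ifelse(targetClass == "circRNA", "circRNA", "mRNA")
    edges <- data.frame(mirna = mirna, target = target,
                        targetClass = targetClass, stringsAsFactors = FALSE)
    edges <- edges[order(edges$targetClass, edges$mirna, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    new("TripartiteNetwork",
        circNodes = sort(nm[cls == "circRNA"]),
        mirnaNodes = sort(nm[cls == "miRNA"]),
        mrnaNodes = sort(nm[cls == "mRNA"]),
        edges = edges)
}

#' Convert a TripartiteNetwork to an igraph object
#'
#' Vertices carry a \code{nodeClass} attribute (\code{"circRNA"},
#' \code{"miRNA"}, \code{"mRNA"}); edges run miRNA -> target.
#'
#' @param network a \linkS4class{TripartiteNetwork}.
#' @return an igraph graph.
#' @export
asIgraph <- function(network) {
    stopifnot(is(network, "TripartiteNetwork"))
    nodes <- data.frame(
        name = c(circNodes(network), mirnaNodes(network),
                 mrnaNodes(network)),
        nodeClass = c(rep("circRNA", length(circNodes(network))),
                      rep("miRNA", length(mirnaNodes(network))),
                      rep("mRNA", length(mrnaNodes(network)))),
        stringsAsFactors = FALSE)
    ed <- networkEdges(network)
    igraph::graph_from_data_frame(ed[, c("mirna", "target")],
                                  directed = FALSE, vertices = nodes)
}

#' Summarize a tripartite network as node/edge counts
#'
#' @param network a \linkS4class{TripartiteNetwork}.
#' @return list of counts by class (suitable for JSON export).
#' @export
networkSummary <- function(network) {
    stopifnot(is(network, "TripartiteNetwork"))
    ed <- networkEdges(network)
    list(nodes = length(circNodes(network)) + length(mirnaNodes(network)) +
             length(mrnaNodes(network)),
         circRNAs = length(circNodes(network)),
         miRNAs = length(mirnaNodes(network)),
         mRNAs = length(mrnaNodes(network)),
         edges = nrow(ed),
         mirnaCircEdges = sum(ed$targetClass == "circRNA"),
         mirnaMrnaEdges = sum(ed$targetClass == "mRNA"))
}
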
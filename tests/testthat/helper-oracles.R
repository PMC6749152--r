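# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (nested loops, exhaustive enumeration) so they cannot
# share a defect with the implementation they check.

# All-pairs set-intersection count of shared miRNA regulators.
bfSharedCounts <- function(edges) {
    circTargets <- unique(edges$target[edges$targetClass == "circRNA"])
    mrnaTargets <- unique(edges$target[edges$targetClass == "mRNA"])
    res <- list()
    for (cc in circTargets) {
        mirsC <- edges$mirna[edges$target == cc]
        for (gg in mrnaTargets) {
            mirsG <- edges$mirna[edges$target == gg]
            k <- length(intersect(mirsC, mirsG))
            if (k > 0)
                res[[length(res) + 1L]] <-
                    data.frame(circ = cc, mrna = gg, sharedCount = k,
                               stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(circ = character(), mrna = character(),
                          sharedCount = integer()))
    out <- do.call(rbind, res)
    out <- out[order(out$circ, out$mrna), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Triple-loop crosstalk enumeration over all (circ, miRNA, mRNA) combos.
bfTriples <- function(edges, minShared) {
    circTargets <- unique(edges$target[edges$targetClass == "circRNA"])
    mrnaTargets <- unique(edges$target[edges$targetClass == "mRNA"])
    mirs <- unique(edges$mirna)
    res <- list()
    for (cc in circTargets) {
        mirsC <- edges$mirna[edges$target == cc]
        for (gg in mrnaTargets) {
            mirsG <- edges$mirna[edges$target == gg]
            shared <- intersect(mirsC, mirsG)
            if (length(shared) >= minShared)
                for (mm in mirs)
                    if (mm %in% shared)
                        res[[length(res) + 1L]] <-
                            data.frame(circ = cc, mirna = mm, mrna = gg,
                                       sharedCount = length(shared),
                                       stringsAsFactors = FALSE)
        }
    }
    if (!length(res)) return(circeNet:::emptyTriples())
    out <- do.call(rbind, res)
    out <- out[order(out$circ, out$mirna, out$mrna), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Row-by-row membership filters.
bfDiseaseFilter <- function(triples, cdeg, demir) {
    keep <- logical(nrow(triples))
    for (i in seq_len(nrow(triples)))
        keep[i] <- triples$mrna[i] %in% cdeg || triples$mirna[i] %in% demir
    out <- triples[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

bfRiskFilter <- function(triples, knownGenes, knownMirs) {
    bfDiseaseFilter(triples, knownGenes, knownMirs)
}

# Exhaustive hypergeometric upper tail: enumerate all size-n draws from a
# universe with K marked elements, count draws with >= k marks.
bfHypergeomUpper <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
    mean(hits)
}

# Random typed interaction instance for oracle comparisons.
randomInteractions <- function(seed, nCirc = 20, nMir = 40, nMrna = 30,
                               p = 0.15) {
    set.seed(seed)
    circs <- sprintf("c%02d", seq_len(nCirc))
    mirs <- sprintf("m%02d", seq_len(nMir))
    genes <- sprintf("g%02d", seq_len(nMrna))
    grid <- expand.grid(mirna = mirs, target = c(circs, genes),
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < p
    ed <- grid[keep, , drop = FALSE]
    ed$targetClass <- ifelse(ed$target %in% circs, "circRNA", "mRNA")
    MirTargetSet(ed$mirna, ed$target, ed$targetClass)
}

# Small engineered expression dataset with exact group means/variances.
exactDataset <- function() {
    # per feature: case mean 2, control mean 1, pooled variance 1 (a = 1)
    vals <- rbind(g1 = c(1, 2, 3, 0, 1, 2),
                  g2 = c(4, 5, 6, 3, 4, 5),
                  g3 = c(2, 3, 4, 2, 3, 4))  # zero effect
    colnames(vals) <- paste0("s", 1:6)
    ExpressionDataset(vals, rep(c("case", "control"), each = 3), "exact")
}

randomDataset <- function(seed, nFeatures = 60, n1 = 5, n2 = 4,
                          tag = "rand") {
    set.seed(seed)
    vals <- matrix(rnorm(nFeatures * (n1 + n2), mean = 7), nFeatures)
    rownames(vals) <- sprintf("f%03d", seq_len(nFeatures))
    colnames(vals) <- sprintf("s%02d", seq_len(n1 + n2))
    ExpressionDataset(vals, c(rep("case", n1), rep("control", n2)), tag)
}

# Sorted-row equality for triple tables.
expectSameTriples <- function(a, b, checkShared = TRUE) {
    cols <- c("circ", "mirna", "mrna", if (checkShared) "sharedCount")
    a <- a[do.call(order, a[cols]), cols, drop = FALSE]
    b <- b[do.call(order, b[cols]), cols, drop = FALSE]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
}
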
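writeEdgeFile <- function(df, path = tempfile(fileext = ".tsv")) {
    names(df) <- c("mirna", "target", "target_class")
    data.table::fwrite(df, path, sep = "\t")
    path
}

test_that("interaction reading deduplicates and validates classes", {
    f <- writeEdgeFile(data.frame(m = rep("m1", 3), t = rep("c1", 3),
                                  k = rep("circRNA", 3)))
    expect_message(x <- readInteractions(f), "2 duplicate")
    expect_equal(nrow(interactionEdges(x)), 1L)

    f2 <- writeEdgeFile(data.frame(m = c("m1", "m2"), t = c("x1", "x1"),
                                   k = c("circRNA", "mRNA")))
    expect_error(readInteractions(f2), "both classes")

    f3 <- writeEdgeFile(data.frame(m = "m1", t = "x1", k = "lncRNA"))
    expect_error(readInteractions(f3), "lncRNA")

    f4 <- writeEdgeFile(data.frame(m = character(), t = character(),
                                   k = character()))
    expect_warning(x4 <- readInteractions(f4), "empty")
    expect_equal(nrow(interactionEdges(x4)), 0L)
})

test_that("shared-miRNA counts equal direct set intersections", {
    x <- MirTargetSet(
        mirna = c(paste0("m", 1:6), paste0("m", 2:7)),
        target = c(rep("c1", 6), rep("g1", 6)),
        targetClass = c(rep("circRNA", 6), rep("mRNA", 6)))
    cnt <- sharedMirnaCounts(x)
    expect_equal(cnt$sharedCount[cnt$circ == "c1" & cnt$mrna == "g1"], 5L)

    # disjoint regulator sets produce no pair
    y <- MirTargetSet(c("m1", "m2"), c("c1", "g1"), c("circRNA", "mRNA"))
    expect_equal(nrow(sharedMirnaCounts(y)), 0L)
})

test_that("shared-miRNA counts match the brute-force oracle", {
    for (s in c(2, 9, 31)) {
        x <- randomInteractions(s, nCirc = 20, nMir = 40, nMrna = 30)
        got <- sharedMirnaCounts(x)
        want <- bfSharedCounts(interactionEdges(x))
        got$sharedCount <- as.integer(got$sharedCount)
        want$sharedCount <- as.integer(want$sharedCount)
        expect_equal(got, want)
    }
})

test_that("shared-miRNA counts are invariant to input row order", {
    x <- randomInteractions(4)
    ed <- interactionEdges(x)
    set.seed(1)
    shuf <- ed[sample(nrow(ed)), , drop = FALSE]
    y <- MirTargetSet(shuf$mirna, shuf$target, shuf$targetClass)
    expect_equal(sharedMirnaCounts(x), sharedMirnaCounts(y))
})

test_that("network construction reproduces forced small instances", {
    # one planted pair sharing exactly five miRNAs
    x <- MirTargetSet(mirna = rep(paste0("m", 1:5), 2),
                      target = rep(c("c1", "g1"), each = 5),
                      targetClass = rep(c("circRNA", "mRNA"), each = 5))
    res <- buildCirceNet(x, minShared = 5)
    expect_equal(nrow(res$triples), 5L)
    expect_equal(nrow(networkEdges(res$network)), 10L)
    expect_equal(length(circNodes(res$network)) +
                 length(mirnaNodes(res$network)) +
                 length(mrnaNodes(res$network)), 7L)

    # a pair sharing only four miRNAs contributes nothing at threshold five
    x4 <- MirTargetSet(mirna = rep(paste0("m", 1:4), 2),
                       target = rep(c("c1", "g1"), each = 4),
                       targetClass = rep(c("circRNA", "mRNA"), each = 4))
    res4 <- buildCirceNet(x4, minShared = 5)
    expect_equal(nrow(res4$triples), 0L)
    expect_equal(nrow(networkEdges(res4$network)), 0L)

    expect_error(buildCirceNet(x, minShared = 0), ">= 1")
})

test_that("triple enumeration matches brute force on random instances", {
    for (s in c(1, 7, 19)) {
        x <- randomInteractions(s, nCirc = 10, nMir = 25, nMrna = 15,
                                p = 0.25)
        res <- buildCirceNet(x, minShared = 3)
        want <- bfTriples(interactionEdges(x), minShared = 3)
        expectSameTriples(res$triples, want)
    }
})

test_that("every retained edge occurs in at least one triple", {
    x <- randomInteractions(12, p = 0.2)
    res <- buildCirceNet(x, minShared = 3)
    ed <- networkEdges(res$network)
    circKeys <- unique(paste(res$triples$mirna, res$triples$circ))
    mrnaKeys <- unique(paste(res$triples$mirna, res$triples$mrna))
    edKeys <- paste(ed$mirna, ed$target)
    expect_setequal(edKeys, c(circKeys, mrnaKeys))
    methods::validObject(res$network)
})

test_that("raising the shared-miRNA threshold never adds structure", {
    x <- randomInteractions(5, p = 0.25)
    prev <- buildCirceNet(x, minShared = 1)
    for (th in 2:6) {
        cur <- buildCirceNet(x, minShared = th)
        expect_lte(nrow(cur$triples), nrow(prev$triples))
        expect_lte(nrow(networkEdges(cur$network)),
                   nrow(networkEdges(prev$network)))
        # triples at the higher threshold are a subset
        keyCur <- with(cur$triples, paste(circ, mirna, mrna))
        keyPrev <- with(prev$triples, paste(circ, mirna, mrna))
        expect_true(all(keyCur %in% keyPrev))
        prev <- cur
    }
})
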
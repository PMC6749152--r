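smallTriples <- function() {
    data.frame(circ = c("c1", "c1", "c2", "c3"),
               mirna = c("m1", "m2", "m1", "m3"),
               mrna = c("g1", "g2", "g3", "g4"),
               sharedCount = 5L, stringsAsFactors = FALSE)
}

test_that("disease extraction applies the disjunctive DE rule", {
    tr <- smallTriples()
    ann <- DiseaseAnnotation(cdegSet = "g1", demirSet = "m3")
    res <- extractDiseaseNetwork(tr, ann)
    # g1 retained via CDEG, g4 via DEmiR m3, others dropped
    expect_setequal(res$triples$mrna, c("g1", "g4"))
    # empty annotation: warning, empty network
    expect_warning(empty <- extractDiseaseNetwork(tr, DiseaseAnnotation()),
                   "empty")
    expect_equal(nrow(empty$triples), 0L)
    expect_equal(length(circNodes(empty$network)), 0L)
})

test_that("risk flagging applies the disjunctive known-id rule", {
    tr <- smallTriples()
    expect_equal(nrow(flagRiskTriples(tr, DiseaseAnnotation())), 0L)
    ann <- DiseaseAnnotation(knownGenes = "g3", knownMirs = "m2")
    risk <- flagRiskTriples(tr, ann)
    expect_setequal(paste(risk$circ, risk$mrna), c("c1 g2", "c2 g3"))
})

test_that("disease and risk filters match brute force on random instances", {
    for (s in c(3, 14)) {
        x <- randomInteractions(s, p = 0.25)
        tr <- buildCirceNet(x, minShared = 3)$triples
        set.seed(s)
        ann <- DiseaseAnnotation(
            cdegSet = sample(unique(tr$mrna), min(5, length(unique(tr$mrna)))),
            demirSet = sample(unique(tr$mirna), 2),
            knownGenes = sample(unique(tr$mrna), 3),
            knownMirs = sample(unique(tr$mirna), 1))
        dis <- extractDiseaseNetwork(tr, ann)
        expectSameTriples(dis$triples,
                          bfDiseaseFilter(tr, ann@cdegSet, ann@demirSet))
        risk <- flagRiskTriples(dis$triples, ann)
        expectSameTriples(risk, bfRiskFilter(dis$triples, ann@knownGenes,
                                             ann@knownMirs))
        # nesting: risk subset of disease subset of all
        expect_true(all(paste(risk$circ, risk$mirna, risk$mrna) %in%
                        paste(dis$triples$circ, dis$triples$mirna,
                              dis$triples$mrna)))
        expect_true(all(paste(dis$triples$circ, dis$triples$mirna,
                              dis$triples$mrna) %in%
                        paste(tr$circ, tr$mirna, tr$mrna)))
        # idempotence
        again <- extractDiseaseNetwork(tr, ann)
        expect_equal(dis$triples, again$triples)
        expect_equal(networkEdges(dis$network), networkEdges(again$network))
    }
})

test_that("circRNA ranking orders by count with lexicographic ties", {
    tr <- data.frame(circ = c(rep("c9", 3), "c2"),
                     mirna = paste0("m", 1:4),
                     mrna = paste0("g", 1:4), sharedCount = 5L)
    r <- rankCircRNAs(tr)
    expect_equal(r$circ, c("c9", "c2"))
    expect_equal(r$rank, 1:2)

    tied <- data.frame(circ = c("cB", "cB", "cA", "cA"),
                       mirna = paste0("m", 1:4),
                       mrna = paste0("g", 1:4), sharedCount = 5L)
    rt <- rankCircRNAs(tied)
    expect_equal(rt$circ, c("cA", "cB"))
    expect_equal(rt$riskTripleCount, c(2L, 2L))

    expect_equal(nrow(rankCircRNAs(tr[0, ])), 0L)
})

test_that("coverage column reports risk over total triples per circRNA", {
    all <- smallTriples()
    risk <- all[all$circ == "c1", ][1, , drop = FALSE]
    r <- rankCircRNAs(risk, all)
    expect_equal(r$totalCount[r$circ == "c1"], 2L)
    expect_equal(r$coverage[r$circ == "c1"], 0.5)
})

test_that("circRNA neighborhoods are induced by its triples", {
    tr <- smallTriples()
    hood <- circNeighborhood("c2", tr)
    expect_equal(nrow(hood$triples), 1L)
    expect_equal(nrow(networkEdges(hood$network)), 2L)
    expect_equal(sort(hood$summary$id), sort(c("c2", "m1", "g3")))

    err <- tryCatch(circNeighborhood("c9", tr), error = conditionMessage)
    expect_match(err, "nearest ids")
    expect_match(err, "c1|c2|c3")

    ann <- DiseaseAnnotation(cdegSet = "g3", knownMirs = "m1")
    hood2 <- circNeighborhood("c2", tr, ann)
    expect_true(hood2$summary$isDE[hood2$summary$id == "g3"])
    expect_true(hood2$summary$isKnown[hood2$summary$id == "m1"])
})

test_that("the planted risk circRNA tops the ranking and permutation breaks it", {
    study <- simulateStudy(simulationConfig(seed = 42))
    built <- buildCirceNet(study$interactions, 5)
    truth <- study$truth
    ann <- DiseaseAnnotation(cdegSet = truth@deFeatures,
                             demirSet = truth@deMirs,
                             knownGenes = truth@knownGenes,
                             knownMirs = truth@knownMirs)
    dis <- extractDiseaseNetwork(built$triples, ann)
    risk <- flagRiskTriples(dis$triples, ann)
    rk <- rankCircRNAs(risk)
    expect_equal(rk$circ[1], truth@plantedRiskCirc)

    # permuting the known labels destroys the rank-1 position almost always
    geneUniverse <- sprintf("gene_%04d", seq_len(2000))
    mirUniverse <- c(sprintf("mir_%03d", seq_len(80)),
                     sprintf("mir_curated_%03d", 1:200))
    set.seed(99)
    kept <- vapply(1:200, function(i) {
        pAnn <- DiseaseAnnotation(
            cdegSet = truth@deFeatures, demirSet = truth@deMirs,
            knownGenes = sample(geneUniverse, length(truth@knownGenes)),
            knownMirs = sample(mirUniverse, length(truth@knownMirs)))
        pr <- rankCircRNAs(flagRiskTriples(dis$triples, pAnn))
        nrow(pr) > 0 && pr$circ[1] == truth@plantedRiskCirc
    }, logical(1))
    expect_lt(mean(kept), 0.1)
})
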
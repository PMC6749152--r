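test_that("generators are pure functions of the seed", {
    cfg <- simulationConfig(seed = 3, nFeatures = 300, nDatasets = 2L)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(exprsValues(s1$datasets[[1]]),
                     exprsValues(s2$datasets[[1]]))
    expect_identical(interactionEdges(s1$interactions),
                     interactionEdges(s2$interactions))
    expect_identical(s1$truth@knownGenes, s2$truth@knownGenes)
    expect_identical(s1$truth@knownMirs, s2$truth@knownMirs)
    f1 <- tempfile(); f2 <- tempfile()
    writeGMT(s1$collection, f1); writeGMT(s2$collection, f2)
    expect_identical(readLines(f1), readLines(f2))
    # generators do not disturb the caller's RNG stream
    set.seed(1); before <- rnorm(1)
    set.seed(1); invisible(simulateStudy(cfg)); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("invalid study conditions are rejected with messages", {
    expect_error(simulationConfig(fracDE = 2), "\\[0, 1\\]")
    expect_error(simulationConfig(s0Sq = -1), "positive")
    expect_error(simulationConfig(effectMean = NaN), "finite")
    expect_error(simulationConfig(nMir = 4, sharedPool = 8), "sharedPool")
    expect_error(simulationConfig(nFeatures = 100, nMrna = 300), "nMrna")
})

test_that("a zero DE fraction produces a null study", {
    cfg <- simulationConfig(seed = 2, nFeatures = 500, nDatasets = 2L,
                            fracDE = 0)
    sim <- simulateExpression(cfg)
    expect_length(sim$truth@deFeatures, 0L)
    stats <- lapply(sim$datasets, moderatedT)
    hits <- selectDE(combineDatasets(stats), 0.05)
    expect_lte(nrow(hits), 5L)  # essentially no discoveries under the null
})

test_that("simulated variances follow the scaled inverse chi-square prior", {
    # E[sigma^2] = s0Sq * d0 / (d0 - 2); check via unbiased pooled variances
    means <- vapply(1:50, function(s) {
        cfg <- simulationConfig(seed = s, nFeatures = 5000, nDatasets = 1L,
                                nCase = 3L, nControl = 3L, fracDE = 0)
        mean(statsTable(moderatedT(simulateExpression(cfg)$datasets[[1]],
                                   d0 = 0))$sSq)
    }, numeric(1))
    expect_lt(abs(mean(means) - 0.05 * 4 / 2) / (0.05 * 4 / 2), 0.10)
})

test_that("the generated prior is recovered by the estimator", {
    cfg <- simulationConfig(seed = 8, nFeatures = 5000, nDatasets = 1L,
                            nCase = 3L, nControl = 3L, d0 = 4, s0Sq = 0.05)
    ms <- moderatedT(simulateExpression(cfg)$datasets[[1]])
    expect_lt(abs(priorDf(ms) - 4) / 4, 0.2)
    expect_lt(abs(priorVar(ms) - 0.05) / 0.05, 0.1)
})

test_that("planted interactions produce exactly the forced edge counts", {
    cfg <- simulationConfig(seed = 1, nPlantedPairs = 1L, riskPairs = 1L,
                            sharedPool = 5L, backgroundEdgeProb = 0)
    res <- simulateInteractions(cfg)
    expect_equal(nrow(interactionEdges(res$interactions)), 10L)
    built <- buildCirceNet(res$interactions, minShared = 5)
    expectSameTriples(built$triples, res$truth@plantedTriples)
})

test_that("planted triples survive enumeration under background noise", {
    res <- simulateInteractions(simulationConfig(seed = 1))
    built <- buildCirceNet(res$interactions, minShared = 5)
    keyBuilt <- with(built$triples, paste(circ, mirna, mrna))
    keyPlanted <- with(res$truth@plantedTriples, paste(circ, mirna, mrna))
    expect_true(all(keyPlanted %in% keyBuilt))
})

test_that("known lists concentrate on the planted risk circRNA", {
    cfg <- simulationConfig(seed = 6)
    ints <- simulateInteractions(cfg)
    truth <- simulateKnownLists(cfg, ints$truth)
    expect_length(truth@knownGenes, 27L)
    expect_length(truth@knownMirs, 45L)
    pt <- truth@plantedTriples
    isRisk <- pt$mrna %in% truth@knownGenes | pt$mirna %in% truth@knownMirs
    cnt <- table(pt$circ[isRisk])
    expect_equal(names(which.max(cnt)), truth@plantedRiskCirc)
    # strict dominance
    others <- cnt[names(cnt) != truth@plantedRiskCirc]
    if (length(others)) expect_gt(max(cnt), max(others))
    # empty lists are allowed and yield zero risk triples downstream
    cfg0 <- simulationConfig(seed = 6, nKnownGenes = 0L, nKnownMirs = 0L)
    truth0 <- simulateKnownLists(cfg0, simulateInteractions(cfg0)$truth)
    ann <- DiseaseAnnotation(knownGenes = truth0@knownGenes,
                             knownMirs = truth0@knownMirs)
    expect_equal(nrow(flagRiskTriples(truth0@plantedTriples, ann)), 0L)
    # determinism
    truth2 <- simulateKnownLists(cfg, simulateInteractions(cfg)$truth)
    expect_identical(truth@knownGenes, truth2@knownGenes)
    expect_identical(truth@knownMirs, truth2@knownMirs)
})

test_that("gene-set generation requires planted structure and is seeded", {
    cfg <- simulationConfig(seed = 4)
    expect_error(simulateGeneSets(cfg, circeNet:::emptyTruth()),
                 "plantedTriples")
    ints <- simulateInteractions(cfg)
    g1 <- simulateGeneSets(cfg, ints$truth)
    g2 <- simulateGeneSets(cfg, ints$truth)
    expect_identical(geneSets(g1$collection), geneSets(g2$collection))
    expect_identical(g1$truth@enrichedTerm, "planted_set")
    expect_true(all(unique(ints$truth@plantedTriples$mrna) %in%
                    geneSets(g1$collection)$planted_set))
})
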
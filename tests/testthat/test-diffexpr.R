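test_that("moderated t with d0 = 0 equals the ordinary pooled t-test", {
    ed <- exactDataset()
    ms <- moderatedT(ed, d0 = 0)
    tab <- statsTable(ms)
    expect_equal(tab$tMod[tab$feature == "g1"], 1 / sqrt(2 / 3),
                 tolerance = 1e-12)
    expect_equal(tab$tMod[tab$feature == "g3"], 0)
    expect_equal(tab$pTwo[tab$feature == "g3"], 1)

    ed2 <- randomDataset(11)
    tab2 <- statsTable(moderatedT(ed2, d0 = 0))
    v <- exprsValues(ed2); cond <- sampleConditions(ed2)
    for (i in seq_len(nrow(v))) {
        tt <- t.test(v[i, cond == "case"], v[i, cond == "control"],
                     var.equal = TRUE)
        expect_equal(tab2$tMod[i], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(tab2$pTwo[i], tt$p.value, tolerance = 1e-10)
    }
})

test_that("moderated t with d0 = Inf fixes the posterior variance at s0Sq", {
    ed <- randomDataset(3)
    ms <- moderatedT(ed, d0 = Inf, s0Sq = 0.7)
    tab <- statsTable(ms)
    expect_true(all(tab$sTildeSq == 0.7))
    z <- tab$effect / sqrt(0.7 * (1 / 5 + 1 / 4))
    expect_equal(tab$tMod, z, tolerance = 1e-12)
    expect_equal(tab$pTwo, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("posterior variance and |t| interpolate between data and prior", {
    ed <- randomDataset(7, nFeatures = 120)
    ms <- moderatedT(ed)
    tab <- statsTable(ms)
    expect_true(is.finite(priorDf(ms)) || priorDf(ms) == Inf)
    lo <- pmin(tab$sSq, priorVar(ms)); hi <- pmax(tab$sSq, priorVar(ms))
    expect_true(all(tab$sTildeSq >= lo - 1e-12 & tab$sTildeSq <= hi + 1e-12))
    tOrd <- statsTable(moderatedT(ed, d0 = 0))$tMod
    tPrior <- tab$effect / sqrt(priorVar(ms) * (1 / 5 + 1 / 4))
    loT <- pmin(abs(tOrd), abs(tPrior)); hiT <- pmax(abs(tOrd), abs(tPrior))
    expect_true(all(abs(tab$tMod) >= loT - 1e-9 &
                    abs(tab$tMod) <= hiT + 1e-9))
})

test_that("moderated t agrees with the limma empirical-Bayes route", {
    skip_if_not_installed("limma")
    # variances drawn from a finite-d0 prior so the shrinkage is non-trivial
    cfg <- simulationConfig(seed = 21, nFeatures = 500, nDatasets = 1L,
                            nCase = 6L, nControl = 6L, d0 = 4, s0Sq = 0.05)
    ed <- simulateExpression(cfg)$datasets[[1]]
    ms <- moderatedT(ed)
    expect_true(is.finite(priorDf(ms)))
    design <- cbind(1, sampleConditions(ed) == "case")
    fit <- limma::eBayes(limma::lmFit(exprsValues(ed), design))
    expect_equal(priorDf(ms), fit$df.prior, tolerance = 1e-8)
    expect_equal(priorVar(ms), fit$s2.prior, tolerance = 1e-8)
    expect_equal(statsTable(ms)$tMod, unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(statsTable(ms)$pTwo, unname(fit$p.value[, 2]),
                 tolerance = 1e-8)
})

test_that("a zero-variance feature is rescued by shrinkage", {
    set.seed(5)
    vals <- matrix(rnorm(50 * 8), 50)
    vals[1, ] <- c(rep(2, 4), rep(1, 4))  # constant within both groups
    rownames(vals) <- sprintf("f%02d", 1:50)
    ed <- ExpressionDataset(vals, rep(c("case", "control"), each = 4))
    tab <- statsTable(moderatedT(ed))
    expect_gt(tab$sTildeSq[1], 0)
    expect_true(is.finite(tab$tMod[1]))
    expect_true(tab$pTwo[1] > 0 && tab$pTwo[1] < 1)
})

test_that("prior estimation handles degenerate and outlier inputs", {
    expect_error(estimatePrior(rep(1, 5), 4), "at least 10")
    fit <- estimatePrior(rep(0.5, 100), 4)
    expect_identical(fit$d0, Inf)
    expect_equal(fit$s0Sq, exp(log(0.5) - digamma(2) + log(2)),
                 tolerance = 1e-10)
    # an extreme outlier pushes the spread past the trigamma bound
    s2 <- c(rep(0.5, 99), 1e6)
    fit2 <- estimatePrior(s2, 20)
    expect_true(is.finite(fit2$d0) && fit2$d0 > 0)
})

test_that("prior hyperparameters are recovered from their own model", {
    d0s <- s0s <- numeric(5)
    for (i in 1:5) {
        set.seed(100 + i)
        sigma2 <- 0.05 * 4 / rchisq(5000, df = 4)
        s2 <- sigma2 * rchisq(5000, df = 4) / 4
        fit <- estimatePrior(s2, 4)
        d0s[i] <- fit$d0; s0s[i] <- fit$s0Sq
    }
    expect_true(all(abs(d0s - 4) / 4 < 0.2))
    expect_true(all(abs(s0s - 0.05) / 0.05 < 0.1))
})

test_that("meta-combination follows signed-z Stouffer arithmetic", {
    mkStats <- function(p, effect, n1 = 5L, n2 = 5L, tag = "d") {
        tab <- data.frame(feature = "f1", effect = effect, sSq = 1,
                          dg = n1 + n2 - 2, sTildeSq = 1, tMod = 1,
                          pTwo = p, stringsAsFactors = FALSE)
        new("ModeratedStats", table = tab, d0 = 0, s0Sq = NA_real_,
            nCase = n1, nControl = n2, datasetTag = tag)
    }
    # single dataset: identity
    one <- combineDatasets(list(mkStats(0.10, 1)))
    expect_equal(resultTable(one)$zMeta, qnorm(0.95), tolerance = 1e-10)
    # two equal datasets, both p = 0.10, positive effects
    two <- combineDatasets(list(mkStats(0.10, 1), mkStats(0.10, 1)))
    expect_equal(resultTable(two)$zMeta, 2.3262, tolerance = 1e-4)
    expect_equal(resultTable(two)$pTwo, 0.0200, tolerance = 1e-3)
    # opposite signs cancel
    opp <- combineDatasets(list(mkStats(0.10, 1), mkStats(0.10, -1)))
    expect_equal(resultTable(opp)$zMeta, 0, tolerance = 1e-12)
    expect_equal(resultTable(opp)$pTwo, 1, tolerance = 1e-12)
})

test_that("features observed in only some datasets combine over those", {
    t1 <- data.frame(feature = c("a", "b"), effect = c(1, 1), sSq = 1,
                     dg = 8, sTildeSq = 1, tMod = 1, pTwo = c(0.1, 0.2))
    t2 <- data.frame(feature = "a", effect = 1, sSq = 1, dg = 8,
                     sTildeSq = 1, tMod = 1, pTwo = 0.1)
    s1 <- new("ModeratedStats", table = t1, d0 = 0, s0Sq = NA_real_,
              nCase = 5L, nControl = 5L, datasetTag = "d1")
    s2 <- new("ModeratedStats", table = t2, d0 = 0, s0Sq = NA_real_,
              nCase = 5L, nControl = 5L, datasetTag = "d2")
    res <- resultTable(combineDatasets(list(s1, s2)))
    expect_equal(res$nDatasetsObserved[res$feature == "a"], 2L)
    expect_equal(res$nDatasetsObserved[res$feature == "b"], 1L)
    expect_equal(res$zMeta[res$feature == "b"], qnorm(0.9),
                 tolerance = 1e-10)
})

test_that("BH adjustment matches hand arithmetic and p.adjust", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    for (s in 1:10) {
        set.seed(s)
        p <- runif(50)^2
        expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
    }
    expect_error(bhAdjust(c(0.1, NA), features = c("x", "y")), "y")
})

test_that("selectDE applies a strict threshold and validates it", {
    tab <- data.frame(feature = c("a", "b", "c"), zMeta = c(3, 2, 0),
                      pTwo = c(0.001, 0.02, 0.9), fdr = c(0.003, 0.03, 0.9),
                      direction = c(1, 1, -1), nDatasetsObserved = 1L)
    res <- new("MetaDEResult", table = tab, nDatasets = 1L)
    expect_error(selectDE(res, 0), "\\(0, 1]")
    expect_error(selectDE(res, 1.2), "\\(0, 1]")
    expect_equal(selectDE(res, 1.0)$feature, c("a", "b", "c"))
    expect_equal(selectDE(res, 0.03)$feature, "a")  # strict: 0.03 excluded
    # discovery count is non-decreasing in the threshold
    counts <- vapply(c(0.001, 0.01, 0.05, 0.5, 1), function(th)
        nrow(selectDE(res, th)), numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("planted differential expression is recovered with high recall", {
    recalls <- vapply(1:20, function(s) {
        cfg <- simulationConfig(seed = s, nFeatures = 400, nDatasets = 1L,
                                nCase = 10L, nControl = 10L,
                                effectMean = 1.5)
        sim <- simulateExpression(cfg)
        res <- singleDatasetDE(sim$datasets[[1]])
        hits <- selectDE(res, 0.05)$feature
        mean(sim$truth@deFeatures %in% hits)
    }, numeric(1))
    expect_gte(mean(recalls), 0.8)
})
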
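#' Construct a SimulationConfig
#'
#' Creates the study-condition object consumed by every generator. The
#' defaults encode the emulated study design: six brain-region gene
#' expression datasets sharing one DE gene membership, one 4-vs-4 miRNA
#' dataset, a variance prior that is scaled inverse chi-square (matching the
#' moderated-t model), a tripartite interaction table with planted
#' circRNA-mRNA pairs each sharing a pool of miRNAs, curated known-disease
#' lists of 27 genes and 45 miRNAs, and a gene-set collection with one
#' planted over-represented term.
#'
#' @param seed single integer; every generator derives its own RNG stream
#'   from it, so outputs are byte-identical across runs and adding one
#'   generator never shifts another's draws.
#' @param nFeatures genes on the expression platform.
#' @param nCase,nControl samples per condition in each gene dataset.
#' @param nDatasets number of gene datasets (brain-region units).
#' @param fracDE fraction of features differentially expressed.
#' @param effectMean,effectSd log2 fold-change magnitude distribution; the
#'   sign is random per feature and held fixed across datasets, the
#'   magnitude is redrawn per dataset.
#' @param d0,s0Sq variance-prior degrees of freedom (may be \code{Inf}) and
#'   scale: true variances are \code{s0Sq * d0 / rchisq(d0)}.
#' @param nCirc,nMir,nMrna network node counts; mRNA nodes are the first
#'   \code{nMrna} platform genes.
#' @param nPlantedPairs circRNA-mRNA pairs planted to share
#'   \code{sharedPool} miRNAs. With the default \code{riskPairs = 1} every
#'   planted circRNA has the same crosstalk topology, so the risk circRNA is
#'   distinguished purely by known-disease coverage (the quantity the
#'   prioritization ranks), not by degree.
#' @param riskPairs planted pairs assigned to the designated risk circRNA.
#' @param sharedPool miRNAs shared by each planted pair.
#' @param backgroundEdgeProb independent probability of each non-planted
#'   (miRNA, target) edge.
#' @param nKnownGenes,nKnownMirs curated known-disease list sizes.
#' @param nCaseMir,nControlMir samples per condition in the miRNA dataset.
#' @param fracDEMir fraction of miRNAs differentially expressed.
#' @param nGeneSets,geneSetMin,geneSetMax random gene-set collection shape.
#' @param baselineMean,baselineSd per-feature baseline log2 intensity
#'   distribution.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nFeatures = 2000L, nCase = 10L,
                             nControl = 10L, nDatasets = 6L, fracDE = 0.1,
                             effectMean = 1.0, effectSd = 0.25,
                             d0 = 4, s0Sq = 0.05,
                             nCirc = 40L, nMir = 80L, nMrna = 300L,
                             nPlantedPairs = 24L, riskPairs = 1L,
                             sharedPool = 8L, backgroundEdgeProb = 0.01,
                             nKnownGenes = 27L, nKnownMirs = 45L,
                             nCaseMir = 4L, nControlMir = 4L,
                             fracDEMir = 0.15,
                             nGeneSets = 30L, geneSetMin = 20L,
                             geneSetMax = 60L,
                             baselineMean = 7, baselineSd = 1) {
    asInt <- function(x, what) {
        if (length(x) != 1L || is.na(x) || !is.finite(as.numeric(x)))
            stop(what, " must be a single finite number")
        as.integer(x)
    }
    cfg <- new("SimulationConfig",
        seed = asInt(seed, "seed"),
        nFeatures = asInt(nFeatures, "nFeatures"),
        nCase = asInt(nCase, "nCase"), nControl = asInt(nControl, "nControl"),
        nDatasets = asInt(nDatasets, "nDatasets"),
        fracDE = as.numeric(fracDE),
        effectMean = as.numeric(effectMean), effectSd = as.numeric(effectSd),
        d0 = as.numeric(d0), s0Sq = as.numeric(s0Sq),
        nCirc = asInt(nCirc, "nCirc"), nMir = asInt(nMir, "nMir"),
        nMrna = asInt(nMrna, "nMrna"),
        nPlantedPairs = asInt(nPlantedPairs, "nPlantedPairs"),
        riskPairs = asInt(riskPairs, "riskPairs"),
        sharedPool = asInt(sharedPool, "sharedPool"),
        backgroundEdgeProb = as.numeric(backgroundEdgeProb),
        nKnownGenes = asInt(nKnownGenes, "nKnownGenes"),
        nKnownMirs = asInt(nKnownMirs, "nKnownMirs"),
        nCaseMir = asInt(nCaseMir, "nCaseMir"),
        nControlMir = asInt(nControlMir, "nControlMir"),
        fracDEMir = as.numeric(fracDEMir),
        nGeneSets = asInt(nGeneSets, "nGeneSets"),
        geneSetMin = asInt(geneSetMin, "geneSetMin"),
        geneSetMax = asInt(geneSetMax, "geneSetMax"),
        baselineMean = as.numeric(baselineMean),
        baselineSd = as.numeric(baselineSd))
    methods::validObject(cfg)
    cfg
}

geneIds <- function(config) sprintf("gene_%04d", seq_len(config@nFeatures))
circIds <- function(config) sprintf("circ_%03d", seq_len(config@nCirc))
mirIds <- function(config) sprintf("mir_%03d", seq_len(config@nMir))
mrnaNodeIds <- function(config) sprintf("gene_%04d", seq_len(config@nMrna))
curatedMirUniverse <- function() sprintf("mir_curated_%03d", 1:200)

emptyTruth <- function() {
    new("GroundTruth", deFeatures = character(), deMirs = character(),
        deSigns = numeric(), plantedTriples = emptyTriples(),
        plantedRiskCirc = NA_character_, knownGenes = character(),
        knownMirs = character(), enrichedTerm = NA_character_)
}

#' Simulate a miRNA-target interaction table with planted ceRNA structure
#'
#' Plants \code{nPlantedPairs} circRNA-mRNA pairs, each of whose members
#' targets a common pool of \code{sharedPool} miRNAs (so each pair
#' qualifies at any crosstalk threshold up to the pool size and contributes
#' one triple per pool miRNA). \code{riskPairs} of the pairs are assigned to
#' one randomly chosen risk circRNA; the remaining pairs go to distinct
#' other circRNAs. Background (miRNA, target) edges are added independently
#' with \code{backgroundEdgeProb}; duplicates are collapsed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{interactions} (a \linkS4class{MirTargetSet}) and
#'   \code{truth} (a \linkS4class{GroundTruth} carrying the planted triples
#'   and risk circRNA).
#' @export
simulateInteractions <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    methods::validObject(config)
    if (config@nMir < config@sharedPool)
        stop("nMir must be >= sharedPool")
    circs <- circIds(config); mirs <- mirIds(config)
    mrnas <- mrnaNodeIds(config)
    withSeed(componentSeed(config@seed, "interactions"), {
        riskCirc <- sample(circs, 1L)
        nOther <- config@nPlantedPairs - config@riskPairs
        otherCircs <- if (nOther > 0L)
            sample(setdiff(circs, riskCirc), nOther) else character()
        pairCircs <- c(rep(riskCirc, config@riskPairs), otherCircs)
        pairMrnas <- sample(mrnas, config@nPlantedPairs)
        pools <- lapply(seq_len(config@nPlantedPairs),
                        function(i) sample(mirs, config@sharedPool))

        planted <- do.call(rbind, lapply(seq_len(config@nPlantedPairs),
            function(i) {
                data.frame(mirna = pools[[i]],
                           target = rep(c(pairCircs[i], pairMrnas[i]),
                                        each = config@sharedPool),
                           targetClass = rep(c("circRNA", "mRNA"),
                                             each = config@sharedPool),
                           stringsAsFactors = FALSE)
            }))

        targets <- c(circs, mrnas)
        classes <- c(rep("circRNA", length(circs)),
                     rep("mRNA", length(mrnas)))
        grid <- expand.grid(mirna = mirs, j = seq_along(targets),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        keep <- stats::rbinom(nrow(grid), 1L,
                              config@backgroundEdgeProb) == 1L
        background <- data.frame(mirna = grid$mirna[keep],
                                 target = targets[grid$j[keep]],
                                 targetClass = classes[grid$j[keep]],
                                 stringsAsFactors = FALSE)

        edges <- unique(rbind(planted, background))
        edges <- edges[order(edges$targetClass, edges$mirna, edges$target), ,
                       drop = FALSE]
        rownames(edges) <- NULL

        plantedTriples <- do.call(rbind, lapply(
            seq_len(config@nPlantedPairs), function(i) {
                data.frame(circ = pairCircs[i], mirna = sort(pools[[i]]),
                           mrna = pairMrnas[i],
                           sharedCount = config@sharedPool,
                           stringsAsFactors = FALSE)
            }))
        plantedTriples <- plantedTriples[order(plantedTriples$circ,
                                               plantedTriples$mirna,
                                               plantedTriples$mrna), ,
                                         drop = FALSE]
        rownames(plantedTriples) <- NULL

        truth <- emptyTruth()
        truth@plantedTriples <- plantedTriples
        truth@plantedRiskCirc <- riskCirc
        list(interactions = new("MirTargetSet", edges = edges),
             truth = truth)
    })
}

#' Simulate multi-dataset two-condition gene expression
#'
#' Emulates several brain-region microarray datasets that share one
#' differential-expression membership. Per dataset, each feature's true
#' variance is drawn from the scaled inverse chi-square prior
#' \code{s0Sq * d0 / rchisq(d0)} (constant \code{s0Sq} when \code{d0 = Inf}),
#' matching the moderated-t model so hyperparameter recovery is a meaningful
#' check. Non-DE features have equal group means; DE features shift the case
#' mean by \code{sign * Normal(effectMean, effectSd^2)} with the sign fixed
#' per feature across datasets (consistent DE) and the magnitude redrawn per
#' dataset (between-region heterogeneity).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param forcedDE feature ids forced into the DE set (used to plant the
#'   network's mRNA partners); the DE set is their union with a random draw
#'   up to \code{round(fracDE * nFeatures)} features.
#' @return list with \code{datasets} (list of
#'   \linkS4class{ExpressionDataset}) and \code{truth} (a
#'   \linkS4class{GroundTruth} with \code{deFeatures} and \code{deSigns}).
#' @export
simulateExpression <- function(config, forcedDE = character()) {
    stopifnot(is(config, "SimulationConfig"))
    methods::validObject(config)
    features <- geneIds(config)
    if (!all(forcedDE %in% features))
        stop("forcedDE contains ids outside the feature universe")
    withSeed(componentSeed(config@seed, "expression"), {
        nDE <- round(config@fracDE * config@nFeatures)
        extra <- max(0L, nDE - length(forcedDE))
        pool <- setdiff(features, forcedDE)
        de <- sort(c(forcedDE,
                     if (extra > 0L) sample(pool, min(extra, length(pool)))
                     else character()))
        signs <- stats::setNames(sample(c(-1, 1), length(de), replace = TRUE),
                                 de)
        mu <- stats::rnorm(config@nFeatures, config@baselineMean,
                           config@baselineSd)
        n1 <- config@nCase; n2 <- config@nControl
        nF <- config@nFeatures
        deIdx <- match(de, features)
        datasets <- lapply(seq_len(config@nDatasets), function(d) {
            sigma2 <- if (is.infinite(config@d0)) rep(config@s0Sq, nF)
                      else config@s0Sq * config@d0 /
                           stats::rchisq(nF, df = config@d0)
            delta <- numeric(nF)
            if (length(deIdx))
                delta[deIdx] <- signs *
                    stats::rnorm(length(deIdx), config@effectMean,
                                 config@effectSd)
            means <- cbind(matrix(mu + delta, nF, n1),
                           matrix(mu, nF, n2))
            vals <- means + matrix(stats::rnorm(nF * (n1 + n2)),
                                   nF, n1 + n2) * sqrt(sigma2)
            tag <- sprintf("region_%02d", d)
            colnames(vals) <- c(sprintf("%s_case_%02d", tag, seq_len(n1)),
                                sprintf("%s_ctrl_%02d", tag, seq_len(n2)))
            rownames(vals) <- features
            ExpressionDataset(vals,
                              c(rep("case", n1), rep("control", n2)),
                              datasetTag = tag)
        })
        truth <- emptyTruth()
        truth@deFeatures <- de
        truth@deSigns <- signs
        list(datasets = datasets, truth = truth)
    })
}

#' Simulate a single two-condition miRNA expression dataset
#'
#' Same generative model as [simulateExpression()] but over the miRNA
#' universe, with its own (small) group sizes — the emulated design is a
#' single 4-vs-4 miRNA microarray.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param forcedDEMirs optional miRNA ids forced into the DE set.
#' @return list with \code{dataset}, \code{deMirs}, \code{deSigns}.
#' @export
simulateMirExpression <- function(config, forcedDEMirs = character()) {
    stopifnot(is(config, "SimulationConfig"))
    mirs <- mirIds(config)
    if (!all(forcedDEMirs %in% mirs))
        stop("forcedDEMirs contains ids outside the miRNA universe")
    withSeed(componentSeed(config@seed, "mir_expression"), {
        nDE <- round(config@fracDEMir * config@nMir)
        extra <- max(0L, nDE - length(forcedDEMirs))
        pool <- setdiff(mirs, forcedDEMirs)
        de <- sort(c(forcedDEMirs,
                     if (extra > 0L) sample(pool, min(extra, length(pool)))
                     else character()))
        signs <- stats::setNames(sample(c(-1, 1), length(de), replace = TRUE),
                                 de)
        nM <- config@nMir
        sigma2 <- if (is.infinite(config@d0)) rep(config@s0Sq, nM)
                  else config@s0Sq * config@d0 /
                       stats::rchisq(nM, df = config@d0)
        mu <- stats::rnorm(nM, config@baselineMean, config@baselineSd)
        delta <- numeric(nM)
        deIdx <- match(de, mirs)
        if (length(deIdx))
            delta[deIdx] <- signs * stats::rnorm(length(deIdx),
                                                 config@effectMean,
                                                 config@effectSd)
        n1 <- config@nCaseMir; n2 <- config@nControlMir
        means <- cbind(matrix(mu + delta, nM, n1), matrix(mu, nM, n2))
        vals <- means + matrix(stats::rnorm(nM * (n1 + n2)), nM, n1 + n2) *
            sqrt(sigma2)
        colnames(vals) <- c(sprintf("mir_case_%02d", seq_len(n1)),
                            sprintf("mir_ctrl_%02d", seq_len(n2)))
        rownames(vals) <- mirs
        ds <- ExpressionDataset(vals, c(rep("case", n1), rep("control", n2)),
                                datasetTag = "mirna_dataset")
        list(dataset = ds, deMirs = de, deSigns = signs)
    })
}

#' Simulate curated known-disease gene and miRNA lists
#'
#' Emulates manually curated disease resources. The known-gene list contains
#' the planted risk circRNA's mRNA partners (so that circRNA dominates the
#' risk-crosstalk ranking), filled up to \code{nKnownGenes} with platform
#' genes outside the planted partners. The known-miRNA list contains up to
#' three miRNAs from the risk circRNA's shared pools (emulating a small
#' number of known disease miRNAs that mediate its crosstalk), filled from a
#' curated namespace outside the platform's miRNA universe — real curated
#' miRNA lists are mostly off-platform.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth \linkS4class{GroundTruth} from [simulateInteractions()].
#' @return the updated \linkS4class{GroundTruth} with \code{knownGenes} and
#'   \code{knownMirs} filled.
#' @export
simulateKnownLists <- function(config, truth) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
    pt <- truth@plantedTriples
    if (nrow(pt) == 0L)
        stop("interaction truth must be generated first ",
             "(plantedTriples is empty)")
    withSeed(componentSeed(config@seed, "known_lists"), {
        riskMrnas <- sort(unique(pt$mrna[pt$circ == truth@plantedRiskCirc]))
        riskMirs <- sort(unique(pt$mirna[pt$circ == truth@plantedRiskCirc]))

        knownGenes <- character()
        if (config@nKnownGenes > 0L) {
            core <- riskMrnas[seq_len(min(length(riskMrnas),
                                          config@nKnownGenes))]
            nFill <- config@nKnownGenes - length(core)
            avail <- setdiff(geneIds(config), unique(pt$mrna))
            if (nFill > length(avail))
                stop("nKnownGenes exceeds available gene ids (",
                     length(avail) + length(core), ")")
            knownGenes <- sort(c(core,
                                 if (nFill > 0L) sample(avail, nFill)
                                 else character()))
        }

        knownMirs <- character()
        if (config@nKnownMirs > 0L) {
            nPool <- min(3L, config@nKnownMirs, length(riskMirs))
            core <- if (nPool > 0L) sample(riskMirs, nPool) else character()
            nFill <- config@nKnownMirs - length(core)
            avail <- curatedMirUniverse()
            if (nFill > length(avail))
                stop("nKnownMirs exceeds available curated miRNA ids (",
                     length(avail) + length(core), ")")
            knownMirs <- sort(c(core,
                                if (nFill > 0L) sample(avail, nFill)
                                else character()))
        }

        truth@knownGenes <- knownGenes
        truth@knownMirs <- knownMirs

        if (length(knownGenes) || length(knownMirs)) {
            isRisk <- pt$mrna %in% knownGenes | pt$mirna %in% knownMirs
            cnt <- table(pt$circ[isRisk])
            riskCnt <- if (truth@plantedRiskCirc %in% names(cnt))
                cnt[[truth@plantedRiskCirc]] else 0L
            others <- cnt[names(cnt) != truth@plantedRiskCirc]
            if (length(others) && max(others) >= riskCnt)
                warning("planted risk circRNA does not strictly dominate ",
                        "the planted risk-triple counts")
        }
        truth
    })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Random gene sets over the network mRNA universe plus one planted term
#' that contains every planted triple's mRNA (hence is over-represented in
#' any query derived from the planted crosstalk), padded with random
#' universe genes up to the configured maximum set size.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth \linkS4class{GroundTruth} from [simulateInteractions()].
#' @return list with \code{collection} (a \linkS4class{GeneSetCollection})
#'   and \code{truth} (updated with \code{enrichedTerm}).
#' @export
simulateGeneSets <- function(config, truth) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
    pt <- truth@plantedTriples
    if (nrow(pt) == 0L)
        stop("interaction truth must be generated first ",
             "(plantedTriples is empty)")
    universe <- mrnaNodeIds(config)
    withSeed(componentSeed(config@seed, "genesets"), {
        plantedGenes <- sort(unique(pt$mrna))
        target <- min(config@geneSetMax, length(universe))
        extraN <- max(0L, target - length(plantedGenes))
        extras <- if (extraN > 0L)
            sample(setdiff(universe, plantedGenes), extraN) else character()
        plantedSet <- sort(c(plantedGenes, extras))

        sizes <- sample(seq(config@geneSetMin, config@geneSetMax),
                        config@nGeneSets, replace = TRUE)
        if (any(sizes > length(universe)))
            stop("gene-set size exceeds the universe")
        rand <- lapply(sizes, function(s) sort(sample(universe, s)))
        names(rand) <- sprintf("set_%03d", seq_len(config@nGeneSets))

        sets <- c(rand, list(planted_set = plantedSet))
        desc <- stats::setNames(
            c(sprintf("random background set %d",
                      seq_len(config@nGeneSets)),
              "planted over-represented set"),
            names(sets))
        truth@enrichedTerm <- "planted_set"
        list(collection = GeneSetCollection(sets, desc), truth = truth)
    })
}

#' Simulate a complete synthetic ceRNA study
#'
#' Orchestrates every generator under one seed: interaction table with
#' planted crosstalk, multi-dataset gene expression whose DE set contains
#' the planted mRNA partners, a single miRNA expression dataset, curated
#' known-disease lists concentrated on the planted risk circRNA, and a
#' gene-set collection with one planted enriched term. The returned ground
#' truth labels everything needed for parameter-recovery and recovery-rate
#' checks.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{datasets}, \code{mirDataset},
#'   \code{interactions}, \code{collection}, \code{truth}, \code{config}.
#' @examples
#' study <- simulateStudy(simulationConfig(seed = 7, nDatasets = 2,
#'                                         nFeatures = 300))
#' study$truth
#' @export
simulateStudy <- function(config = simulationConfig()) {
    ints <- simulateInteractions(config)
    truth <- ints$truth
    expr <- simulateExpression(config,
                               forcedDE = unique(truth@plantedTriples$mrna))
    mir <- simulateMirExpression(config)
    truth@deFeatures <- expr$truth@deFeatures
    truth@deSigns <- expr$truth@deSigns
    truth@deMirs <- mir$deMirs
    truth <- simulateKnownLists(config, truth)
    gs <- simulateGeneSets(config, truth)
    truth <- gs$truth
    list(datasets = expr$datasets, mirDataset = mir$dataset,
         interactions = ints$interactions, collection = gs$collection,
         truth = truth, config = config)
}
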
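#' Assemble a pipeline configuration
#'
#' Collects the thresholds, seed, input locations (or synthetic-study
#' parameters) and output directory of one end-to-end run. The object is a
#' plain serializable list: [writePipelineConfig()] /
#' [readPipelineConfig()] round-trip it through JSON to an equal value.
#'
#' Thresholds default to the conventional analysis settings: gene FDR 0.01
#' (cross-dataset), miRNA FDR 0.05, minimum of 5 shared miRNAs per
#' circRNA-mRNA pair, ORA FDR 0.05.
#'
#' @param outDir run directory (created if missing).
#' @param seed integer seed for the synthetic study.
#' @param geneFdr,mirFdr,minShared,oraFdr analysis thresholds.
#' @param universePolicy \code{"network"} (ORA background = mRNA nodes of
#'   the disease network) or \code{"file"} (read from
#'   \code{universeFile}).
#' @param universeFile id-list file used when
#'   \code{universePolicy == "file"}.
#' @param simulate when TRUE (default) the run starts by generating a
#'   synthetic study from \code{simArgs}; when FALSE the \code{*Path}
#'   arguments must point at existing inputs.
#' @param simArgs named list passed to [simulationConfig()]; its seed is
#'   overridden by \code{seed}.
#' @param exprsPaths,annotPaths character vectors (one per dataset) of
#'   expression and annotation TSVs, for \code{simulate = FALSE}.
#' @param mirExprsPath,mirAnnotPath miRNA dataset TSVs.
#' @param interactionsPath interaction TSV.
#' @param knownGenesPath,knownMirsPath curated id-list files.
#' @param gmtPath gene-set GMT file.
#' @return a list of class \code{"circeNetConfig"}.
#' @export
pipelineConfig <- function(outDir = tempfile("circenet_run_"), seed = 1L,
                           geneFdr = 0.01, mirFdr = 0.05, minShared = 5L,
                           oraFdr = 0.05, universePolicy = c("network",
                                                             "file"),
                           universeFile = NULL, simulate = TRUE,
                           simArgs = list(), exprsPaths = NULL,
                           annotPaths = NULL, mirExprsPath = NULL,
                           mirAnnotPath = NULL, interactionsPath = NULL,
                           knownGenesPath = NULL, knownMirsPath = NULL,
                           gmtPath = NULL) {
    universePolicy <- match.arg(universePolicy)
    for (thr in list(geneFdr = geneFdr, mirFdr = mirFdr, oraFdr = oraFdr)) {
        if (!is.numeric(thr) || thr <= 0 || thr > 1)
            stop("FDR thresholds must lie in (0, 1]")
    }
    if (minShared < 1) stop("minShared must be >= 1")
    if (universePolicy == "file" && is.null(universeFile))
        stop("universePolicy 'file' needs universeFile")
    cfg <- list(outDir = outDir, seed = as.integer(seed),
                geneFdr = geneFdr, mirFdr = mirFdr,
                minShared = as.integer(minShared), oraFdr = oraFdr,
                universePolicy = universePolicy,
                universeFile = universeFile, simulate = isTRUE(simulate),
                simArgs = simArgs, exprsPaths = exprsPaths,
                annotPaths = annotPaths, mirExprsPath = mirExprsPath,
                mirAnnotPath = mirAnnotPath,
                interactionsPath = interactionsPath,
                knownGenesPath = knownGenesPath,
                knownMirsPath = knownMirsPath, gmtPath = gmtPath)
    class(cfg) <- "circeNetConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param config a \code{"circeNetConfig"} list.
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
    stopifnot(inherits(config, "circeNetConfig"))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    raw$simArgs <- as.list(raw$simArgs)
    do.call(pipelineConfig, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full ceRNA analysis pipeline
#'
#' Executes simulate (or load) -> differential expression -> network
#' construction -> disease extraction -> risk prioritization -> degree
#' statistics -> enrichment, writing every intermediate artifact into the
#' run directory plus a manifest (package version, seed, thresholds, md5
#' checksum of every written file). With the same configuration and seed the
#' manifest checksums are identical across runs. Any stage failure aborts
#' with the stage name and cause; artifacts written before the failure are
#' retained for debugging.
#'
#' @param config a \code{"circeNetConfig"} from [pipelineConfig()].
#' @return invisibly, a list with the run directory, the manifest, and the
#'   main in-memory results (meta-analysis, network, triples, ranking,
#'   power-law fit, enrichment table, and the ground truth when simulated).
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "circeNetConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outDir, ...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    }

    inputs <- stage("simulate", {
        if (config$simulate) {
            simArgs <- config$simArgs
            simArgs$seed <- config$seed
            simCfg <- do.call(simulationConfig, simArgs)
            study <- simulateStudy(simCfg)
            dir.create(out("inputs"), showWarnings = FALSE)
            for (i in seq_along(study$datasets))
                writeExpressionDataset(study$datasets[[i]],
                    out("inputs", sprintf("exprs_%02d.tsv", i)),
                    out("inputs", sprintf("annot_%02d.tsv", i)))
            writeExpressionDataset(study$mirDataset,
                out("inputs", "mir_exprs.tsv"), out("inputs",
                                                    "mir_annot.tsv"))
            writeInteractions(study$interactions,
                              out("inputs", "interactions.tsv"))
            writeIdList(study$truth@knownGenes,
                        out("inputs", "known_genes.txt"))
            writeIdList(study$truth@knownMirs,
                        out("inputs", "known_mirs.txt"))
            writeGMT(study$collection, out("inputs", "genesets.gmt"))
            jsonlite::write_json(
                list(deFeatures = study$truth@deFeatures,
                     deMirs = study$truth@deMirs,
                     plantedRiskCirc = study$truth@plantedRiskCirc,
                     enrichedTerm = study$truth@enrichedTerm,
                     plantedTriples = study$truth@plantedTriples),
                out("inputs", "truth.json"), auto_unbox = TRUE, digits = NA)
            list(datasets = study$datasets, mirDataset = study$mirDataset,
                 interactions = study$interactions,
                 collection = study$collection,
                 knownGenes = study$truth@knownGenes,
                 knownMirs = study$truth@knownMirs, truth = study$truth)
        } else {
            if (is.null(config$exprsPaths) || is.null(config$annotPaths))
                stop("expression input paths are required")
            datasets <- Map(readExpressionDataset, config$exprsPaths,
                            config$annotPaths)
            # interactions are loaded lazily by the build-net stage
            list(datasets = datasets,
                 mirDataset = readExpressionDataset(config$mirExprsPath,
                                                    config$mirAnnotPath),
                 interactions = NULL,
                 collection = readGMT(config$gmtPath),
                 knownGenes = readIdList(config$knownGenesPath),
                 knownMirs = readIdList(config$knownMirsPath),
                 truth = NULL)
        }
    })

    de <- stage("de", {
        statsList <- lapply(inputs$datasets, moderatedT)
        meta <- combineDatasets(statsList)
        cdegs <- selectDE(meta, config$geneFdr)
        mirRes <- singleDatasetDE(inputs$mirDataset)
        demirs <- selectDE(mirRes, config$mirFdr)
        data.table::fwrite(resultTable(meta), out("meta_results.tsv"),
                           sep = "\t")
        data.table::fwrite(cdegs, out("de_genes.tsv"), sep = "\t")
        data.table::fwrite(resultTable(mirRes), out("mir_results.tsv"),
                           sep = "\t")
        data.table::fwrite(demirs, out("de_mirs.tsv"), sep = "\t")
        list(meta = meta, cdegs = cdegs, mirRes = mirRes, demirs = demirs)
    })

    net <- stage("build-net", {
        interactions <- inputs$interactions %||%
            readInteractions(config$interactionsPath %||% "<missing>")
        built <- buildCirceNet(interactions, config$minShared)
        writeNetworkTSV(built$network, out("circenet_edges.tsv"))
        writeNetworkGraphML(built$network, out("circenet.graphml"))
        writeTriples(built$triples, out("triples.tsv"))
        jsonlite::write_json(networkSummary(built$network),
                             out("circenet_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        built
    })

    annotation <- DiseaseAnnotation(cdegSet = de$cdegs$feature,
                                    demirSet = de$demirs$feature,
                                    knownGenes = inputs$knownGenes,
                                    knownMirs = inputs$knownMirs)

    disease <- stage("extract", {
        dis <- extractDiseaseNetwork(net$triples, annotation)
        writeNetworkTSV(dis$network, out("disease_edges.tsv"))
        writeNetworkGraphML(dis$network, out("disease.graphml"))
        writeTriples(dis$triples, out("disease_triples.tsv"))
        jsonlite::write_json(networkSummary(dis$network),
                             out("disease_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        dis
    })

    prior <- stage("prioritize", {
        risk <- flagRiskTriples(disease$triples, annotation)
        ranking <- rankCircRNAs(risk, disease$triples)
        writeTriples(risk, out("risk_triples.tsv"))
        data.table::fwrite(ranking, out("ranking.tsv"), sep = "\t")
        list(risk = risk, ranking = ranking)
    })

    fit <- stage("stats", {
        if (nrow(disease$triples) == 0L) {
            message("disease network empty; degree statistics skipped")
            NULL
        } else {
            dd <- degreeDistribution(disease$network)
            data.table::fwrite(dd, out("degree_hist.tsv"), sep = "\t")
            f <- fitPowerLaw(nodeDegrees(disease$network))
            jsonlite::write_json(
                list(alpha = f@alpha, method = f@method, xmin = f@xmin,
                     nTail = f@nTail, loglogSlope = f@loglogSlope,
                     loglogR2 = f@loglogR2),
                out("powerlaw.json"), auto_unbox = TRUE, digits = NA)
            f
        }
    })

    enrichment <- stage("enrich", {
        if (nrow(prior$ranking) == 0L) {
            message("no risk circRNAs; enrichment skipped")
            NULL
        } else {
            topCirc <- prior$ranking$circ[1]
            hood <- circNeighborhood(topCirc, disease$triples, annotation)
            writeTriples(hood$triples, out("top_circ_triples.tsv"))
            data.table::fwrite(hood$summary, out("top_circ_summary.tsv"),
                               sep = "\t")
            universe <- if (config$universePolicy == "file")
                readIdList(config$universeFile)
            else mrnaNodes(disease$network)
            message("ORA universe: ", length(universe), " genes (policy ",
                    config$universePolicy, ")")
            enr <- runORA(unique(hood$triples$mrna), inputs$collection,
                          universe)
            data.table::fwrite(enr, out("enrichment.tsv"), sep = "\t")
            enr
        }
    })

    manifest <- stage("manifest", {
        files <- sort(list.files(config$outDir, recursive = TRUE))
        files <- setdiff(files, "manifest.json")
        sums <- tools::md5sum(file.path(config$outDir, files))
        m <- list(package = "circeNet",
                  version = as.character(utils::packageVersion("circeNet")),
                  seed = config$seed,
                  thresholds = list(geneFdr = config$geneFdr,
                                    mirFdr = config$mirFdr,
                                    minShared = config$minShared,
                                    oraFdr = config$oraFdr),
                  universePolicy = config$universePolicy,
                  nCdegs = nrow(de$cdegs), nDemirs = nrow(de$demirs),
                  topCirc = if (nrow(prior$ranking)) prior$ranking$circ[1]
                            else NA,
                  checksums = as.list(stats::setNames(unname(sums), files)))
        jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                             digits = NA)
        m
    })

    invisible(list(dir = config$outDir, manifest = manifest, de = de,
                   network = net, disease = disease, risk = prior$risk,
                   ranking = prior$ranking, powerLawFit = fit,
                   enrichment = enrichment, annotation = annotation,
                   truth = inputs$truth))
}
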
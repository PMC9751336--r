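#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Collects input paths, decision thresholds and the seed for
#' \code{\link{runPipeline}}. Defaults are the canonical thresholds of the
#' analysis: transcript p < 0.1 with |fold change| > 2, protein FDR < 0.1 with
#' |fold change| > 1.5, network high-confidence cutoff 0.7, regulator
#' activation |z| > 3. File names default to the layout written by
#' \code{\link{writeStudy}} under \code{inputDir}.
#'
#' @param inputDir directory holding the input tables.
#' @param outDir output directory (created by the run).
#' @param countsFile,samplesFile,intensitiesFile,mappingFile,gdaFile,networkFile,locationFile,drugFile,panelFile,termsFile,regulatorFile
#'   individual paths, defaulting into \code{inputDir}; \code{panelFile = NULL}
#'   falls back to the bundled 28-gene panel; \code{termsFile} and
#'   \code{regulatorFile} are optional stages when \code{NA}.
#' @param genePThreshold,geneFcThreshold transcript decision rule.
#' @param proteinFdrThreshold,proteinFcThreshold protein decision rule.
#' @param networkMinScore high-confidence interaction cutoff.
#' @param regulatorZ regulator activation threshold.
#' @param seed integer recorded in the run manifest (the pipeline itself is
#'   deterministic; the seed governs an optional simulation stage).
#' @param simulate optional \linkS4class{SimulationConfig}; when given, the
#'   run first generates the study into \code{inputDir}.
#' @return A validated configuration list.
#' @export
pipelineConfig <- function(inputDir, outDir,
        countsFile = file.path(inputDir, "counts.tsv"),
        samplesFile = file.path(inputDir, "samples.tsv"),
        intensitiesFile = file.path(inputDir, "intensities.tsv"),
        mappingFile = file.path(inputDir, "mapping.tsv"),
        gdaFile = file.path(inputDir, "gda.tsv"),
        networkFile = file.path(inputDir, "network.tsv"),
        locationFile = file.path(inputDir, "locations.tsv"),
        drugFile = file.path(inputDir, "drugs.tsv"),
        panelFile = NULL,
        termsFile = file.path(inputDir, "terms.gmt"),
        regulatorFile = file.path(inputDir, "regulators.tsv"),
        genePThreshold = 0.1, geneFcThreshold = 2,
        proteinFdrThreshold = 0.1, proteinFcThreshold = 1.5,
        networkMinScore = 0.7, regulatorZ = 3, seed = 1L,
        simulate = NULL) {
    thr <- c(gene_p = genePThreshold, gene_fc = geneFcThreshold,
        protein_fdr = proteinFdrThreshold, protein_fc = proteinFcThreshold,
        network_min_score = networkMinScore, regulator_z = regulatorZ)
    if (any(!is.finite(thr)) || any(thr <= 0))
        stop("all thresholds must be positive")
    cfg <- list(inputDir = inputDir, outDir = outDir,
        countsFile = countsFile, samplesFile = samplesFile,
        intensitiesFile = intensitiesFile, mappingFile = mappingFile,
        gdaFile = gdaFile, networkFile = networkFile,
        locationFile = locationFile, drugFile = drugFile,
        panelFile = panelFile, termsFile = termsFile,
        regulatorFile = regulatorFile, thresholds = thr,
        seed = as.integer(seed), simulate = simulate)
    class(cfg) <- "fibroscorePipelineConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
            call. = FALSE))
}

.safeLabel <- function(x) gsub("[^A-Za-z0-9_.-]", "-", x)

#' Run the full analysis pipeline
#'
#' Executes, in order: optional simulation of the study inputs, input reading
#' and validation, activation scoring with group tests, per-source
#' differential expression on both omics layers, cross-omics integration
#' (feature matching, fold-change correlations, location prevalence,
#' ECM/membrane-filtered sample clustering, PCA), term enrichment and
#' regulator activation calls, and the target-prioritization cascade. All
#' artifacts are written as plain-text tables plus a machine-readable manifest
#' (package version, seed, thresholds, md5 of every artifact); identical
#' inputs and configuration yield byte-identical outputs.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @importFrom SummarizedExperiment assay colData
#' @importFrom utils packageVersion
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "fibroscorePipelineConfig"))
    if (!is.null(config$simulate))
        .stage("simulate", writeStudy(simulateStudy(config$simulate),
            config$inputDir))
    thr <- config$thresholds

    samples <- .stage("validation", readSampleSheet(config$samplesFile))
    counts <- .stage("validation", readOmicsMatrix(config$countsFile, "counts"))
    intens <- .stage("validation",
        readOmicsMatrix(config$intensitiesFile, "intensities"))
    mapping <- .stage("validation", readMappingTable(config$mappingFile))
    gda <- .stage("validation", readGdaTable(config$gdaFile))
    network <- .stage("validation", readNetworkTable(config$networkFile))
    locations <- .stage("validation", readLocationTable(config$locationFile))
    drugs <- .stage("validation", readDrugTable(config$drugFile))
    panel <- .stage("validation", if (is.null(config$panelFile))
        cfActivationPanel() else readGenePanel(config$panelFile))
    terms <- if (!is.null(config$termsFile) && file.exists(config$termsFile))
        .stage("validation", readGmt(config$termsFile)) else NULL
    regulators <- if (!is.null(config$regulatorFile) &&
            file.exists(config$regulatorFile))
        .stage("validation", readRegulatorTable(config$regulatorFile)) else NULL

    seT <- .stage("validation", asOmicsExperiment(counts, samples, "counts"))
    seP <- .stage("validation",
        asOmicsExperiment(intens, samples, "intensities"))
    sources <- unique(samples$source)

    sf <- .stage("normalization", medianRatioSizeFactors(assay(seT)))

    act <- .stage("score", testScoreDifferences(
        computeActivationScores(seT, panel = panel, sizeFactors = sf)))

    deT <- list(); deP <- list()
    for (src in sources) {
        deT[[src]] <- .stage(paste0("de-transcript-", src),
            deTest(seT, source = src, layer = "transcript", sizeFactors = sf,
                sigThreshold = thr[["gene_p"]],
                fcThreshold = thr[["gene_fc"]]))
        deP[[src]] <- .stage(paste0("de-protein-", src),
            deTest(seP, source = src, layer = "protein",
                sigThreshold = thr[["protein_fdr"]],
                fcThreshold = thr[["protein_fc"]]))
    }

    crossomics <- .stage("crossomics", {
        map <- matchFeatures(rownames(counts), rownames(intens), mapping)
        geneOfProtein <- structure(mapping$gene_id, names = mapping$protein_id)
        corrBySource <- lapply(sources, function(src) {
            all <- fcCorrelation(deT[[src]], deP[[src]], map, FALSE)
            dep <- suppressWarnings(
                fcCorrelation(deT[[src]], deP[[src]], map, TRUE))
            list(source = src, r_all = all$r, n_all = all$n,
                r_dep = dep$r, n_dep = dep$n, dep_defined = dep$defined)
        })
        names(corrBySource) <- sources
        depProteins <- sort(unique(unlist(lapply(deP, function(d) {
            tab <- deTable(d)
            tab$feature_id[tab$call != "ns"]
        }))), method = "radix")
        depGenes <- sort(unique(geneOfProtein[depProteins]), method = "radix")
        allGenes <- sort(unique(geneOfProtein[rownames(intens)]),
            method = "radix")
        prevalence <- locationPrevalence(allGenes, locations, depGenes)
        ecmPm <- locations$feature_id[locations$location %in%
            c("extracellular space", "plasma membrane")]
        clustSubset <- depProteins[geneOfProtein[depProteins] %in% ecmPm]
        normP <- totalAreaNormalize(intens)
        clust <- if (length(clustSubset) >= 2)
            sampleCorrelationClustering(normP, clustSubset) else NULL
        logCounts <- log2(sweep(counts, 2, sf, "/") + 1)
        pca <- pcaSamples(logCounts)
        list(map = map, geneOfProtein = geneOfProtein,
            corrBySource = corrBySource, prevalence = prevalence,
            depProteins = depProteins, clust = clust, pca = pca)
    })

    enrich <- NULL
    if (!is.null(terms)) enrich <- .stage("annotate", {
        out <- lapply(sources, function(src) {
            degs <- c(deCalls(deT[[src]], "up"), deCalls(deT[[src]], "down"))
            enrichTerms(degs, rownames(counts), terms)
        })
        names(out) <- sources
        out
    })
    regCalls <- NULL
    if (!is.null(regulators)) regCalls <- .stage("annotate", {
        out <- lapply(sources, function(src)
            regulatorActivation(deT[[src]], regulators,
                zThreshold = thr[["regulator_z"]]))
        names(out) <- sources
        out
    })

    prioritized <- .stage("prioritize", {
        geneOfProtein <- crossomics$geneOfProtein
        upDepGenes <- sort(unique(unlist(lapply(deP, function(d) {
            g <- geneOfProtein[deCalls(d, "up")]
            g[!is.na(g)]
        }))), method = "radix")
        associated <- filterDiseaseAssociated(upDepGenes, gda)
        added <- expandNetwork(associated$genes, upDepGenes, network,
            minScore = thr[["network_min_score"]])
        panelObj <- buildPanel(associated, added, deP, drugs,
            network = network, minScore = thr[["network_min_score"]],
            geneOfProtein = geneOfProtein)
        vennUp <- intersectSources(deT, "up")
        vennDown <- intersectSources(deT, "down")
        list(upDepGenes = upDepGenes, associated = associated, added = added,
            panel = panelObj, vennUp = vennUp, vennDown = vennDown)
    })

    paths <- .stage("report", .writeReport(config, samples, act, deT, deP,
        crossomics, enrich, regCalls, prioritized))

    invisible(list(activation = act, deTranscript = deT, deProtein = deP,
        crossomics = crossomics, enrichment = enrich, regulators = regCalls,
        prioritized = prioritized, sizeFactors = sf, paths = paths))
}

.writeReport <- function(config, samples, act, deT, deP, crossomics, enrich,
        regCalls, prioritized) {
    out <- config$outDir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    p <- function(f) file.path(out, f)
    paths <- character()

    sc <- data.frame(samples,
        score = as.numeric(activationScores(act))[match(samples$sample_id,
            names(activationScores(act)))])
    paths["scores"] <- writeTsv(sc, p("activation_scores.tsv"))
    jsonlite::write_json(list(anova = anovaTable(act),
        tukey = tukeyTable(act), used_genes = usedGenes(act),
        dropped_genes = droppedGenes(act)),
        p("activation_tests.json"), auto_unbox = TRUE, digits = NA)
    paths["score_tests"] <- p("activation_tests.json")

    for (src in names(deT)) {
        f <- p(sprintf("de_transcript_%s.tsv", .safeLabel(src)))
        paths[paste0("de_transcript_", src)] <- writeTsv(deTable(deT[[src]]), f)
        f <- p(sprintf("de_protein_%s.tsv", .safeLabel(src)))
        paths[paste0("de_protein_", src)] <- writeTsv(deTable(deP[[src]]), f)
    }

    jsonlite::write_json(list(coverage = crossomics$map$coverage,
        correlations = unname(crossomics$corrBySource)),
        p("correlation_report.json"), auto_unbox = TRUE, digits = NA)
    paths["correlation_report"] <- p("correlation_report.json")
    paths["location_prevalence"] <- writeTsv(crossomics$prevalence,
        p("location_prevalence.tsv"))
    if (!is.null(crossomics$clust)) {
        C <- crossomics$clust$sampleCorr
        paths["sample_correlation"] <- writeTsv(
            data.frame(sample_id = rownames(C), C, check.names = FALSE),
            p("sample_correlation.tsv"))
        writeLines(crossomics$clust$newick, p("dendrogram.nwk"))
        paths["dendrogram"] <- p("dendrogram.nwk")
    }
    pcaDf <- data.frame(sample_id = rownames(crossomics$pca$coordinates),
        crossomics$pca$coordinates, check.names = FALSE)
    paths["pca"] <- writeTsv(pcaDf, p("pca_coordinates.tsv"))
    paths["pca_explained"] <- writeTsv(
        data.frame(component = seq_along(crossomics$pca$explained),
            explained = crossomics$pca$explained),
        p("pca_explained.tsv"))

    if (!is.null(enrich))
        for (src in names(enrich))
            paths[paste0("enrichment_", src)] <- writeTsv(enrich[[src]],
                p(sprintf("enrichment_%s.tsv", .safeLabel(src))))
    if (!is.null(regCalls))
        for (src in names(regCalls))
            paths[paste0("regulators_", src)] <- writeTsv(regCalls[[src]],
                p(sprintf("regulators_%s.tsv", .safeLabel(src))))

    jsonlite::write_json(list(up = prioritized$vennUp$regions,
        down = prioritized$vennDown$regions),
        p("venn.json"), digits = NA)
    paths["venn"] <- p("venn.json")
    paths["panel"] <- writeTsv(panelTable(prioritized$panel), p("panel.tsv"))
    members <- panelMembers(prioritized$panel)
    net <- readNetworkTable(config$networkFile)
    sub <- net[net$node_a %in% members & net$node_b %in% members &
        net$combined_score >= config$thresholds[["network_min_score"]], ]
    sub <- sub[order(sub$node_a, sub$node_b, method = "radix"), ]
    paths["panel_network"] <- writeTsv(sub, p("panel_network.tsv"))

    manifest <- list(package = "fibroscore",
        version = as.character(packageVersion("fibroscore")),
        seed = config$seed,
        thresholds = as.list(config$thresholds),
        artifacts = as.list(structure(
            unname(tools::md5sum(sort(unname(paths), method = "radix"))),
            names = basename(sort(unname(paths), method = "radix")))))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
        digits = NA)
    paths["manifest"] <- p("manifest.json")
    paths
}
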
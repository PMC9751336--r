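#' @include AllClasses.R
NULL

## Synthetic multi-omics generator. Counts are negative-binomial around
## log-normal gene baselines with per-sample library-size factors drawn
## log-uniform in [0.5, 2] so size-factor estimation is exercised
## non-trivially; protein intensities are log-normal around gene-linked
## baselines with planted fold changes coupled to the transcript program.

.fibrosisDiseases <- c("pulmonary fibrosis", "cardiac fibrosis",
    "hepatic fibrosis", "renal fibrosis")

.cellLocations <- c("extracellular space", "plasma membrane", "cytoplasm",
    "nucleus", "other")

.sampleDesign <- function(config) {
    grid <- expand.grid(replicate = seq_len(config@nReplicates),
        condition = c("control", "treated"), source = config@sources,
        stringsAsFactors = FALSE)
    grid <- grid[, c("source", "condition", "replicate")]
    grid$sample_id <- paste(grid$source, grid$condition, grid$replicate, sep = "_")
    grid[, c("sample_id", "source", "condition", "replicate")]
}

.plantDegSets <- function(config, geneIds) {
    nonPanel <- setdiff(geneIds, config@panelGenes)
    sets <- list()
    for (src in config@sources) {
        nDeg <- round(config@fracDeg * length(nonPanel))
        if (nDeg > 0) {
            genes <- sample(nonPanel, nDeg)
            signs <- sample(c(-1, 1), nDeg, replace = TRUE)
            df <- data.frame(gene_id = genes,
                lfc = signs * config@lfcMagnitude,
                stringsAsFactors = FALSE)
        } else {
            df <- data.frame(gene_id = character(), lfc = numeric())
        }
        if (config@panelTreatmentLfc > 0) {
            df <- rbind(df, data.frame(gene_id = config@panelGenes,
                lfc = config@panelTreatmentLfc))
        }
        o <- order(df$gene_id, method = "radix")
        sets[[src]] <- df[o, , drop = FALSE]
        rownames(sets[[src]]) <- NULL
    }
    sets
}

#' Simulate a transcript count matrix with planted ground truth
#'
#' Draws gene baseline means from a log-normal, plants per-source treatment
#' effects on a random gene subset (and the marker panel, when
#' \code{panelTreatmentLfc > 0}), shifts panel genes upward in the control
#' samples of pre-activated sources, and samples negative-binomial counts
#' (Var = mu + alpha mu^2) scaled by per-sample library factors.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with \code{se}, a \code{SummarizedExperiment} of counts
#'   (colData: sample_id, source, condition, replicate), and \code{truth}, a
#'   \linkS4class{GroundTruth} carrying the planted effects.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 60, nProteins = 30, seed = 3))
#' dim(SummarizedExperiment::assay(sim$se))
#' @importFrom stats rlnorm runif rnbinom rpois rnorm
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
simulateCounts <- function(config) {
    validObject(config)
    nPanel <- length(config@panelGenes)
    geneIds <- c(config@panelGenes,
        sprintf("SYNG%04d", seq_len(config@nGenes - nPanel)))
    design <- .sampleDesign(config)
    withr::with_seed(config@seed, {
        mu <- rlnorm(config@nGenes, config@nbMeanLogMu, config@nbMeanLogSd)
        names(mu) <- geneIds
        lambda <- exp(runif(nrow(design), log(config@libSizeRange[1]),
            log(config@libSizeRange[2])))
        degSets <- .plantDegSets(config, geneIds)
        counts <- matrix(0L, nrow = config@nGenes, ncol = nrow(design),
            dimnames = list(geneIds, design$sample_id))
        panelInd <- as.numeric(geneIds %in% config@panelGenes)
        for (j in seq_len(nrow(design))) {
            src <- design$source[j]
            lfcVec <- numeric(config@nGenes)
            names(lfcVec) <- geneIds
            ds <- degSets[[src]]
            lfcVec[ds$gene_id] <- ds$lfc
            shift <- if (design$condition[j] == "treated") lfcVec
                else if (src %in% config@preactivatedSources)
                    config@panelOffset * panelInd
                else numeric(config@nGenes)
            m <- mu * 2^shift * lambda[j]
            counts[, j] <- if (config@dispersion > 0)
                rnbinom(config@nGenes, mu = m, size = 1 / config@dispersion)
                else rpois(config@nGenes, m)
        }
    })
    se <- SummarizedExperiment(assays = list(counts = counts),
        colData = DataFrame(design, row.names = design$sample_id))
    metadata(se)$config <- config
    truth <- new("GroundTruth", degSets = degSets, depSets = list(),
        preactivatedSources = config@preactivatedSources,
        panelGenes = config@panelGenes, panelOffset = config@panelOffset,
        baselineMu = mu, mapping = data.frame(gene_id = character(),
            protein_id = character()), expectedPanel = character(),
        moduleGenes = character())
    list(se = se, truth = truth)
}

#' Simulate a protein intensity matrix coupled to the transcript truth
#'
#' Proteins map 1:1 to a gene subset; a configurable fraction are "orphans"
#' mapped to genes outside the transcript universe, emulating incomplete
#' transcript coverage of the proteome. For proteins of planted differential
#' genes the true protein log2 fold change is
#' \code{rho * transcript_lfc + sqrt(1 - rho^2) * noise}; intensities are
#' log-normal around gene-linked baselines with measurement noise
#' \code{proteinNoiseSd} and per-sample loading factors.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth} from \code{\link{simulateCounts}}.
#' @return A list with \code{se} (intensities \code{SummarizedExperiment}) and
#'   the updated \code{truth} (protein mapping and planted DEP sets filled in).
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
simulateProteome <- function(config, truth) {
    validObject(config)
    stopifnot(is(truth, "GroundTruth"))
    geneIds <- names(truth@baselineMu)
    if (config@nProteins > length(geneIds))
        stop("nProteins exceeds the simulated gene universe")
    design <- .sampleDesign(config)
    nOrphan <- round(config@orphanFrac * config@nProteins)
    nMapped <- config@nProteins - nOrphan
    rho <- config@couplingRho
    withr::with_seed(config@seed + 1L, {
        mappedGenes <- sample(geneIds, nMapped)
        orphanGenes <- if (nOrphan > 0) sprintf("ORPH%03d", seq_len(nOrphan))
            else character()
        protGenes <- c(mappedGenes, orphanGenes)
        proteinIds <- paste0("P.", protGenes)
        ## dampened abundance coupling: protein log2 baselines track gene
        ## baselines at half strength so no single protein dominates the
        ## column totals (total-area normalization stays well-behaved)
        logMu <- log2(truth@baselineMu)
        base <- numeric(config@nProteins)
        base[seq_len(nMapped)] <- 10 + 0.5 * (logMu[mappedGenes] - mean(logMu)) +
            rnorm(nMapped, 0, 1)
        if (nOrphan > 0)
            base[nMapped + seq_len(nOrphan)] <- 10 + rnorm(nOrphan, 0, 1.3)
        names(base) <- proteinIds
        depSets <- list()
        pLfc <- list()
        for (src in names(truth@degSets)) {
            ds <- truth@degSets[[src]]
            hit <- ds$gene_id %in% mappedGenes
            g <- ds$gene_id[hit]
            tl <- ds$lfc[hit]
            pl <- rho * tl + sqrt(1 - rho^2) *
                rnorm(length(tl), 0, config@lfcMagnitude)
            df <- data.frame(protein_id = paste0("P.", g), gene_id = g,
                lfc = pl, stringsAsFactors = FALSE)
            o <- order(df$protein_id, method = "radix")
            depSets[[src]] <- df[o, , drop = FALSE]
            rownames(depSets[[src]]) <- NULL
            v <- numeric(config@nProteins)
            names(v) <- proteinIds
            v[df$protein_id] <- df$lfc
            pLfc[[src]] <- v
        }
        loading <- exp(runif(nrow(design), log(0.7), log(1.4)))
        intensities <- matrix(0, nrow = config@nProteins, ncol = nrow(design),
            dimnames = list(proteinIds, design$sample_id))
        for (j in seq_len(nrow(design))) {
            eff <- if (design$condition[j] == "treated")
                pLfc[[design$source[j]]] else numeric(config@nProteins)
            intensities[, j] <- 2^(base + eff +
                rnorm(config@nProteins, 0, config@proteinNoiseSd)) * loading[j]
        }
        if (config@missingRate > 0) {
            idx <- sample(length(intensities),
                round(config@missingRate * length(intensities)))
            intensities[idx] <- NA_real_
        }
    })
    se <- SummarizedExperiment(assays = list(intensities = intensities),
        colData = DataFrame(design, row.names = design$sample_id))
    metadata(se)$config <- config
    truth@depSets <- depSets
    truth@mapping <- data.frame(gene_id = protGenes, protein_id = proteinIds,
        stringsAsFactors = FALSE)
    validObject(truth)
    list(se = se, truth = truth)
}

#' Simulate annotation tables with a planted network module
#'
#' Generates a gene-disease association table over the four fibrosis labels
#' (plus decoy non-fibrosis rows), an undirected interaction network whose
#' background edge scores stay below the high-confidence cutoff while a planted
#' module wires some non-associated upregulated proteins to associated ones at
#' high confidence, a single-location cell-location table (differential
#' proteins enriched for extracellular space / plasma membrane), a
#' drug-availability table, GMT-style term sets, and an upstream-regulator edge
#' table with one planted activated and one planted inhibited regulator.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth} after
#'   \code{\link{simulateProteome}}.
#' @return An \linkS4class{AnnotationBundle}.
#' @export
simulateAnnotations <- function(config, truth) {
    validObject(config)
    stopifnot(is(truth, "GroundTruth"))
    geneIds <- names(truth@baselineMu)
    upDepGenes <- sort(unique(unlist(lapply(truth@depSets,
        function(d) d$gene_id[d$lfc > 0]))), method = "radix")
    depGenes <- sort(unique(unlist(lapply(truth@depSets,
        function(d) d$gene_id))), method = "radix")
    upDegGenes <- sort(unique(unlist(lapply(truth@degSets,
        function(d) d$gene_id[d$lfc > 0]))), method = "radix")
    orphanGenes <- setdiff(truth@mapping$gene_id, geneIds)
    withr::with_seed(config@seed + 2L, {
        ## gene-disease associations
        nAssoc <- round(config@assocFrac * length(upDepGenes))
        associated <- sort(sample(upDepGenes, nAssoc), method = "radix")
        gdaRows <- list()
        for (g in associated) {
            dis <- sample(.fibrosisDiseases, sample(1:3, 1))
            gdaRows[[g]] <- data.frame(gene_id = g, disease = dis,
                score = round(runif(length(dis), 0.05, 0.9), 3))
        }
        bg <- sample(setdiff(geneIds, upDepGenes),
            min(40L, length(setdiff(geneIds, upDepGenes))))
        for (g in bg)
            gdaRows[[g]] <- data.frame(gene_id = g,
                disease = sample(.fibrosisDiseases, 1),
                score = round(runif(1, 0.01, 0.5), 3))
        decoy <- sample(upDepGenes, min(5L, length(upDepGenes)))
        for (g in decoy)
            gdaRows[[paste0(g, ".decoy")]] <- data.frame(gene_id = g,
                disease = "dilated cardiomyopathy",
                score = round(runif(1, 0.1, 0.6), 3))
        gda <- do.call(rbind, gdaRows)
        gda <- gda[!duplicated(paste(gda$gene_id, gda$disease)), ]
        gda <- gda[order(gda$gene_id, gda$disease, method = "radix"), ]
        rownames(gda) <- NULL

        ## interaction network: planted high-confidence module + sub-cutoff noise
        pool <- setdiff(upDepGenes, associated)
        moduleGenes <- sort(sample(pool, min(config@nModule, length(pool))),
            method = "radix")
        edges <- list()
        if (length(moduleGenes) && length(associated)) {
            for (g in moduleGenes) {
                partners <- sample(associated, min(2L, length(associated)))
                edges[[g]] <- data.frame(node_a = g, node_b = partners,
                    combined_score = config@moduleScore)
            }
        }
        nBg <- config@nBackgroundEdges
        a <- sample(geneIds, nBg, replace = TRUE)
        b <- sample(geneIds, nBg, replace = TRUE)
        keep <- a != b
        edges[["background"]] <- data.frame(node_a = a[keep], node_b = b[keep],
            combined_score = round(runif(sum(keep), 0.15, 0.699), 3))
        net <- do.call(rbind, edges)
        key <- paste(pmin(net$node_a, net$node_b), pmax(net$node_a, net$node_b))
        net <- net[!duplicated(key), ]
        net <- net[order(net$node_a, net$node_b, method = "radix"), ]
        rownames(net) <- NULL

        ## cell locations: one per feature; differential proteins lean ECM/membrane
        features <- c(geneIds, orphanGenes)
        isDep <- features %in% depGenes
        locBg <- c(0.08, 0.10, 0.40, 0.27, 0.15)
        locDep <- c(0.22, 0.20, 0.25, 0.18, 0.15)
        loc <- character(length(features))
        loc[!isDep] <- sample(.cellLocations, sum(!isDep), replace = TRUE,
            prob = locBg)
        loc[isDep] <- sample(.cellLocations, sum(isDep), replace = TRUE,
            prob = locDep)
        locations <- data.frame(feature_id = features, location = loc,
            stringsAsFactors = FALSE)
        locations <- locations[order(locations$feature_id, method = "radix"), ]
        rownames(locations) <- NULL

        ## drug availability
        targetsWithDrugs <- c(associated, moduleGenes)
        druggable <- sort(sample(targetsWithDrugs,
            ceiling(0.35 * length(targetsWithDrugs))), method = "radix")
        druggable <- c(druggable, sample(setdiff(geneIds, druggable), 5L))
        drugs <- data.frame(gene_id = druggable,
            drug_name = paste0("CMPD-", druggable),
            status = sample(c("approved", "investigational"),
                length(druggable), replace = TRUE),
            stringsAsFactors = FALSE)
        drugs <- drugs[order(drugs$gene_id, method = "radix"), ]
        rownames(drugs) <- NULL

        ## GMT-style term sets: random processes plus location-derived terms
        terms <- list()
        labels <- character()
        for (i in seq_len(15)) {
            id <- sprintf("T%02d", i)
            terms[[id]] <- sort(sample(geneIds,
                sample(10:40, 1)), method = "radix")
            labels[id] <- sprintf("synthetic process %02d", i)
        }
        ecm <- locations$feature_id[locations$location == "extracellular space"]
        pm <- locations$feature_id[locations$location == "plasma membrane"]
        terms[["LOC:ECM"]] <- sort(intersect(ecm, geneIds), method = "radix")
        labels["LOC:ECM"] <- "extracellular matrix organization"
        terms[["LOC:PM"]] <- sort(intersect(pm, geneIds), method = "radix")
        labels["LOC:PM"] <- "plasma membrane component"
        terms <- terms[lengths(terms) > 0]
        attr(terms, "labels") <- labels[names(terms)]

        ## upstream-regulator edges: one planted activator, one planted repressor
        nReg <- min(40L, length(upDegGenes))
        regRows <- list(
            data.frame(regulator = "REG-ACT",
                target = sample(upDegGenes, nReg), sign = 1L),
            data.frame(regulator = "REG-INH",
                target = sample(upDegGenes, nReg), sign = -1L))
        for (r in c("REG-NULL1", "REG-NULL2")) {
            tg <- sample(geneIds, 30L)
            regRows[[r]] <- data.frame(regulator = r, target = tg,
                sign = sample(c(-1L, 1L), 30L, replace = TRUE))
        }
        regulators <- do.call(rbind, regRows)
        regulators <- regulators[!duplicated(
            paste(regulators$regulator, regulators$target)), ]
        regulators <- regulators[order(regulators$regulator, regulators$target,
            method = "radix"), ]
        rownames(regulators) <- NULL
    })
    new("AnnotationBundle", gda = gda, network = net, locations = locations,
        drugs = drugs, terms = terms, regulators = regulators)
}

## Independent brute-force reference for the expected prioritized panel:
## plain loops over table rows, deliberately sharing no code with the
## prioritization module under test.
.bruteForceExpectedPanel <- function(truth, bundle, minScore = 0.7) {
    candidates <- sort(unique(unlist(lapply(truth@depSets,
        function(d) d$gene_id[d$lfc > 0]))), method = "radix")
    gda <- bundle@gda
    associated <- character()
    for (g in candidates) {
        rows <- gda[gda$gene_id == g & gda$disease %in% .fibrosisDiseases &
            gda$score > 0, , drop = FALSE]
        if (nrow(rows) > 0) associated <- c(associated, g)
    }
    net <- bundle@network
    added <- character()
    for (g in setdiff(candidates, associated)) {
        hit <- FALSE
        for (i in seq_len(nrow(net))) {
            if (net$combined_score[i] < minScore) next
            if ((net$node_a[i] == g && net$node_b[i] %in% associated) ||
                (net$node_b[i] == g && net$node_a[i] %in% associated)) {
                hit <- TRUE
                break
            }
        }
        if (hit) added <- c(added, g)
    }
    sort(unique(c(associated, added)), method = "radix")
}

#' Simulate a complete synthetic study
#'
#' Runs \code{\link{simulateCounts}}, \code{\link{simulateProteome}} and
#' \code{\link{simulateAnnotations}} in sequence and derives the expected
#' prioritized panel from the planted truth by an independent brute-force scan
#' over the annotation tables.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{transcripts}, \code{proteins}
#'   (\code{SummarizedExperiment}s), \code{annotations}
#'   (\linkS4class{AnnotationBundle}), \code{truth}
#'   (\linkS4class{GroundTruth}, \code{expectedPanel} filled) and
#'   \code{config}.
#' @examples
#' study <- simulateStudy(simulationConfig(nGenes = 80, nProteins = 50, seed = 5))
#' study$truth
#' @export
simulateStudy <- function(config) {
    cs <- simulateCounts(config)
    pr <- simulateProteome(config, cs$truth)
    truth <- pr$truth
    bundle <- simulateAnnotations(config, truth)
    truth@expectedPanel <- .bruteForceExpectedPanel(truth, bundle)
    truth@moduleGenes <- sort(intersect(truth@expectedPanel,
        setdiff(unlist(lapply(truth@depSets, function(d) d$gene_id)),
            bundle@gda$gene_id)), method = "radix")
    list(transcripts = cs$se, proteins = pr$se, annotations = bundle,
        truth = truth, config = config)
}

#' Configuration of the bundled end-to-end fixture
#'
#' A deterministic study used by the pipeline smoke tests and worked examples,
#' designed so the planted differential-protein truth is exactly recoverable
#' by the protein decision rule: perfect transcript-protein coupling
#' (rho = 1), low protein measurement noise, and a perturbed-protein mass
#' fraction of a few percent (as in real DIA studies) so the composition bias
#' of total-area normalization stays far from the fold-change decision
#' boundary. The expected prioritized panel is then a deterministic contract.
#'
#' @param seed RNG seed of the fixture.
#' @return A \linkS4class{SimulationConfig}.
#' @export
fixtureConfig <- function(seed = 101L) {
    simulationConfig(nGenes = 1500L, nProteins = 750L, fracDeg = 0.04,
        couplingRho = 1, proteinNoiseSd = 0.1, seed = seed)
}

#' Write a simulated study to disk as plain-text tables
#'
#' Emits the counts and intensity matrices, sample sheet, gene-protein mapping,
#' annotation tables, marker panel, GMT term sets, regulator table and a truth
#' JSON, in the fixed TSV dialect the readers expect.
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @importFrom SummarizedExperiment assay colData
#' @importFrom utils write.table
#' @export
writeStudy <- function(study, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    paths <- c(counts = p("counts.tsv"), intensities = p("intensities.tsv"),
        samples = p("samples.tsv"), mapping = p("mapping.tsv"),
        gda = p("gda.tsv"), network = p("network.tsv"),
        locations = p("locations.tsv"), drugs = p("drugs.tsv"),
        panel = p("panel.txt"), terms = p("terms.gmt"),
        regulators = p("regulators.tsv"), truth = p("truth.json"))
    writeOmicsMatrix(assay(study$transcripts), paths[["counts"]])
    writeOmicsMatrix(assay(study$proteins), paths[["intensities"]])
    writeTsv(as.data.frame(colData(study$transcripts)), paths[["samples"]])
    ann <- study$annotations
    writeTsv(study$truth@mapping, paths[["mapping"]])
    writeTsv(ann@gda, paths[["gda"]])
    writeTsv(ann@network, paths[["network"]])
    writeTsv(ann@locations, paths[["locations"]])
    writeTsv(ann@drugs, paths[["drugs"]])
    writeLines(study$truth@panelGenes, paths[["panel"]])
    writeGmt(ann@terms, paths[["terms"]])
    writeTsv(ann@regulators, paths[["regulators"]])
    truth <- study$truth
    jsonlite::write_json(list(
        deg_sets = truth@degSets, dep_sets = truth@depSets,
        preactivated_sources = truth@preactivatedSources,
        panel_genes = truth@panelGenes, panel_offset = truth@panelOffset,
        expected_panel = truth@expectedPanel,
        module_genes = truth@moduleGenes),
        paths[["truth"]], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
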
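#' @import methods
#' @include AllGenerics.R
NULL

## Central S4 containers. Omics matrices travel as SummarizedExperiment objects
## (assay "counts" or "intensities"; colData columns sample_id, source,
## condition, replicate); the classes below hold simulation parameters, planted
## truth, and stage results.

#' Simulation parameters for the synthetic cardiac-fibroblast study
#'
#' Captures every knob of the synthetic multi-omics generator that emulates a
#' three-source (aHCF, fHCF, hiPSC-CF) x two-condition (control, TGF-beta
#' treated) x three-replicate activation study: negative-binomial transcript
#' counts over log-normal gene baselines, log-normal protein intensities
#' partially coupled to transcript fold changes, and the annotation tables
#' (gene-disease scores, interaction network, cell locations, drugs, term
#' sets) consumed downstream.
#'
#' @slot nGenes number of simulated genes (includes the marker panel).
#' @slot nProteins number of simulated proteins (at most \code{nGenes}).
#' @slot sources character vector of cell-source labels.
#' @slot nReplicates replicates per source x condition cell (at least 2).
#' @slot nbMeanLogMu,nbMeanLogSd meanlog/sdlog of the log-normal draw of gene
#'   baseline means.
#' @slot dispersion negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @slot libSizeRange range of the log-uniform per-sample library-size factor
#'   draw (default 0.5 to 2); equal bounds disable library-size variation.
#' @slot fracDeg fraction of non-panel genes given a planted treatment effect
#'   per source.
#' @slot lfcMagnitude absolute planted log2 fold change of those genes.
#' @slot panelGenes marker-panel gene symbols (always part of the universe).
#' @slot panelOffset log2 shift added to panel genes in the control samples of
#'   pre-activated sources (basal-activation contrast).
#' @slot panelTreatmentLfc log2 treatment effect planted on panel genes in all
#'   sources (0 disables; nonzero panel genes join the "up" truth sets).
#' @slot preactivatedSources sources whose control samples carry the offset.
#' @slot couplingRho target correlation between transcript and protein planted
#'   log2 fold changes for coupled proteins.
#' @slot proteinNoiseSd log2-scale sd of protein measurement noise.
#' @slot orphanFrac fraction of proteins mapped to genes outside the transcript
#'   universe (emulates incomplete transcript coverage of the proteome).
#' @slot missingRate fraction of intensity entries set to NA (off by default).
#' @slot assocFrac fraction of upregulated differential proteins given fibrosis
#'   disease-association rows.
#' @slot nModule number of non-associated upregulated proteins wired to
#'   associated ones at high confidence (the planted network module).
#' @slot moduleScore combined score of planted module edges.
#' @slot nBackgroundEdges number of random background network edges (scores
#'   drawn below the high-confidence cutoff).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer", nProteins = "integer",
        sources = "character", nReplicates = "integer",
        nbMeanLogMu = "numeric", nbMeanLogSd = "numeric",
        dispersion = "numeric", libSizeRange = "numeric",
        fracDeg = "numeric", lfcMagnitude = "numeric",
        panelGenes = "character", panelOffset = "numeric",
        panelTreatmentLfc = "numeric", preactivatedSources = "character",
        couplingRho = "numeric", proteinNoiseSd = "numeric",
        orphanFrac = "numeric", missingRate = "numeric",
        assocFrac = "numeric", nModule = "integer", moduleScore = "numeric",
        nBackgroundEdges = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@nProteins < 1L) msg <- c(msg, "nProteins must be positive")
    if (object@nProteins > object@nGenes)
        msg <- c(msg, "nProteins must not exceed nGenes")
    if (length(object@sources) < 1L || anyDuplicated(object@sources))
        msg <- c(msg, "sources must be non-empty and unique")
    if (object@nReplicates < 2L)
        msg <- c(msg, "nReplicates must be at least 2 (group tests undefined otherwise)")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (length(object@libSizeRange) != 2 || any(object@libSizeRange <= 0) ||
            diff(object@libSizeRange) < 0)
        msg <- c(msg, "libSizeRange must be two positive non-decreasing values")
    for (s in c("fracDeg", "orphanFrac", "missingRate", "assocFrac")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
    }
    if (abs(object@couplingRho) > 1)
        msg <- c(msg, "couplingRho must lie in [-1, 1]")
    if (object@proteinNoiseSd < 0) msg <- c(msg, "proteinNoiseSd must be >= 0")
    if (object@moduleScore < 0 || object@moduleScore > 1)
        msg <- c(msg, "moduleScore must lie in [0, 1]")
    if (length(object@panelGenes) < 1L || anyDuplicated(object@panelGenes))
        msg <- c(msg, "panelGenes must be non-empty and unique")
    if (object@nGenes < length(object@panelGenes))
        msg <- c(msg, "nGenes must be at least the panel size (panel genes live in the universe)")
    if (!all(object@preactivatedSources %in% object@sources))
        msg <- c(msg, "preactivatedSources must be a subset of sources")
    if (is.na(object@seed) || object@seed >= 2^31 - 10)
        msg <- c(msg, "seed must be a finite integer below 2^31 - 10")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the study design the package targets: three cardiac
#' fibroblast sources, control vs TGF-beta-treated, n = 3 replicates, with the
#' two primary-cell sources pre-activated (panel offset on their control
#' samples) relative to hiPSC-derived cells.
#'
#' @param nGenes,nProteins universe sizes (desk-scale defaults).
#' @param sources,nReplicates design layout.
#' @param nbMeanLogMu,nbMeanLogSd,dispersion,libSizeRange count model
#'   parameters.
#' @param fracDeg,lfcMagnitude planted differential-expression program.
#' @param panelGenes,panelOffset,panelTreatmentLfc,preactivatedSources marker
#'   panel behaviour.
#' @param couplingRho,proteinNoiseSd,orphanFrac,missingRate proteome model.
#' @param assocFrac,nModule,moduleScore,nBackgroundEdges annotation tables.
#' @param seed RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, nProteins = 60, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nGenes = 600L, nProteins = 300L,
        sources = c("aHCF", "fHCF", "hiPSC-CF"), nReplicates = 3L,
        nbMeanLogMu = 5, nbMeanLogSd = 1.5, dispersion = 0.05,
        libSizeRange = c(0.5, 2), fracDeg = 0.1, lfcMagnitude = 2,
        panelGenes = cfActivationPanel(), panelOffset = 0.5,
        panelTreatmentLfc = 1, preactivatedSources = c("aHCF", "fHCF"),
        couplingRho = 0.8, proteinNoiseSd = 0.3,
        orphanFrac = 0.09, missingRate = 0,
        assocFrac = 0.25, nModule = 3L, moduleScore = 0.9,
        nBackgroundEdges = 400L, seed = 1L) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nProteins = as.integer(nProteins),
        sources = as.character(sources), nReplicates = as.integer(nReplicates),
        nbMeanLogMu = as.numeric(nbMeanLogMu), nbMeanLogSd = as.numeric(nbMeanLogSd),
        dispersion = as.numeric(dispersion),
        libSizeRange = as.numeric(libSizeRange), fracDeg = as.numeric(fracDeg),
        lfcMagnitude = as.numeric(lfcMagnitude),
        panelGenes = as.character(panelGenes), panelOffset = as.numeric(panelOffset),
        panelTreatmentLfc = as.numeric(panelTreatmentLfc),
        preactivatedSources = as.character(preactivatedSources),
        couplingRho = as.numeric(couplingRho), proteinNoiseSd = as.numeric(proteinNoiseSd),
        orphanFrac = as.numeric(orphanFrac), missingRate = as.numeric(missingRate),
        assocFrac = as.numeric(assocFrac), nModule = as.integer(nModule),
        moduleScore = as.numeric(moduleScore),
        nBackgroundEdges = as.integer(nBackgroundEdges), seed = as.integer(seed))
}

#' Planted ground truth of a synthetic study
#'
#' Records, per source, the planted differentially expressed genes and proteins
#' with their true log2 fold changes, the pre-activated sources, gene baseline
#' means, and the brute-force expected prioritized panel derived from the truth
#' plus the annotation tables at generation time (never by the pipeline under
#' test).
#'
#' @slot degSets named list (per source) of data.frames with columns
#'   \code{gene_id}, \code{lfc}.
#' @slot depSets named list (per source) of data.frames with columns
#'   \code{protein_id}, \code{gene_id}, \code{lfc}.
#' @slot preactivatedSources sources whose control samples carry the panel offset.
#' @slot panelGenes,panelOffset the marker panel and its quiescence offset.
#' @slot baselineMu named numeric of true gene baseline means.
#' @slot mapping data.frame \code{gene_id}, \code{protein_id}.
#' @slot expectedPanel character; brute-force expected prioritized-panel members.
#' @slot moduleGenes character; the planted network-module genes.
#' @export
setClass("GroundTruth",
    representation(degSets = "list", depSets = "list",
        preactivatedSources = "character", panelGenes = "character",
        panelOffset = "numeric", baselineMu = "numeric",
        mapping = "data.frame", expectedPanel = "character",
        moduleGenes = "character"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    for (s in names(object@degSets)) {
        d <- object@degSets[[s]]
        if (anyDuplicated(d$gene_id))
            msg <- c(msg, sprintf("duplicate planted genes for source %s", s))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth planted differential gene sets per source.
#' @param object a \code{GroundTruth}.
#' @export
setMethod("degSets", "GroundTruth", function(object) object@degSets)

#' @describeIn GroundTruth planted differential protein sets per source.
#' @export
setMethod("depSets", "GroundTruth", function(object) object@depSets)

#' @describeIn GroundTruth brute-force expected prioritized panel.
#' @export
setMethod("expectedPanel", "GroundTruth", function(object) object@expectedPanel)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@baselineMu), "genes;",
        nrow(object@mapping), "protein mappings\n")
    for (s in names(object@degSets))
        cat(sprintf("  %s: %d planted DEGs, %d planted DEPs\n", s,
            nrow(object@degSets[[s]]), nrow(object@depSets[[s]])))
    cat("  pre-activated:", paste(object@preactivatedSources, collapse = ", "), "\n")
    cat("  expected panel:", length(object@expectedPanel), "members\n")
})

#' Per-sample activation scores with group tests
#'
#' Result of the marker-panel summed z-score: per-gene z-scores of log
#' expression across all samples and their per-sample sum, plus (after
#' \code{\link{testScoreDifferences}}) the two-way ANOVA table and Tukey HSD
#' contrasts over the source x condition cells.
#'
#' @slot scores named numeric, one score per sample; sums to zero by
#'   construction.
#' @slot zMatrix genes x samples z-score matrix (dropped genes as zero rows).
#' @slot usedGenes,droppedGenes panel genes used / dropped (absent or
#'   zero-variance).
#' @slot design data.frame with sample_id, source, condition, replicate.
#' @slot anova two-way ANOVA table (factors, interaction) or empty before
#'   testing.
#' @slot tukey Tukey HSD contrasts over cell means, adjusted p-values.
#' @export
setClass("ActivationScores",
    representation(scores = "numeric", zMatrix = "matrix",
        usedGenes = "character", droppedGenes = "character",
        design = "data.frame", anova = "data.frame", tukey = "data.frame"))

setValidity("ActivationScores", function(object) {
    msg <- character()
    if (length(object@scores) != ncol(object@zMatrix))
        msg <- c(msg, "scores length must equal number of z-matrix columns")
    if (abs(sum(object@scores)) > 1e-6 * max(1, length(object@scores)))
        msg <- c(msg, "activation scores must sum to zero (z rows are centered)")
    if (length(msg)) msg else TRUE
})

#' @describeIn ActivationScores the per-sample summed z-scores.
#' @param object an \code{ActivationScores}.
#' @export
setMethod("activationScores", "ActivationScores", function(object) object@scores)

#' @describeIn ActivationScores the per-gene per-sample z matrix.
#' @export
setMethod("zMatrix", "ActivationScores", function(object) object@zMatrix)

#' @describeIn ActivationScores panel genes that entered the score.
#' @export
setMethod("usedGenes", "ActivationScores", function(object) object@usedGenes)

#' @describeIn ActivationScores panel genes dropped (absent or zero variance).
#' @export
setMethod("droppedGenes", "ActivationScores", function(object) object@droppedGenes)

#' @describeIn ActivationScores two-way ANOVA table (after testing).
#' @export
setMethod("anovaTable", "ActivationScores", function(object) object@anova)

#' @describeIn ActivationScores Tukey HSD contrasts (after testing).
#' @export
setMethod("tukeyTable", "ActivationScores", function(object) object@tukey)

setMethod("show", "ActivationScores", function(object) {
    cat("ActivationScores:", length(object@scores), "samples;",
        length(object@usedGenes), "panel genes used,",
        length(object@droppedGenes), "dropped\n")
    print(round(object@scores, 3))
    if (nrow(object@anova))
        cat("ANOVA computed; see anovaTable()/tukeyTable()\n")
})

#' Differential expression result for one source and omics layer
#'
#' Per-feature moderated-t statistics together with the layer-specific decision
#' rule: transcripts are called at raw p < 0.1 and |fold change| > 2, proteins
#' at BH FDR < 0.1 and |fold change| > 1.5 (defaults; configurable).
#'
#' @slot table data.frame with columns feature_id, mean_control, mean_treated,
#'   log2fc, signed_fc, p_value, fdr, call.
#' @slot layer "transcript" or "protein".
#' @slot source the contrasted cell source.
#' @slot priorDf moderation prior degrees of freedom.
#' @slot thresholds named numeric: sig (p or FDR cutoff) and fc (linear signed
#'   fold-change cutoff).
#' @export
setClass("DEResult",
    representation(table = "data.frame", layer = "character",
        source = "character", priorDf = "numeric", thresholds = "numeric"))

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("feature_id", "mean_control", "mean_treated", "log2fc",
        "signed_fc", "p_value", "fdr", "call")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, "table must carry the canonical result columns")
    if (!object@layer %in% c("transcript", "protein"))
        msg <- c(msg, "layer must be 'transcript' or 'protein'")
    if (length(msg)) msg else TRUE
})

#' @describeIn DEResult the per-feature result table.
#' @param object a \code{DEResult}.
#' @export
setMethod("deTable", "DEResult", function(object) object@table)

#' @describeIn DEResult feature ids called in a direction ("up"/"down").
#' @param direction which call class to extract.
#' @export
setMethod("deCalls", "DEResult", function(object, direction = c("up", "down")) {
    direction <- match.arg(direction)
    sort(object@table$feature_id[object@table$call == direction], method = "radix")
})

setMethod("show", "DEResult", function(object) {
    tab <- object@table
    cat(sprintf("DEResult [%s, %s]: %d features; %d up, %d down (sig < %g, |fc| > %g)\n",
        object@layer, object@source, nrow(tab),
        sum(tab$call == "up"), sum(tab$call == "down"),
        object@thresholds[["sig"]], object@thresholds[["fc"]]))
})

#' Static annotation resources for the prioritization cascade
#'
#' Bundles the gene-disease association scores, interaction-network edges with
#' combined confidence scores, cell-location assignments, drug availability
#' rows, term sets (GMT-style), and the upstream-regulator edge table.
#'
#' @slot gda data.frame gene_id, disease, score.
#' @slot network data.frame node_a, node_b, combined_score (undirected, no
#'   self-loops, no duplicates).
#' @slot locations data.frame feature_id, location.
#' @slot drugs data.frame gene_id, drug_name, status.
#' @slot terms named list of term-member character vectors; attribute "labels"
#'   carries display names.
#' @slot regulators data.frame regulator, target, sign (+1/-1).
#' @export
setClass("AnnotationBundle",
    representation(gda = "data.frame", network = "data.frame",
        locations = "data.frame", drugs = "data.frame", terms = "list",
        regulators = "data.frame"))

setValidity("AnnotationBundle", function(object) {
    msg <- character()
    net <- object@network
    if (nrow(net)) {
        if (any(net$node_a == net$node_b)) msg <- c(msg, "network contains self-loops")
        key <- paste(pmin(net$node_a, net$node_b), pmax(net$node_a, net$node_b))
        if (anyDuplicated(key)) msg <- c(msg, "network contains duplicate undirected edges")
        if (any(net$combined_score < 0 | net$combined_score > 1))
            msg <- c(msg, "combined scores must lie in [0, 1]")
    }
    if (nrow(object@gda) && any(object@gda$score <= 0 | object@gda$score > 1))
        msg <- c(msg, "GDA scores must lie in (0, 1]")
    reg <- object@regulators
    if (nrow(reg) && anyDuplicated(paste(reg$regulator, reg$target)))
        msg <- c(msg, "duplicate (regulator, target) rows")
    if (length(msg)) msg else TRUE
})

#' @describeIn AnnotationBundle gene-disease association table.
#' @param object an \code{AnnotationBundle}.
#' @export
setMethod("gdaTable", "AnnotationBundle", function(object) object@gda)

#' @describeIn AnnotationBundle interaction-network edge table.
#' @export
setMethod("networkEdges", "AnnotationBundle", function(object) object@network)

#' @describeIn AnnotationBundle cell-location table.
#' @export
setMethod("locationTable", "AnnotationBundle", function(object) object@locations)

#' @describeIn AnnotationBundle drug-availability table.
#' @export
setMethod("drugTable", "AnnotationBundle", function(object) object@drugs)

#' @describeIn AnnotationBundle named list of term-member sets.
#' @export
setMethod("termSets", "AnnotationBundle", function(object) object@terms)

#' @describeIn AnnotationBundle upstream-regulator edge table.
#' @export
setMethod("regulatorEdges", "AnnotationBundle", function(object) object@regulators)

setMethod("show", "AnnotationBundle", function(object) {
    cat("AnnotationBundle:\n")
    cat("  GDA rows:", nrow(object@gda),
        " network edges:", nrow(object@network),
        " locations:", nrow(object@locations), "\n")
    cat("  drug rows:", nrow(object@drugs),
        " term sets:", length(object@terms),
        " regulator edges:", nrow(object@regulators), "\n")
})

#' Ranked panel of prioritized fibrosis targets
#'
#' Output of the prioritization cascade: fibrosis-associated upregulated
#' proteins plus high-confidence network-added neighbours, ranked by breadth of
#' upregulation across sources, disease-association strength, connectivity to
#' associated members, and gene id (deterministic total order).
#'
#' @slot table data.frame with one row per member: gene_id, provenance
#'   ("disease-associated" or "network-added"), max_gda_score, diseases,
#'   partners, n_sources_up, sources_up, degree_assoc, drug_available, drugs,
#'   rank.
#' @export
setClass("PrioritizedPanel", representation(table = "data.frame"))

setValidity("PrioritizedPanel", function(object) {
    msg <- character()
    tab <- object@table
    if (nrow(tab)) {
        if (!all(tab$provenance %in% c("disease-associated", "network-added")))
            msg <- c(msg, "provenance must be disease-associated or network-added")
        bad <- tab$provenance == "network-added" & !nzchar(tab$partners)
        if (any(bad))
            msg <- c(msg, "network-added members must record at least one associated partner")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn PrioritizedPanel the ranked member table.
#' @param object a \code{PrioritizedPanel}.
#' @export
setMethod("panelTable", "PrioritizedPanel", function(object) object@table)

#' @describeIn PrioritizedPanel member gene ids in rank order.
#' @export
setMethod("panelMembers", "PrioritizedPanel", function(object) object@table$gene_id)

setMethod("show", "PrioritizedPanel", function(object) {
    tab <- object@table
    cat(sprintf("PrioritizedPanel: %d members (%d disease-associated, %d network-added, %d druggable)\n",
        nrow(tab), sum(tab$provenance == "disease-associated"),
        sum(tab$provenance == "network-added"), sum(tab$drug_available)))
    if (nrow(tab)) print(utils::head(tab[, c("rank", "gene_id", "provenance",
        "n_sources_up", "max_gda_score", "drug_available")], 10), row.names = FALSE)
})
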
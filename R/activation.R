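#' @include AllClasses.R
NULL

#' The 28-gene cardiac fibroblast activation marker panel
#'
#' Canonical myofibroblast and ECM-remodeling markers (alpha-smooth-muscle
#' actin, fibrillar collagens, integrins, matrix metalloproteinase machinery,
#' matricellular proteins) used by the activation score. Shipped as a
#' plain-text fixture under \code{extdata/panels/}.
#'
#' @return Character vector of 28 gene symbols.
#' @examples
#' cfActivationPanel()
#' @export
cfActivationPanel <- function() {
    readGenePanel(system.file("extdata", "panels", "cf_activation_28.txt",
        package = "fibroscore", mustWork = TRUE))
}

#' Read a gene panel file
#'
#' One gene symbol per line; blank lines and \code{#} comment lines ignored.
#'
#' @param path path to the panel file.
#' @return Character vector of gene symbols (non-empty, duplicates rejected).
#' @export
readGenePanel <- function(path) {
    lines <- trimws(readLines(path))
    genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(genes) == 0) stop("panel file contains no genes: ", path)
    if (anyDuplicated(genes))
        stop("duplicate panel genes: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    genes
}

.activationCore <- function(mat, design, panel, sizeFactors = NULL) {
    if (is.null(colnames(mat))) stop("matrix must have sample column names")
    if (ncol(mat) < 3)
        stop("at least 3 samples are required for z-score standardization")
    if (!is.null(sizeFactors)) {
        if (length(sizeFactors) != ncol(mat) || any(sizeFactors <= 0))
            stop("sizeFactors must be one positive value per sample")
        mat <- sweep(mat, 2, sizeFactors, "/")
    }
    present <- intersect(panel, rownames(mat))
    absent <- setdiff(panel, rownames(mat))
    if (length(absent))
        warning("panel genes absent from the matrix: ",
            paste(absent, collapse = ", "))
    if (length(present) == 0)
        stop("no panel gene present in the matrix")
    L <- log2(mat[present, , drop = FALSE] + 1)
    mu <- rowMeans(L)
    sdv <- apply(L, 1, stats::sd)   # sample sd, n - 1 denominator
    zero <- !is.finite(sdv) | sdv == 0
    z <- (L - mu) / ifelse(zero, 1, sdv)
    z[zero, ] <- 0
    used <- present[!zero]
    dropped <- c(absent, present[zero])
    if (length(used) == 0)
        stop("all panel genes have zero variance; activation score undefined")
    scores <- colSums(z[!zero, , drop = FALSE])
    new("ActivationScores", scores = scores, zMatrix = z,
        usedGenes = used, droppedGenes = dropped,
        design = if (is.null(design)) data.frame() else design,
        anova = data.frame(), tukey = data.frame())
}

#' Compute the cardiac fibroblast activation score
#'
#' For each sample, counts are (optionally size-factor) normalized, converted
#' to log2 with a pseudocount of 1, z-scored per gene across all samples
#' (sample standard deviation, n - 1), and the z-scores of the marker panel are
#' summed: \code{S_j = sum_g z_gj}. Higher scores indicate a more activated,
#' myofibroblast-like state. Zero-variance or absent panel genes are dropped
#' (recorded, contributing 0). Because every z row is centered, the scores sum
#' to zero over samples; only contrasts between samples are meaningful.
#'
#' @param object a counts \code{SummarizedExperiment} (design taken from
#'   \code{colData}) or a numeric genes x samples matrix.
#' @param panel character vector of marker genes (default: the bundled 28-gene
#'   panel).
#' @param sizeFactors optional positive per-sample normalization factors
#'   (e.g. from \code{\link{medianRatioSizeFactors}}); \code{NULL} uses raw
#'   counts.
#' @param design for the matrix method, an optional data.frame with columns
#'   sample_id, source, condition, replicate (needed later for group tests).
#' @param ... passed between methods.
#' @return An \linkS4class{ActivationScores}.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 60, nProteins = 30, seed = 2))
#' res <- computeActivationScores(sim$se)
#' activationScores(res)
#' @export
setMethod("computeActivationScores", "SummarizedExperiment",
    function(object, panel = cfActivationPanel(), sizeFactors = NULL, ...) {
        design <- as.data.frame(SummarizedExperiment::colData(object))
        .activationCore(SummarizedExperiment::assay(object), design, panel,
            sizeFactors)
    })

#' @rdname computeActivationScores
#' @export
setMethod("computeActivationScores", "matrix",
    function(object, panel = cfActivationPanel(), sizeFactors = NULL,
        design = NULL, ...) {
        .activationCore(object, design, panel, sizeFactors)
    })

#' Test activation-score differences across sources and conditions
#'
#' Fits a two-way fixed-effects ANOVA of the per-sample scores on source,
#' condition and their interaction, followed by Tukey HSD over the source x
#' condition cell means (all pairwise contrasts, family-wise adjusted
#' p-values). The control-vs-control contrasts compare basal (quiescent-state)
#' activation between sources.
#'
#' @param result an \linkS4class{ActivationScores} whose design records
#'   source, condition and replicate for every sample.
#' @return The \linkS4class{ActivationScores} with \code{anovaTable} and
#'   \code{tukeyTable} filled.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 60, nProteins = 30, seed = 2))
#' res <- testScoreDifferences(computeActivationScores(sim$se))
#' head(tukeyTable(res))
#' @importFrom stats aov TukeyHSD
#' @export
testScoreDifferences <- function(result) {
    stopifnot(is(result, "ActivationScores"))
    design <- result@design
    if (!all(c("source", "condition") %in% names(design)))
        stop("design must carry source and condition columns")
    if (length(unique(design$source)) < 2)
        stop("at least 2 sources are required")
    if (!setequal(unique(design$condition), c("control", "treated")))
        stop("both conditions (control, treated) are required")
    cells <- table(design$source, design$condition)
    if (any(cells < 2)) {
        bad <- which(cells < 2, arr.ind = TRUE)
        stop("cell with fewer than 2 replicates: ",
            paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
                sep = ":", collapse = ", "))
    }
    df <- data.frame(score = as.numeric(result@scores),
        source = factor(design$source),
        condition = factor(design$condition))
    fit <- aov(score ~ source * condition, data = df)
    an <- as.data.frame(summary(fit)[[1]])
    an$term <- trimws(rownames(an))
    names(an) <- c("df", "sum_sq", "mean_sq", "F", "p_value", "term")
    an <- an[, c("term", "df", "sum_sq", "mean_sq", "F", "p_value")]
    rownames(an) <- NULL
    df$cell <- interaction(df$source, df$condition, sep = ":")
    cellFit <- aov(score ~ cell, data = df)
    rss <- sum(stats::residuals(cellFit)^2)
    tss <- sum((df$score - mean(df$score))^2)
    if (rss <= 1e-12 * max(tss, 1))
        stop("zero within-group variance; Tukey p-values would be ",
            "degenerate rather than informative")
    tk <- TukeyHSD(cellFit)$cell
    tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
        lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
        row.names = NULL, stringsAsFactors = FALSE)
    if (all(is.nan(tukey$p_adj)))
        warning("within-cell variance is zero; Tukey p-values undefined (NaN)")
    result@anova <- an
    result@tukey <- tukey
    result
}
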
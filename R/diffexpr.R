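#' @include AllClasses.R
NULL

#' Median-of-ratios size factors
#'
#' The classic bulk RNA-seq normalization: for each sample, the size factor is
#' the median over reference genes (genes with strictly positive counts in all
#' samples) of the ratio between the sample's count and the gene's geometric
#' mean across samples.
#'
#' @param counts genes x samples numeric matrix of non-negative counts.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' medianRatioSizeFactors(m)   # 1/sqrt(2), sqrt(2)
#' @importFrom stats median
#' @export
medianRatioSizeFactors <- function(counts) {
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be finite and non-negative")
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
        stop("no gene has positive counts in all samples; ",
            "median-of-ratios undefined (consider a pseudo-reference fallback)")
    logc <- log(counts[ref, , drop = FALSE])
    logGeo <- rowMeans(logc)
    sf <- apply(logc, 2, function(x) exp(median(x - logGeo)))
    if (any(sf <= 0)) stop("non-positive size factor estimated")
    sf
}

#' Total-area normalization of protein intensities
#'
#' Scales each sample (column) so that its total intensity equals the mean
#' column sum of the input, the standard global normalization for DIA/SWATH
#' quantification matrices.
#'
#' @param intensities proteins x samples positive numeric matrix.
#' @return Matrix of the same shape with equal column sums.
#' @export
totalAreaNormalize <- function(intensities) {
    if (any(!is.finite(intensities)) || any(intensities <= 0))
        stop("intensities must be finite and strictly positive")
    cs <- colSums(intensities)
    if (any(cs == 0)) stop("zero-sum column: ",
        paste(colnames(intensities)[cs == 0], collapse = ", "))
    sweep(intensities, 2, mean(cs) / cs, "*")
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the step-up false-discovery-rate procedure;
#' rejects non-finite values or values outside [0, 1].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0) return(numeric())
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must be finite and lie in [0, 1]")
    p.adjust(p, method = "BH")
}

.signedFc <- function(lfc) ifelse(lfc >= 0, 2^lfc, -2^(-lfc))

.deCore <- function(mat, design, source, layer, sizeFactors, priorDf,
        sigThreshold, fcThreshold) {
    layer <- match.arg(layer, c("transcript", "protein"))
    if (!source %in% design$source)
        stop("unknown source: ", source)
    if (layer == "transcript") {
        sf <- if (is.null(sizeFactors)) medianRatioSizeFactors(mat) else sizeFactors
        if (length(sf) != ncol(mat) || any(sf <= 0))
            stop("sizeFactors must be one positive value per sample")
        norm <- sweep(mat, 2, sf, "/")
        logmat <- log2(norm + 1)
        defaults <- c(sig = 0.1, fc = 2)
    } else {
        norm <- totalAreaNormalize(mat)
        logmat <- log2(norm)
        defaults <- c(sig = 0.1, fc = 1.5)
    }
    sig <- if (is.null(sigThreshold)) defaults[["sig"]] else sigThreshold
    fcThr <- if (is.null(fcThreshold)) defaults[["fc"]] else fcThreshold
    sel <- design$source == source
    ctrl <- sel & design$condition == "control"
    trt <- sel & design$condition == "treated"
    n1 <- sum(ctrl); n2 <- sum(trt)
    if (n1 < 2 || n2 < 2)
        stop("at least 2 replicates per condition are required (got ",
            n1, " control, ", n2, " treated)")
    xc <- logmat[, ctrl, drop = FALSE]
    xt <- logmat[, trt, drop = FALSE]
    mC <- rowMeans(xc); mT <- rowMeans(xt)
    d <- n1 + n2 - 2
    s2 <- (rowSums((xc - mC)^2) + rowSums((xt - mT)^2)) / d
    if (all(s2 == 0))
        stop("zero within-group variance for every feature; test undefined")
    s2prior <- mean(s2)     # pooled prior variance
    s2mod <- (priorDf * s2prior + d * s2) / (priorDf + d)
    lfc <- mT - mC
    tstat <- lfc / sqrt(s2mod * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = priorDf + d)
    fdr <- bhAdjust(p)
    signedFc <- .signedFc(lfc)
    crit <- if (layer == "transcript") p < sig else fdr < sig
    call <- ifelse(crit & abs(signedFc) > fcThr,
        ifelse(lfc > 0, "up", "down"), "ns")
    tab <- data.frame(feature_id = rownames(mat),
        mean_control = rowMeans(norm[, ctrl, drop = FALSE]),
        mean_treated = rowMeans(norm[, trt, drop = FALSE]),
        log2fc = lfc, signed_fc = signedFc, p_value = p, fdr = fdr,
        call = call, row.names = NULL, stringsAsFactors = FALSE)
    new("DEResult", table = tab, layer = layer, source = source,
        priorDf = priorDf, thresholds = c(sig = sig, fc = fcThr))
}

#' Differential expression test for one source and omics layer
#'
#' Contrasts treated vs control samples of a single cell source on
#' log2-normalized values: transcripts as \code{log2(count/s_j + 1)} with
#' median-of-ratios size factors (computed on the full matrix unless
#' supplied), proteins as \code{log2} of total-area-normalized intensities.
#' The per-feature statistic is a moderated t with empirical-Bayes variance
#' moderation: the pooled prior variance is the mean of per-feature pooled
#' variances and is blended with \code{priorDf} prior degrees of freedom;
#' p-values come from the t distribution with \code{priorDf + n1 + n2 - 2}
#' degrees of freedom and BH FDR is computed over the layer's features.
#'
#' Decision rules (defaults, configurable): transcripts are called up/down at
#' raw p < 0.1 and |signed fold change| > 2; proteins at FDR < 0.1 and
#' |signed fold change| > 1.5. The signed linear fold change uses the
#' negative-reciprocal convention (\code{2^lfc} if lfc >= 0 else
#' \code{-2^-lfc}), so -2 means 2-fold down.
#'
#' @param object a \code{SummarizedExperiment} (design from colData) or a
#'   features x samples matrix.
#' @param source cell-source label to contrast.
#' @param layer "transcript" or "protein".
#' @param design for the matrix method, data.frame with sample_id, source,
#'   condition.
#' @param sizeFactors optional per-sample positive factors (transcript layer).
#' @param priorDf moderation prior degrees of freedom (default 4).
#' @param sigThreshold,fcThreshold override the layer's default decision rule.
#' @param ... passed between methods.
#' @return A \linkS4class{DEResult}.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 80, nProteins = 40, seed = 4))
#' res <- deTest(sim$se, source = "aHCF", layer = "transcript")
#' res
#' @export
setMethod("deTest", "SummarizedExperiment",
    function(object, source, layer = c("transcript", "protein"),
        sizeFactors = NULL, priorDf = 4, sigThreshold = NULL,
        fcThreshold = NULL, ...) {
        design <- as.data.frame(SummarizedExperiment::colData(object))
        .deCore(SummarizedExperiment::assay(object), design, source, layer,
            sizeFactors, priorDf, sigThreshold, fcThreshold)
    })

#' @rdname deTest
#' @export
setMethod("deTest", "matrix",
    function(object, source, layer = c("transcript", "protein"),
        design = NULL, sizeFactors = NULL, priorDf = 4, sigThreshold = NULL,
        fcThreshold = NULL, ...) {
        if (is.null(design)) stop("design is required for the matrix method")
        .deCore(object, design, source, layer, sizeFactors, priorDf,
            sigThreshold, fcThreshold)
    })
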
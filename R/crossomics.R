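#' @include AllClasses.R
NULL

#' Match proteome features to transcriptome features
#'
#' Pairs each protein with its transcript through the gene-protein mapping and
#' reports the coverage: the fraction of all proteins whose mapped gene is
#' present in the transcript universe.
#'
#' @param transcriptIds character; gene ids of the transcript universe.
#' @param proteinIds character; protein ids of the proteome.
#' @param mapping data.frame with columns \code{gene_id}, \code{protein_id}
#'   (unique per protein).
#' @return List with \code{pairs} (data.frame gene_id, protein_id) and
#'   \code{coverage} in [0, 1].
#' @export
matchFeatures <- function(transcriptIds, proteinIds, mapping) {
    stopifnot(all(c("gene_id", "protein_id") %in% names(mapping)))
    if (anyDuplicated(mapping$protein_id))
        stop("duplicate protein_id in mapping: ",
            paste(unique(mapping$protein_id[duplicated(mapping$protein_id)]),
                collapse = ", "))
    hit <- mapping$protein_id %in% proteinIds & mapping$gene_id %in% transcriptIds
    pairs <- mapping[hit, c("gene_id", "protein_id"), drop = FALSE]
    rownames(pairs) <- NULL
    coverage <- if (length(proteinIds) == 0) 0 else nrow(pairs) / length(proteinIds)
    list(pairs = pairs, coverage = coverage)
}

#' Correlate transcript and protein fold changes
#'
#' Pearson correlation of log2 fold changes over matched transcript-protein
#' pairs, optionally restricted to pairs whose protein was called
#' differentially expressed. With fewer than 3 pairs the correlation is
#' flagged undefined rather than returned as a silent NaN.
#'
#' @param deTranscript,deProtein \linkS4class{DEResult} objects for the same
#'   source.
#' @param map result of \code{\link{matchFeatures}}.
#' @param restrictToDep keep only pairs with protein call != "ns".
#' @return List with \code{r}, \code{n} and logical \code{defined}.
#' @importFrom stats cor
#' @export
fcCorrelation <- function(deTranscript, deProtein, map, restrictToDep = FALSE) {
    stopifnot(is(deTranscript, "DEResult"), is(deProtein, "DEResult"))
    tt <- deTranscript@table
    pt <- deProtein@table
    pairs <- map$pairs
    ti <- match(pairs$gene_id, tt$feature_id)
    pi <- match(pairs$protein_id, pt$feature_id)
    ok <- !is.na(ti) & !is.na(pi)
    ti <- ti[ok]; pi <- pi[ok]
    if (restrictToDep) {
        keep <- pt$call[pi] != "ns"
        ti <- ti[keep]; pi <- pi[keep]
    }
    n <- length(ti)
    if (n < 3) {
        warning("fewer than 3 pairs; correlation undefined")
        return(list(r = NA_real_, n = n, defined = FALSE))
    }
    list(r = cor(tt$log2fc[ti], pt$log2fc[pi]), n = n, defined = TRUE)
}

#' Cell-location prevalence of all features and of differential features
#'
#' Fraction of features per cellular location, computed for the full feature
#' set and for the differential subset; features absent from the location
#' table are bucketed as "other". Each fraction column sums to 1.
#'
#' @param features character; all feature ids (gene ids).
#' @param locationTable data.frame \code{feature_id}, \code{location}.
#' @param depFeatures character; the differential subset (optional).
#' @return data.frame with columns location, frac_all and (when
#'   \code{depFeatures} is given) frac_dep.
#' @export
locationPrevalence <- function(features, locationTable, depFeatures = NULL) {
    lookup <- function(ids) {
        loc <- locationTable$location[match(ids, locationTable$feature_id)]
        loc[is.na(loc) | !loc %in% .cellLocations] <- "other"
        factor(loc, levels = .cellLocations)
    }
    out <- data.frame(location = .cellLocations,
        frac_all = as.numeric(table(lookup(features)) / max(1, length(features))))
    if (!is.null(depFeatures))
        out$frac_dep <- as.numeric(table(lookup(depFeatures)) /
            max(1, length(depFeatures)))
    out
}

#' Sample-sample correlation and correlation-distance clustering
#'
#' Pairwise Pearson correlation of samples on the log2 values of a feature
#' subset, followed by agglomerative clustering with average linkage on the
#' distance 1 - PCC. Constant sample vectors yield undefined correlations;
#' these pairs are flagged and assigned maximal distance for the clustering.
#'
#' @param mat positive features x samples matrix (e.g. normalized
#'   intensities).
#' @param featureSubset feature ids to use (>= 2 required).
#' @param pseudocount added before log2 (0 for strictly positive data).
#' @return List with \code{sampleCorr} (samples x samples matrix),
#'   \code{hclust}, \code{newick} (dendrogram string) and \code{undefined}
#'   (character of sample pairs with undefined correlation).
#' @importFrom stats cor hclust as.dist
#' @export
sampleCorrelationClustering <- function(mat, featureSubset = rownames(mat),
        pseudocount = 0) {
    sub <- intersect(featureSubset, rownames(mat))
    if (length(sub) < 2)
        stop("at least 2 features are required for sample correlation")
    L <- log2(mat[sub, , drop = FALSE] + pseudocount)
    C <- suppressWarnings(cor(L))
    undef <- character()
    if (anyNA(C)) {
        idx <- which(is.na(C) & upper.tri(C), arr.ind = TRUE)
        undef <- paste(rownames(C)[idx[, 1]], colnames(C)[idx[, 2]], sep = "~")
        warning("undefined correlations (constant sample vectors): ",
            paste(undef, collapse = ", "))
        C[is.na(C)] <- 0
        diag(C) <- 1
    }
    hc <- hclust(as.dist(1 - C), method = "average")
    newick <- ape::write.tree(ape::as.phylo(hc))
    list(sampleCorr = C, hclust = hc, newick = newick, undefined = undef)
}

#' Principal component analysis of samples
#'
#' Column-centered (not scaled) SVD-based PCA of samples in feature space, the
#' standard first look at a normalized expression matrix.
#'
#' @param mat features x samples numeric matrix (e.g. log2 normalized counts).
#' @param rank number of components to report (default all).
#' @return List with \code{coordinates} (samples x components score matrix)
#'   and \code{explained} (per-component variance fractions, summing to 1
#'   over all components).
#' @importFrom stats prcomp
#' @export
pcaSamples <- function(mat, rank = NULL) {
    if (nrow(mat) < 2 || ncol(mat) < 2)
        stop("at least 2 features and 2 samples are required")
    pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    k <- if (is.null(rank)) ncol(pc$x) else min(rank, ncol(pc$x))
    list(coordinates = pc$x[, seq_len(k), drop = FALSE],
        explained = expl[seq_len(k)])
}
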
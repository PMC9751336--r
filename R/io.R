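#' @include AllClasses.R
NULL

## Fixed table dialect: TSV, UTF-8, '.' decimal separator, '#' comment lines.

.readTsv <- function(path, what = "table") {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
        quote = "")
    nf <- nf[!is.na(nf)]
    if (length(unique(nf)) > 1) {
        lines <- which(nf != nf[1])
        stop("ragged rows in ", path, " (line ",
            paste(utils::head(lines, 5), collapse = ", "), ")")
    }
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
        quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read an omics matrix from TSV
#'
#' First column: feature ids; remaining columns: one per sample. Counts are
#' validated as non-negative integers, intensities as strictly positive reals;
#' ragged rows, duplicate feature ids and violations are hard errors naming
#' the offender.
#'
#' @param path TSV path.
#' @param kind "counts" or "intensities".
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
readOmicsMatrix <- function(path, kind = c("counts", "intensities")) {
    kind <- match.arg(kind)
    df <- .readTsv(path, kind)
    if (ncol(df) < 2) stop("matrix file needs a feature column plus samples: ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate feature ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric values in ", path)
    rownames(mat) <- ids
    if (anyNA(mat)) stop("missing values in ", path)
    if (kind == "counts") {
        if (any(mat < 0) || any(mat != round(mat)))
            stop("counts must be non-negative integers in ", path)
        storage.mode(mat) <- "double"
    } else {
        if (any(mat <= 0))
            stop("intensities must be strictly positive in ", path)
    }
    mat
}

#' Write an omics matrix as TSV
#'
#' @param mat features x samples matrix with dimnames.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeOmicsMatrix <- function(mat, path) {
    df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
        stringsAsFactors = FALSE)
    writeTsv(df, path)
}

#' Read a sample sheet
#'
#' Requires columns sample_id, source, condition (control/treated), replicate;
#' duplicate sample ids and unknown conditions are hard errors.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- .readTsv(path, "sample sheet")
    need <- c("sample_id", "source", "condition", "replicate")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in ", path)
    bad <- setdiff(unique(df$condition), c("control", "treated"))
    if (length(bad))
        stop("unknown condition labels in ", path, ": ",
            paste(bad, collapse = ", "))
    df
}

#' Assemble a SummarizedExperiment from a matrix and sample sheet
#'
#' Columns are reordered to the sample-sheet order; samples missing from
#' either side are hard errors.
#'
#' @param mat features x samples matrix.
#' @param sampleSheet data.frame from \code{\link{readSampleSheet}}.
#' @param kind assay name, "counts" or "intensities".
#' @return A \code{SummarizedExperiment}.
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @export
asOmicsExperiment <- function(mat, sampleSheet, kind = c("counts", "intensities")) {
    kind <- match.arg(kind)
    miss <- setdiff(sampleSheet$sample_id, colnames(mat))
    if (length(miss))
        stop("samples in sheet but not matrix: ", paste(miss, collapse = ", "))
    extra <- setdiff(colnames(mat), sampleSheet$sample_id)
    if (length(extra))
        stop("samples in matrix but not sheet: ", paste(extra, collapse = ", "))
    mat <- mat[, sampleSheet$sample_id, drop = FALSE]
    assays <- list(mat)
    names(assays) <- kind
    SummarizedExperiment(assays = assays,
        colData = DataFrame(sampleSheet, row.names = sampleSheet$sample_id))
}

#' Read a gene-disease association table
#'
#' @param path TSV with columns gene_id, disease, score.
#' @return data.frame; scores validated in (0, 1].
#' @export
readGdaTable <- function(path) {
    df <- .readTsv(path, "GDA")
    need <- c("gene_id", "disease", "score")
    if (!all(need %in% names(df)))
        stop("GDA table lacks columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
    if (any(!is.finite(df$score) | df$score <= 0 | df$score > 1))
        stop("GDA scores must lie in (0, 1] in ", path)
    if (anyDuplicated(paste(df$gene_id, df$disease)))
        stop("duplicate (gene, disease) rows in ", path)
    df
}

#' Read an interaction-network edge table
#'
#' @param path TSV with columns node_a, node_b, combined_score.
#' @return data.frame; undirected, self-loops and duplicate edges rejected,
#'   scores validated in [0, 1].
#' @export
readNetworkTable <- function(path) {
    df <- .readTsv(path, "network")
    need <- c("node_a", "node_b", "combined_score")
    if (!all(need %in% names(df)))
        stop("network table lacks columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
    if (any(df$node_a == df$node_b)) stop("self-loops in ", path)
    key <- paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b))
    if (anyDuplicated(key)) stop("duplicate undirected edges in ", path)
    if (any(!is.finite(df$combined_score) | df$combined_score < 0 |
            df$combined_score > 1))
        stop("combined scores must lie in [0, 1] in ", path)
    df
}

#' Read a cell-location table
#'
#' @param path TSV with columns feature_id, location.
#' @return data.frame.
#' @export
readLocationTable <- function(path) {
    df <- .readTsv(path, "location")
    if (!all(c("feature_id", "location") %in% names(df)))
        stop("location table needs feature_id and location columns")
    if (anyDuplicated(df$feature_id))
        stop("duplicate feature ids in ", path)
    df
}

#' Read a drug-availability table
#'
#' @param path TSV with columns gene_id, drug_name, status.
#' @return data.frame.
#' @export
readDrugTable <- function(path) {
    df <- .readTsv(path, "drug")
    if (!all(c("gene_id", "drug_name", "status") %in% names(df)))
        stop("drug table needs gene_id, drug_name and status columns")
    df
}

#' Read a gene-protein id mapping
#'
#' @param path TSV with columns gene_id, protein_id.
#' @return data.frame; duplicate protein ids rejected.
#' @export
readMappingTable <- function(path) {
    df <- .readTsv(path, "mapping")
    if (!all(c("gene_id", "protein_id") %in% names(df)))
        stop("mapping table needs gene_id and protein_id columns")
    if (anyDuplicated(df$protein_id))
        stop("duplicate protein ids in ", path)
    df
}

#' Read an upstream-regulator edge table
#'
#' @param path TSV with columns regulator, target, sign.
#' @return data.frame with sign coerced to integer +1/-1.
#' @export
readRegulatorTable <- function(path) {
    df <- .readTsv(path, "regulator")
    if (!all(c("regulator", "target", "sign") %in% names(df)))
        stop("regulator table needs regulator, target and sign columns")
    df$sign <- as.integer(df$sign)
    if (!all(df$sign %in% c(-1L, 1L)))
        stop("regulator signs must be +1 or -1 in ", path)
    df
}

#' Read term sets in GMT format
#'
#' Tab-separated: term id, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of member vectors with a "labels" attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad))
        stop("GMT lines with fewer than 3 fields: line ",
            paste(utils::head(bad, 5), collapse = ", "))
    ids <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
    terms <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(terms) <- ids
    labels <- vapply(parts, `[[`, character(1), 2)
    names(labels) <- ids
    attr(terms, "labels") <- labels
    terms
}

#' Write term sets in GMT format
#'
#' @param terms named list of member vectors (optional "labels" attribute).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGmt <- function(terms, path) {
    labels <- attr(terms, "labels")
    lines <- vapply(names(terms), function(id) {
        lab <- if (!is.null(labels) && id %in% names(labels))
            labels[[id]] else id
        paste(c(id, lab, terms[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
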
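#' @include AllClasses.R
NULL

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric over-representation test of a query gene set
#' against term sets within a universe, with optional EASE correction (the
#' observed overlap is decremented by one, floored at zero, before the tail
#' probability is taken), BH FDR over the reported terms, and deterministic
#' ranking by p-value with ties broken by term id.
#'
#' @param query character; the gene set of interest (must be a subset of
#'   \code{universe}).
#' @param universe character; the background gene universe.
#' @param termSets named list of term-member character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param minOverlap terms with observed overlap below this are excluded
#'   (default 0: report all).
#' @param ease use the EASE-adjusted overlap.
#' @return data.frame with term_id, label, overlap, term_size, p_value, fdr,
#'   ranked by p then term id.
#' @examples
#' enrichTerms(c("a", "b"), letters[1:10], list(T1 = c("a", "b", "c")))
#' @importFrom stats phyper
#' @export
enrichTerms <- function(query, universe, termSets, minOverlap = 0,
        ease = FALSE) {
    bad <- setdiff(query, universe)
    if (length(bad))
        stop("query genes outside the universe: ", paste(bad, collapse = ", "))
    universe <- unique(universe)
    query <- unique(query)
    N <- length(universe)
    n <- length(query)
    labels <- attr(termSets, "labels")
    rows <- lapply(names(termSets), function(id) {
        members <- intersect(termSets[[id]], universe)
        K <- length(members)
        k <- length(intersect(members, query))
        if (K == 0 || k < minOverlap) return(NULL)
        kk <- if (ease) max(k - 1, 0) else k
        p <- if (kk == 0) 1 else phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id,
            label = if (!is.null(labels) && id %in% names(labels))
                labels[[id]] else id,
            overlap = k, term_size = K, p_value = p,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term_id = character(), label = character(),
            overlap = integer(), term_size = integer(), p_value = numeric(),
            fdr = numeric()))
    out$fdr <- bhAdjust(out$p_value)
    out <- out[order(out$p_value, out$term_id, method = "radix"), ]
    rownames(out) <- NULL
    out
}

#' Upstream-regulator activation calls by sign consistency
#'
#' For each regulator with signed target edges (+1 activating, -1 repressing),
#' counts its differentially expressed targets whose observed fold-change sign
#' is consistent with the edge sign (N+) versus inconsistent (N-) and forms
#' the sign-consistency statistic \code{z = (N+ - N-) / sqrt(N+ + N-)}. A
#' regulator is called "activated" when z exceeds the threshold strictly and
#' "inhibited" below its negative; regulators without differential targets are
#' "untestable". An overlap gate (one-sided Fisher/hypergeometric p of the
#' target-DEG overlap within the tested universe) suppresses calls for
#' regulators whose targets are not unusually enriched among the DEGs; set
#' \code{maxOverlapP = 1} to disable the gate.
#'
#' @param de a \linkS4class{DEResult} for the transcript layer.
#' @param edges data.frame with columns regulator, target, sign (+1/-1); no
#'   duplicate (regulator, target) rows.
#' @param zThreshold activation threshold (default 3, strict inequality).
#' @param maxOverlapP overlap-p gate (default 0.1, i.e. -log10 p > 1).
#' @return data.frame with regulator, n_targets, n_deg_targets, n_consistent,
#'   z, overlap_p, call.
#' @importFrom stats phyper
#' @export
regulatorActivation <- function(de, edges, zThreshold = 3, maxOverlapP = 0.1) {
    stopifnot(is(de, "DEResult"))
    stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
    if (anyDuplicated(paste(edges$regulator, edges$target)))
        stop("duplicate (regulator, target) rows")
    if (!all(edges$sign %in% c(-1, 1)))
        stop("edge signs must be +1 or -1")
    tab <- de@table
    universe <- tab$feature_id
    degIdx <- tab$call != "ns"
    nUniv <- length(universe)
    nDeg <- sum(degIdx)
    lfcSign <- sign(tab$log2fc)
    names(lfcSign) <- tab$feature_id
    isDeg <- structure(degIdx, names = tab$feature_id)
    regs <- sort(unique(edges$regulator), method = "radix")
    rows <- lapply(regs, function(r) {
        e <- edges[edges$regulator == r & edges$target %in% universe, ]
        nT <- nrow(e)
        hit <- e[isDeg[e$target], , drop = FALSE]
        N <- nrow(hit)
        if (N == 0)
            return(data.frame(regulator = r, n_targets = nT,
                n_deg_targets = 0L, n_consistent = 0L, z = NA_real_,
                overlap_p = NA_real_, call = "untestable",
                stringsAsFactors = FALSE))
        nPlus <- sum(hit$sign * lfcSign[hit$target] > 0)
        z <- (nPlus - (N - nPlus)) / sqrt(N)
        overlapP <- phyper(N - 1, nDeg, nUniv - nDeg, nT, lower.tail = FALSE)
        call <- "none"
        if (overlapP < maxOverlapP) {
            if (z > zThreshold) call <- "activated"
            else if (z < -zThreshold) call <- "inhibited"
        }
        data.frame(regulator = r, n_targets = nT, n_deg_targets = N,
            n_consistent = nPlus, z = z, overlap_p = overlapP, call = call,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
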
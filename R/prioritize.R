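#' @include AllClasses.R
NULL

#' Cross-source intersection regions of differential feature sets
#'
#' Computes every disjoint membership region of the k-way Venn comparison of
#' per-source up- or down-regulated feature sets (all 2^k - 1 regions; region
#' sizes sum to the union size).
#'
#' @param deBySource named list of \linkS4class{DEResult} objects (or plain
#'   character sets) per source.
#' @param direction "up" or "down".
#' @return List with \code{sets} (per-source feature sets) and \code{regions}
#'   (named list keyed like "aHCF" or "aHCF&fHCF").
#' @importFrom utils combn
#' @export
intersectSources <- function(deBySource, direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (length(deBySource) < 2) stop("at least 2 sources are required")
    sets <- lapply(deBySource, function(x) {
        if (is(x, "DEResult")) deCalls(x, direction)
        else sort(unique(as.character(x)), method = "radix")
    })
    srcs <- names(sets)
    regions <- list()
    for (k in seq_along(srcs)) {
        for (combo in as.data.frame(combn(srcs, k), stringsAsFactors = FALSE)) {
            inAll <- Reduce(intersect, sets[combo])
            others <- setdiff(srcs, combo)
            onlyThese <- setdiff(inAll, unlist(sets[others], use.names = FALSE))
            regions[[paste(combo, collapse = "&")]] <-
                sort(onlyThese, method = "radix")
        }
    }
    list(sets = sets, regions = regions)
}

#' Filter features for fibrosis disease association
#'
#' Keeps genes with at least one association row for pulmonary, cardiac,
#' hepatic or renal fibrosis above a minimum score; any positive association
#' counts by default, mirroring the curation practice of keeping low-score
#' literature associations.
#'
#' @param genes character; candidate genes (e.g. upregulated differential
#'   proteins).
#' @param gda data.frame gene_id, disease, score.
#' @param minScore strict lower bound on the association score (default 0).
#' @param diseases the disease whitelist.
#' @return List with \code{genes} (sorted qualifying genes) and \code{detail}
#'   (all qualifying rows).
#' @export
filterDiseaseAssociated <- function(genes, gda, minScore = 0,
        diseases = .fibrosisDiseases) {
    stopifnot(all(c("gene_id", "disease", "score") %in% names(gda)))
    rows <- gda[gda$gene_id %in% genes & gda$disease %in% diseases &
        gda$score > minScore, , drop = FALSE]
    rows <- rows[order(rows$gene_id, rows$disease, method = "radix"), ]
    rownames(rows) <- NULL
    list(genes = sort(unique(rows$gene_id), method = "radix"), detail = rows)
}

#' One-hop high-confidence network expansion
#'
#' Adds candidates that share at least one interaction edge of combined score
#' >= \code{minScore} with a seed member (the high-confidence cutoff 0.7 is
#' inclusive). Genes outside the candidate set are never added and candidates
#' without a qualifying edge stay excluded, mirroring "hide disconnected
#' nodes". Expansion is exactly one hop.
#'
#' @param seedSet character; e.g. the disease-associated genes.
#' @param candidateSet character; the admissible additions (e.g. all
#'   upregulated differential proteins).
#' @param network data.frame node_a, node_b, combined_score in [0, 1].
#' @param minScore inclusive confidence threshold (default 0.7).
#' @return data.frame with gene_id, partners (";"-joined seed partners) and
#'   n_partners, one row per added gene.
#' @export
expandNetwork <- function(seedSet, candidateSet, network, minScore = 0.7) {
    stopifnot(all(c("node_a", "node_b", "combined_score") %in% names(network)))
    if (minScore < 0 || minScore > 1) stop("minScore must lie in [0, 1]")
    hi <- network[network$combined_score >= minScore, , drop = FALSE]
    pool <- setdiff(candidateSet, seedSet)
    rows <- lapply(sort(pool, method = "radix"), function(g) {
        partners <- sort(unique(c(
            hi$node_b[hi$node_a == g & hi$node_b %in% seedSet],
            hi$node_a[hi$node_b == g & hi$node_a %in% seedSet])),
            method = "radix")
        if (length(partners) == 0) return(NULL)
        data.frame(gene_id = g, partners = paste(partners, collapse = ";"),
            n_partners = length(partners), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_id = character(), partners = character(),
            n_partners = integer())
    rownames(out) <- NULL
    out
}

#' Annotate panel members with drug availability
#'
#' @param members character; panel gene ids.
#' @param drugTable data.frame gene_id, drug_name, status.
#' @return data.frame gene_id, drug_available, drugs (";"-joined
#'   "name (status)" entries; empty when unavailable).
#' @export
annotateDrugs <- function(members, drugTable) {
    stopifnot(all(c("gene_id", "drug_name", "status") %in% names(drugTable)))
    rows <- lapply(members, function(g) {
        d <- drugTable[drugTable$gene_id == g, , drop = FALSE]
        d <- d[order(d$drug_name, method = "radix"), , drop = FALSE]
        data.frame(gene_id = g, drug_available = nrow(d) > 0,
            drugs = paste(sprintf("%s (%s)", d$drug_name, d$status),
                collapse = ";"),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_id = character(), drug_available = logical(),
            drugs = character())
    rownames(out) <- NULL
    out
}

#' Assemble the ranked prioritized target panel
#'
#' Combines disease-associated upregulated proteins with their
#' network-added neighbours into a single ranked panel. The deterministic rank
#' key is: number of sources where upregulated (descending), maximum
#' gene-disease association score (descending), high-confidence degree to
#' associated members (descending), gene id (lexical).
#'
#' @param associated result of \code{\link{filterDiseaseAssociated}}.
#' @param added result of \code{\link{expandNetwork}}.
#' @param deBySource named list of protein-layer \linkS4class{DEResult}
#'   objects (or per-source character vectors of upregulated gene ids).
#' @param drugTable data.frame gene_id, drug_name, status.
#' @param network interaction edge table (for the degree component of the
#'   rank key; optional).
#' @param minScore high-confidence cutoff used for the degree (default 0.7).
#' @param geneOfProtein optional named character mapping protein ids to gene
#'   ids, applied to DE calls before counting sources.
#' @return A \linkS4class{PrioritizedPanel}.
#' @export
buildPanel <- function(associated, added, deBySource, drugTable,
        network = NULL, minScore = 0.7, geneOfProtein = NULL) {
    upSets <- lapply(deBySource, function(x) {
        ids <- if (is(x, "DEResult")) deCalls(x, "up")
            else sort(unique(as.character(x)), method = "radix")
        if (!is.null(geneOfProtein)) {
            ids <- geneOfProtein[ids]
            ids <- sort(unique(ids[!is.na(ids)]), method = "radix")
        }
        ids
    })
    members <- c(associated$genes, setdiff(added$gene_id, associated$genes))
    provenance <- c(rep("disease-associated", length(associated$genes)),
        rep("network-added", length(setdiff(added$gene_id, associated$genes))))
    if (length(members) == 0)
        return(new("PrioritizedPanel", table = data.frame(
            gene_id = character(), provenance = character(),
            max_gda_score = numeric(), diseases = character(),
            partners = character(), n_sources_up = integer(),
            sources_up = character(), degree_assoc = integer(),
            drug_available = logical(), drugs = character(),
            rank = integer())))
    detail <- associated$detail
    maxGda <- vapply(members, function(g) {
        s <- detail$score[detail$gene_id == g]
        if (length(s)) max(s) else 0
    }, numeric(1))
    diseases <- vapply(members, function(g) {
        d <- sort(unique(detail$disease[detail$gene_id == g]), method = "radix")
        paste(d, collapse = ";")
    }, character(1))
    partners <- vapply(members, function(g) {
        i <- match(g, added$gene_id)
        if (is.na(i)) "" else added$partners[i]
    }, character(1))
    upIn <- lapply(members, function(g)
        names(upSets)[vapply(upSets, function(s) g %in% s, logical(1))])
    nUp <- lengths(upIn)
    degree <- if (is.null(network)) integer(length(members)) else {
        hi <- network[network$combined_score >= minScore, , drop = FALSE]
        vapply(members, function(g) {
            length(unique(c(
                hi$node_b[hi$node_a == g & hi$node_b %in% associated$genes],
                hi$node_a[hi$node_b == g & hi$node_a %in% associated$genes])))
        }, integer(1))
    }
    drugs <- annotateDrugs(members, drugTable)
    tab <- data.frame(gene_id = members, provenance = provenance,
        max_gda_score = maxGda, diseases = diseases, partners = partners,
        n_sources_up = as.integer(nUp),
        sources_up = vapply(upIn, paste, character(1), collapse = ";"),
        degree_assoc = degree, drug_available = drugs$drug_available,
        drugs = drugs$drugs, row.names = NULL, stringsAsFactors = FALSE)
    o <- order(-tab$n_sources_up, -tab$max_gda_score, -tab$degree_assoc,
        tab$gene_id, method = "radix")
    tab <- tab[o, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    new("PrioritizedPanel", table = tab)
}
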
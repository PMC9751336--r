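## Independent brute-force oracles. Deliberately written from first
## principles with plain loops, sharing no code with the implementation.

# summed z-score of log2(counts + 1), gene by gene
bruteZSum <- function(counts, sizeFactors = NULL) {
    if (!is.null(sizeFactors))
        for (j in seq_len(ncol(counts))) counts[, j] <- counts[, j] / sizeFactors[j]
    L <- log2(counts + 1)
    S <- numeric(ncol(L))
    for (g in seq_len(nrow(L))) {
        m <- mean(L[g, ])
        s <- sqrt(sum((L[g, ] - m)^2) / (ncol(L) - 1))
        if (s > 0) S <- S + (L[g, ] - m) / s
    }
    unname(S)
}

# BH step-up from the definition: adj_i = min over ranks j >= rank(i) of m p_(j)/j
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        r <- which(o == i)
        vals <- numeric(0)
        for (j in r:m) vals <- c(vals, m * p[o[j]] / j)
        adj[i] <- min(c(vals, 1))
    }
    adj
}

# exact hypergeometric upper tail P(X >= k) by term-by-term enumeration
bruteHyperTail <- function(k, termSize, universeSize, querySize) {
    if (k <= 0) return(1)
    tot <- 0
    for (i in k:min(termSize, querySize)) {
        tot <- tot + choose(termSize, i) *
            choose(universeSize - termSize, querySize - i) /
            choose(universeSize, querySize)
    }
    tot
}

# exhaustive one-hop expansion scan over every edge row
bruteExpand <- function(seedSet, candidateSet, edges, minScore) {
    added <- character()
    for (g in setdiff(candidateSet, seedSet)) {
        for (i in seq_len(nrow(edges))) {
            if (edges$combined_score[i] < minScore) next
            a <- edges$node_a[i]; b <- edges$node_b[i]
            if ((a == g && b %in% seedSet) || (b == g && a %in% seedSet)) {
                added <- c(added, g)
                break
            }
        }
    }
    sort(added)
}

# median-of-ratios from the definition, ratio by ratio
bruteSizeFactors <- function(counts) {
    ref <- which(apply(counts, 1, function(x) all(x > 0)))
    geo <- apply(counts[ref, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
    out <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts)))
        out[j] <- median(counts[ref, j] / geo)
    out
}

# minimal DEResult for unit tests of downstream consumers
makeDE <- function(ids, lfc, call, layer = "protein", source = "aHCF",
        p = rep(0.5, length(ids)), fdr = p) {
    tab <- data.frame(feature_id = ids, mean_control = 1, mean_treated = 1,
        log2fc = lfc, signed_fc = ifelse(lfc >= 0, 2^lfc, -2^(-lfc)),
        p_value = p, fdr = fdr, call = call, stringsAsFactors = FALSE)
    new("DEResult", table = tab, layer = layer, source = source,
        priorDf = 4, thresholds = c(sig = 0.1, fc = 1.5))
}

# single-source config used by the DE calibration checks: expression regime
# with baseline means >= 100 and dispersion 0.05
deCalibrationConfig <- function(seed, fracDeg = 0) {
    simulationConfig(nGenes = 2000L, nProteins = 10L, sources = "aHCF",
        preactivatedSources = character(), nReplicates = 3L,
        nbMeanLogMu = log(500), nbMeanLogSd = 0.3, dispersion = 0.05,
        fracDeg = fracDeg, lfcMagnitude = 2, panelTreatmentLfc = 0,
        panelOffset = 0, seed = seed)
}

# compact design for score-recovery power runs: only the quiescence offset
# is planted
offsetConfig <- function(seed, delta) {
    simulationConfig(nGenes = 60L, nProteins = 10L, fracDeg = 0,
        panelTreatmentLfc = 0, panelOffset = delta,
        preactivatedSources = "aHCF", seed = seed)
}

randomCountsMatrix <- function(nGenes = 28, nSamples = 18) {
    matrix(rpois(nGenes * nSamples, lambda = 50) +
            sample(0:5, nGenes * nSamples, replace = TRUE),
        nrow = nGenes,
        dimnames = list(paste0("g", seq_len(nGenes)),
            paste0("s", seq_len(nSamples))))
}
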
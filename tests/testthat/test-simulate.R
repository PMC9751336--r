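test_that("identical config and seed reproduce every output exactly", {
    cfg <- simulationConfig(nGenes = 80L, nProteins = 50L, seed = 42L)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(SummarizedExperiment::assay(s1$transcripts),
        SummarizedExperiment::assay(s2$transcripts))
    expect_identical(SummarizedExperiment::assay(s1$proteins),
        SummarizedExperiment::assay(s2$proteins))
    expect_identical(gdaTable(s1$annotations), gdaTable(s2$annotations))
    expect_identical(networkEdges(s1$annotations), networkEdges(s2$annotations))
    expect_identical(degSets(s1$truth), degSets(s2$truth))
    expect_identical(expectedPanel(s1$truth), expectedPanel(s2$truth))
})

test_that("design shape and labels follow sources x conditions x replicates", {
    cfg <- simulationConfig(nGenes = 40L, nProteins = 20L,
        sources = c("A", "B"), preactivatedSources = "A",
        nReplicates = 4L, seed = 1L)
    sim <- simulateCounts(cfg)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
    expect_equal(nrow(cd), 2 * 2 * 4)
    expect_setequal(unique(cd$source), c("A", "B"))
    expect_setequal(unique(cd$condition), c("control", "treated"))
    expect_equal(unname(table(cd$source, cd$condition)["A", "control"]), 4)
    expect_true(all(SummarizedExperiment::assay(sim$se) >= 0))
    expect_true(all(SummarizedExperiment::assay(sim$se) ==
        round(SummarizedExperiment::assay(sim$se))))
})

test_that("no planted effects leave every truth set empty", {
    cfg <- simulationConfig(nGenes = 50L, nProteins = 20L, fracDeg = 0,
        panelTreatmentLfc = 0, seed = 9L)
    sim <- simulateCounts(cfg)
    expect_true(all(vapply(degSets(sim$truth), nrow, integer(1)) == 0L))
})

test_that("planted truth is internally consistent", {
    cfg <- simulationConfig(nGenes = 200L, nProteins = 100L, seed = 7L)
    sim <- simulateCounts(cfg)
    panel <- cfg@panelGenes
    for (src in names(degSets(sim$truth))) {
        ds <- degSets(sim$truth)[[src]]
        expect_true(all(ds$gene_id %in% names(sim$truth@baselineMu)))
        expect_false(anyDuplicated(ds$gene_id) > 0)
        nonPanel <- ds[!ds$gene_id %in% panel, ]
        expect_true(all(abs(nonPanel$lfc) == cfg@lfcMagnitude))
        expect_true(all(ds$lfc[ds$gene_id %in% panel] == cfg@panelTreatmentLfc))
    }
})

test_that("negative-binomial moments match mu and mu + alpha mu^2", {
    # 10,000 draws of genes with mu = 100, alpha = 0.05, no library variation
    cfg <- simulationConfig(nGenes = 30L, nProteins = 10L, sources = "A",
        preactivatedSources = character(), nReplicates = 5000L,
        nbMeanLogMu = log(100), nbMeanLogSd = 0, dispersion = 0.05,
        libSizeRange = c(1, 1), fracDeg = 0, panelTreatmentLfc = 0,
        panelOffset = 0, seed = 11L)
    sim <- simulateCounts(cfg)
    x <- SummarizedExperiment::assay(sim$se)["SYNG0001", ]
    n <- length(x)
    expect_equal(n, 10000L)
    trueVar <- 100 + 0.05 * 100^2   # 600
    se <- sqrt(trueVar / n)
    expect_lt(abs(mean(x) - 100), 3 * se)
    expect_lt(abs(var(x) - trueVar) / trueVar, 0.15)
})

test_that("config validation rejects degenerate designs", {
    expect_error(simulationConfig(nReplicates = 1L), "nReplicates")
    expect_error(simulationConfig(nGenes = 10L, nProteins = 5L), "panel")
    expect_error(simulationConfig(nGenes = 50L, nProteins = 80L), "nProteins")
    expect_error(simulationConfig(dispersion = -1), "dispersion")
    expect_error(simulationConfig(couplingRho = 1.5), "couplingRho")
})

test_that("perfect coupling with zero noise copies transcript fold changes", {
    cfg <- simulationConfig(nGenes = 120L, nProteins = 120L, couplingRho = 1,
        proteinNoiseSd = 0, orphanFrac = 0, seed = 13L)
    sim <- simulateCounts(cfg)
    pr <- simulateProteome(cfg, sim$truth)
    for (src in names(degSets(pr$truth))) {
        dep <- depSets(pr$truth)[[src]]
        deg <- degSets(pr$truth)[[src]]
        tl <- deg$lfc[match(dep$gene_id, deg$gene_id)]
        expect_equal(dep$lfc, tl)
    }
    expect_true(all(SummarizedExperiment::assay(pr$se) > 0))
})

test_that("zero coupling decorrelates planted protein fold changes", {
    cfg <- simulationConfig(nGenes = 3000L, nProteins = 3000L,
        sources = "A", preactivatedSources = character(),
        couplingRho = 0, orphanFrac = 0, fracDeg = 0.4,
        panelTreatmentLfc = 0, seed = 17L)
    sim <- simulateCounts(cfg)
    pr <- simulateProteome(cfg, sim$truth)
    dep <- depSets(pr$truth)[["A"]]
    deg <- degSets(pr$truth)[["A"]]
    tl <- deg$lfc[match(dep$gene_id, deg$gene_id)]
    expect_gt(nrow(dep), 1000)
    expect_lt(abs(cor(tl, dep$lfc)), 0.07)
})

test_that("annotation tables have the promised structure", {
    study <- simulateStudy(simulationConfig(nGenes = 300L, nProteins = 200L,
        seed = 19L))
    ann <- study$annotations
    gda <- gdaTable(ann)
    expect_true(all(gda$score > 0 & gda$score <= 1))
    net <- networkEdges(ann)
    expect_true(all(net$node_a != net$node_b))
    expect_true(all(net$combined_score >= 0 & net$combined_score <= 1))
    loc <- locationTable(ann)
    expect_false(anyDuplicated(loc$feature_id) > 0)
    frac <- table(loc$location) / nrow(loc)
    expect_equal(sum(frac), 1)
    reg <- regulatorEdges(ann)
    expect_true(all(reg$sign %in% c(-1L, 1L)))
})

test_that("background edges stay below the cutoff so the planted module is the expansion", {
    study <- simulateStudy(simulationConfig(nGenes = 300L, nProteins = 200L,
        seed = 23L))
    net <- networkEdges(study$annotations)
    module <- net[net$combined_score >= 0.7, ]
    expect_true(all(module$combined_score == 0.9))
    truth <- study$truth
    candidates <- sort(unique(unlist(lapply(depSets(truth),
        function(d) d$gene_id[d$lfc > 0]))))
    gda <- gdaTable(study$annotations)
    fibrosis <- c("pulmonary fibrosis", "cardiac fibrosis",
        "hepatic fibrosis", "renal fibrosis")
    associated <- sort(unique(gda$gene_id[gda$gene_id %in% candidates &
        gda$disease %in% fibrosis]))
    added <- bruteExpand(associated, candidates, net, 0.7)
    expect_identical(expectedPanel(truth), sort(unique(c(associated, added))))
})
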
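test_that("median-of-ratios reproduces the exact two-sample case", {
    m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    expect_equal(unname(medianRatioSizeFactors(m)),
        c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    same <- cbind(a = c(5, 9, 2), b = c(5, 9, 2), c = c(5, 9, 2))
    expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))
})

test_that("median-of-ratios matches brute force and the scaling property", {
    set.seed(501)
    for (i in 1:20) {
        m <- randomCountsMatrix(15, 6) + 1
        expect_equal(unname(medianRatioSizeFactors(m)), bruteSizeFactors(m),
            tolerance = 1e-12)
        cfac <- 3
        m2 <- m
        m2[, 2] <- m2[, 2] * cfac
        sf <- medianRatioSizeFactors(m)
        sf2 <- medianRatioSizeFactors(m2)
        shift <- cfac^(1 / ncol(m))   # geometric-mean shift of the reference
        expect_equal(sf2[2], cfac * sf[2] / shift, tolerance = 1e-12,
            ignore_attr = TRUE)
        expect_equal(unname(sf2[-2]), unname(sf[-2] / shift), tolerance = 1e-12)
    }
})

test_that("median-of-ratios agrees with the reference estimator", {
    set.seed(502)
    m <- randomCountsMatrix(200, 8) + 1
    expect_equal(unname(medianRatioSizeFactors(m)),
        unname(DESeq2::estimateSizeFactorsForMatrix(m)), tolerance = 1e-8)
})

test_that("median-of-ratios rejects matrices without an all-positive gene", {
    m <- rbind(c(0, 5), c(5, 0))
    expect_error(medianRatioSizeFactors(m), "pseudo-reference")
})

test_that("total-area normalization equalizes column sums", {
    m <- cbind(a = c(2, 8), b = c(10, 20))   # sums 10 and 30
    out <- totalAreaNormalize(m)
    expect_equal(unname(colSums(out)), c(20, 20))
    eq <- cbind(a = c(3, 7), b = c(6, 4))
    expect_equal(totalAreaNormalize(eq), eq)
    set.seed(503)
    r <- matrix(rlnorm(60, 2, 1), nrow = 10)
    cs <- colSums(totalAreaNormalize(r))
    expect_lt(max(abs(cs - mean(cs))), 1e-9)
    expect_error(totalAreaNormalize(cbind(a = c(1, 1), b = c(0, 0))),
        "positive")
})

test_that("BH adjustment matches the hand-worked and degenerate cases", {
    expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.05)),
        c(0.04, 0.05, 0.05, 0.05))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up on random vectors", {
    set.seed(504)
    for (i in 1:200) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    }
})

test_that("calls are consistent with each layer's decision rule", {
    study <- simulateStudy(simulationConfig(nGenes = 300L, nProteins = 200L,
        seed = 41L))
    deT <- deTest(study$transcripts, "hiPSC-CF", "transcript")
    tt <- deTable(deT)
    sig <- tt$p_value < 0.1 & abs(tt$signed_fc) > 2
    expect_identical(tt$call != "ns", sig)
    expect_identical(tt$call == "up", sig & tt$log2fc > 0)
    expect_gt(sum(tt$call == "up"), 0)
    expect_gt(sum(tt$call == "down"), 0)
    deP <- deTest(study$proteins, "hiPSC-CF", "protein")
    pt <- deTable(deP)
    sigP <- pt$fdr < 0.1 & abs(pt$signed_fc) > 1.5
    expect_identical(pt$call != "ns", sigP)
    # a protein can clear FDR yet fail the fold-change condition
    expect_true(all(pt$call[pt$fdr < 0.1 & abs(pt$signed_fc) <= 1.5] == "ns"))
})

test_that("signed fold change uses the negative-reciprocal convention", {
    expect_equal(fibroscore:::.signedFc(c(0, 1, -1, log2(2.5))),
        c(1, 2, -2, 2.5))
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
    sim <- simulateCounts(simulationConfig(nGenes = 120L, nProteins = 10L,
        seed = 43L))
    m <- SummarizedExperiment::assay(sim$se)
    design <- as.data.frame(SummarizedExperiment::colData(sim$se))
    de1 <- deTest(m, source = "aHCF", layer = "transcript", design = design)
    flipped <- design
    flipped$condition <- ifelse(design$condition == "control", "treated",
        "control")
    de2 <- deTest(m, source = "aHCF", layer = "transcript", design = flipped)
    expect_equal(deTable(de2)$log2fc, -deTable(de1)$log2fc, tolerance = 1e-12)
    expect_equal(deTable(de2)$p_value, deTable(de1)$p_value, tolerance = 1e-12)
})

test_that("rescaling one sample's raw counts barely moves transcript p-values", {
    # size factors absorb the rescaling up to the pseudocount; protein
    # total-area normalization absorbs it exactly
    sim <- simulateCounts(deCalibrationConfig(45L))
    m <- SummarizedExperiment::assay(sim$se)
    design <- as.data.frame(SummarizedExperiment::colData(sim$se))
    de1 <- deTest(m, source = "aHCF", layer = "transcript", design = design)
    m2 <- m
    m2[, 3] <- m2[, 3] * 4
    de2 <- deTest(m2, source = "aHCF", layer = "transcript", design = design)
    expect_lt(max(abs(deTable(de2)$p_value - deTable(de1)$p_value)), 1e-3)

    pr <- simulateProteome(simulationConfig(nGenes = 100L, nProteins = 80L,
        seed = 46L), simulateCounts(simulationConfig(nGenes = 100L,
        nProteins = 80L, seed = 46L))$truth)
    pm <- SummarizedExperiment::assay(pr$se)
    dp1 <- deTest(pm, source = "aHCF", layer = "protein", design = design)
    pm2 <- pm
    pm2[, 5] <- pm2[, 5] * 7
    dp2 <- deTest(pm2, source = "aHCF", layer = "protein", design = design)
    expect_equal(deTable(dp2)$p_value, deTable(dp1)$p_value, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
    m <- randomCountsMatrix(10, 4)
    design <- data.frame(sample_id = colnames(m), source = "aHCF",
        condition = c("control", "treated", "treated", "treated"),
        replicate = c(1, 1, 2, 3))
    expect_error(deTest(m, source = "aHCF", layer = "transcript",
        design = design), "2 replicates")
    expect_error(deTest(m, source = "ghost", layer = "transcript",
        design = design), "unknown source")
    flat <- matrix(5, nrow = 3, ncol = 6,
        dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
    d6 <- data.frame(sample_id = colnames(flat), source = "aHCF",
        condition = rep(c("control", "treated"), each = 3),
        replicate = rep(1:3, 2))
    expect_error(deTest(flat, source = "aHCF", layer = "transcript",
        design = d6), "variance")
})
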
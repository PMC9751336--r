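test_that("feature matching computes coverage over all proteins", {
    mapping <- data.frame(gene_id = paste0("g", 1:10),
        protein_id = paste0("p", 1:10))
    m <- matchFeatures(paste0("g", 1:9), paste0("p", 1:10), mapping)
    expect_equal(m$coverage, 0.9)
    expect_equal(nrow(m$pairs), 9)
    full <- matchFeatures(paste0("g", 1:10), paste0("p", 1:10), mapping)
    expect_equal(full$coverage, 1)
    none <- matchFeatures(character(), paste0("p", 1:10),
        mapping[0, , drop = FALSE])
    expect_equal(none$coverage, 0)
    expect_equal(nrow(none$pairs), 0)
    dup <- rbind(mapping, mapping[1, ])
    expect_error(matchFeatures(paste0("g", 1:10), paste0("p", 1:10), dup),
        "duplicate")
})

test_that("fold-change correlation matches hand-computed values", {
    map <- list(pairs = data.frame(gene_id = c("g1", "g2", "g3"),
        protein_id = c("p1", "p2", "p3")))
    deT <- makeDE(c("g1", "g2", "g3"), c(1, 2, 3), rep("ns", 3),
        layer = "transcript")
    deP <- makeDE(c("p1", "p2", "p3"), c(1, 2, 3), rep("ns", 3))
    expect_equal(fcCorrelation(deT, deP, map)$r, 1)
    deT2 <- makeDE(c("g1", "g2", "g3"), c(0, 1, 2), rep("ns", 3),
        layer = "transcript")
    deP2 <- makeDE(c("p1", "p2", "p3"), c(0, 2, 1), rep("ns", 3))
    expect_equal(fcCorrelation(deT2, deP2, map)$r, 0.5, tolerance = 1e-12)
    # closed-form check
    x <- c(0, 1, 2); y <- c(0, 2, 1)
    rManual <- (sum(x * y) - 3 * mean(x) * mean(y)) /
        sqrt((sum(x^2) - 3 * mean(x)^2) * (sum(y^2) - 3 * mean(y)^2))
    expect_equal(fcCorrelation(deT2, deP2, map)$r, rManual, tolerance = 1e-12)
})

test_that("DEP restriction and the undefined-pair guard behave", {
    map <- list(pairs = data.frame(gene_id = paste0("g", 1:5),
        protein_id = paste0("p", 1:5)))
    deT <- makeDE(paste0("g", 1:5), 1:5, rep("ns", 5), layer = "transcript")
    deP <- makeDE(paste0("p", 1:5), c(1, 2, 3, 4, 5),
        c("up", "up", "up", "ns", "ns"))
    res <- fcCorrelation(deT, deP, map, restrictToDep = TRUE)
    expect_equal(res$n, 3)
    expect_true(res$defined)
    deP2 <- makeDE(paste0("p", 1:5), 1:5, c("up", "up", rep("ns", 3)))
    expect_warning(res2 <- fcCorrelation(deT, deP2, map, restrictToDep = TRUE),
        "undefined")
    expect_false(res2$defined)
    expect_true(is.na(res2$r))
})

test_that("location prevalence partitions to one", {
    loc <- data.frame(feature_id = c("a", "b", "c", "d"),
        location = c("extracellular space", "cytoplasm", "nucleus",
            "cytoplasm"))
    out <- locationPrevalence(c("a", "b", "c", "d"), loc)
    expect_equal(sum(out$frac_all), 1)
    expect_equal(out$frac_all[out$location == "extracellular space"], 0.25)
    both <- locationPrevalence(c("a", "b", "c", "d", "zz"), loc,
        depFeatures = c("a", "b"))
    expect_equal(sum(both$frac_all), 1)
    expect_equal(sum(both$frac_dep), 1)
    # unknown features fall into "other"
    expect_equal(both$frac_all[both$location == "other"], 0.2)
    one <- locationPrevalence(c("b", "d"), loc)
    expect_equal(one$frac_all[one$location == "cytoplasm"], 1)
})

test_that("duplicated samples correlate perfectly and merge first", {
    set.seed(601)
    m <- matrix(rlnorm(40, 5, 1), nrow = 10,
        dimnames = list(paste0("f", 1:10), c("a", "b", "c", "d")))
    m[, "b"] <- m[, "a"]
    cl <- sampleCorrelationClustering(m)
    expect_equal(cl$sampleCorr["a", "b"], 1)
    expect_true(isSymmetric(cl$sampleCorr))
    expect_equal(unname(diag(cl$sampleCorr)), rep(1, 4))
    first <- cl$hclust$merge[1, ]
    expect_setequal(cl$hclust$labels[-first], c("a", "b"))
    # PSD up to numerical tolerance
    expect_gt(min(eigen(cl$sampleCorr, symmetric = TRUE)$values), -1e-10)
})

test_that("clustering topology is invariant to sample order", {
    set.seed(602)
    m <- matrix(rlnorm(60, 5, 1), nrow = 10,
        dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
    cl1 <- sampleCorrelationClustering(m)
    perm <- sample(6)
    cl2 <- sampleCorrelationClustering(m[, perm])
    co1 <- as.matrix(stats::cophenetic(cl1$hclust))
    co2 <- as.matrix(stats::cophenetic(cl2$hclust))
    expect_equal(co2[rownames(co1), colnames(co1)], co1, tolerance = 1e-12)
})

test_that("constant sample vectors are flagged, and tiny subsets rejected", {
    m <- matrix(rlnorm(30, 5, 1), nrow = 10,
        dimnames = list(paste0("f", 1:10), c("a", "b", "c")))
    m[, "c"] <- 1
    expect_warning(cl <- sampleCorrelationClustering(m), "constant")
    expect_true(length(cl$undefined) > 0)
    expect_error(sampleCorrelationClustering(m, featureSubset = "f1"),
        "2 features")
})

test_that("newick export reproduces the tree", {
    set.seed(603)
    m <- matrix(rlnorm(50, 5, 1), nrow = 10,
        dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
    cl <- sampleCorrelationClustering(m)
    tree <- ape::read.tree(text = cl$newick)
    expect_setequal(tree$tip.label, colnames(m))
})

test_that("PCA recovers exact low-rank structure", {
    # samples on an exact line in feature space
    line <- outer(c(1, 2, 3), c(0, 1, 2, 3)) +
        matrix(5, nrow = 3, ncol = 4)
    dimnames(line) <- list(paste0("f", 1:3), paste0("s", 1:4))
    pc <- pcaSamples(line)
    expect_equal(pc$explained[1], 1, tolerance = 1e-12)
    dup <- cbind(line, s5 = line[, 4])
    pc2 <- pcaSamples(dup)
    expect_equal(pc2$coordinates["s5", ], pc2$coordinates["s4", ],
        tolerance = 1e-9)
    # 2x2 closed form: centered SVD scores
    m <- matrix(c(1, 3, 5, 7), nrow = 2,
        dimnames = list(c("f1", "f2"), c("s1", "s2")))
    pc3 <- pcaSamples(m)
    sv <- svd(scale(t(m), center = TRUE, scale = FALSE))
    expect_equal(abs(unname(pc3$coordinates[, 1])), abs(sv$u[, 1] * sv$d[1]),
        tolerance = 1e-12)
    expect_error(pcaSamples(m[1, , drop = FALSE]), "2 features")
})
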
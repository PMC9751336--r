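test_that("Venn regions partition the union", {
    sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = "g3")
    v <- intersectSources(sets, "up")
    expect_equal(v$regions[["A&B&C"]], "g3")
    expect_equal(v$regions[["A"]], "g1")
    expect_equal(v$regions[["A&B"]], "g2")
    expect_equal(v$regions[["B"]], character(0))
    disjoint <- intersectSources(list(A = "x", B = "y"), "up")
    expect_equal(disjoint$regions[["A&B"]], character(0))
    same <- intersectSources(list(A = c("x", "y"), B = c("x", "y")), "up")
    expect_equal(same$regions[["A&B"]], c("x", "y"))
    expect_equal(same$regions[["A"]], character(0))
    expect_error(intersectSources(sets, "sideways"), "arg")
    expect_error(intersectSources(sets["A"], "up"), "2 sources")
})

test_that("Venn region sizes sum to the union size on random triples", {
    set.seed(801)
    for (i in 1:200) {
        pool <- paste0("g", 1:30)
        sets <- list(A = sample(pool, sample(0:20, 1)),
            B = sample(pool, sample(0:20, 1)),
            C = sample(pool, sample(0:20, 1)))
        v <- intersectSources(sets, "up")
        expect_equal(sum(lengths(v$regions)),
            length(unique(unlist(sets))))
        expect_false(anyDuplicated(unlist(v$regions)) > 0)
    }
})

test_that("disease filter honors the whitelist and score bound", {
    gda <- data.frame(gene_id = c("a", "a", "b", "c"),
        disease = c("cardiac fibrosis", "pulmonary fibrosis",
            "dilated cardiomyopathy", "renal fibrosis"),
        score = c(0.3, 0.01, 0.9, 0.4))
    expect_equal(filterDiseaseAssociated(character(), gda)$genes, character(0))
    out <- filterDiseaseAssociated(c("a", "b", "c"), gda)
    expect_setequal(out$genes, c("a", "c"))   # b only has a non-fibrosis row
    strict <- filterDiseaseAssociated(c("a", "b", "c", "d", "e"), gda,
        minScore = 0.05)
    expect_equal(nrow(strict$detail[strict$detail$gene_id == "a", ]), 1)
    # 5 candidates, 2 with fibrosis rows at 0.3 and 0.01, min 0.05 -> 1 kept
    gda2 <- data.frame(gene_id = c("d1", "d2"),
        disease = c("hepatic fibrosis", "hepatic fibrosis"),
        score = c(0.3, 0.01))
    out2 <- filterDiseaseAssociated(paste0("d", 1:5), gda2, minScore = 0.05)
    expect_equal(out2$genes, "d1")
})

test_that("network expansion honors threshold, candidates and hop limit", {
    edges <- data.frame(node_a = c("C", "D", "E"), node_b = c("A", "B", "F"),
        combined_score = c(0.9, 0.6, 0.95))
    out <- expandNetwork(c("A", "B"), c("C", "D", "E"), edges)
    expect_equal(out$gene_id, "C")
    expect_equal(out$partners, "A")
    # strict boundary: 0.69 misses an inclusive 0.7 cutoff
    near <- data.frame(node_a = "X", node_b = "A", combined_score = 0.69)
    expect_equal(nrow(expandNetwork("A", "X", near)), 0)
    at <- data.frame(node_a = "X", node_b = "A", combined_score = 0.7)
    expect_equal(expandNetwork("A", "X", at)$gene_id, "X")
    expect_equal(nrow(expandNetwork("A", "X", edges[0, ])), 0)
})

test_that("expansion equals the exhaustive scan and shrinks with the threshold", {
    set.seed(802)
    for (i in 1:15) {
        nodes <- paste0("n", 1:60)
        ne <- 150
        a <- sample(nodes, ne, replace = TRUE)
        b <- sample(nodes, ne, replace = TRUE)
        keep <- a != b & !duplicated(paste(pmin(a, b), pmax(a, b)))
        edges <- data.frame(node_a = a[keep], node_b = b[keep],
            combined_score = round(runif(sum(keep)), 3))
        seeds <- sample(nodes, 8)
        cands <- sample(nodes, 25)
        prev <- NULL
        for (thr in c(0.3, 0.5, 0.7, 0.9)) {
            got <- expandNetwork(seeds, cands, edges, thr)$gene_id
            expect_identical(got, bruteExpand(seeds, cands, edges, thr))
            if (!is.null(prev)) expect_true(all(got %in% prev))
            prev <- got
        }
        expect_equal(nrow(expandNetwork(seeds, cands, edges, 1)), 0)
    }
})

test_that("drug annotation joins availability per member", {
    drugs <- data.frame(gene_id = c("a", "a", "b"),
        drug_name = c("d1", "d2", "d3"),
        status = c("approved", "investigational", "approved"))
    out <- annotateDrugs(c("a", "b", "c"), drugs)
    expect_identical(out$drug_available, c(TRUE, TRUE, FALSE))
    expect_match(out$drugs[1], "d1 \\(approved\\);d2 \\(investigational\\)")
    none <- annotateDrugs(c("x", "y"), drugs[0, ])
    expect_false(any(none$drug_available))
    members33 <- paste0("m", sprintf("%02d", 1:33))
    nine <- data.frame(gene_id = members33[1:9],
        drug_name = paste0("drug", 1:9), status = "approved")
    expect_equal(sum(annotateDrugs(members33, nine)$drug_available), 9)
})

test_that("panel ranking follows the deterministic key", {
    associated <- list(genes = c("a", "b"),
        detail = data.frame(gene_id = c("a", "b"),
            disease = "cardiac fibrosis", score = c(0.5, 0.9)))
    added <- data.frame(gene_id = "c", partners = "a", n_partners = 1L)
    ups <- list(s1 = c("a", "b", "c"), s2 = c("a", "c"), s3 = "a")
    drugs <- data.frame(gene_id = "b", drug_name = "d", status = "approved")
    panel <- buildPanel(associated, added, ups, drugs)
    tab <- panelTable(panel)
    expect_identical(tab$gene_id, c("a", "c", "b"))   # 3 > 2 > 1 sources
    expect_identical(tab$provenance,
        c("disease-associated", "network-added", "disease-associated"))
    expect_identical(tab$rank, 1:3)
    # tie on sources resolved by GDA score, then lexical
    ups2 <- list(s1 = c("a", "b"))
    tab2 <- panelTable(buildPanel(associated, added[0, ], ups2, drugs))
    expect_identical(tab2$gene_id, c("b", "a"))   # 0.9 > 0.5
    assoc3 <- list(genes = c("x", "y"), detail = data.frame(
        gene_id = c("x", "y"), disease = "renal fibrosis", score = 0.4))
    tab3 <- panelTable(buildPanel(assoc3, added[0, ],
        list(s1 = c("x", "y")), drugs))
    expect_identical(tab3$gene_id, c("x", "y"))   # full tie: lexical
})

test_that("panel assembly is invariant to input order", {
    set.seed(803)
    associated <- list(genes = c("a", "b", "d"),
        detail = data.frame(gene_id = c("a", "b", "d"),
            disease = "hepatic fibrosis", score = c(0.2, 0.6, 0.4)))
    added <- data.frame(gene_id = c("e", "c"), partners = c("a", "b"),
        n_partners = 1L)
    ups <- list(s1 = c("a", "c", "e"), s2 = c("b", "d"))
    drugs <- data.frame(gene_id = c("d", "a"), drug_name = c("z", "w"),
        status = "approved")
    t1 <- panelTable(buildPanel(associated, added, ups, drugs))
    assocR <- list(genes = rev(associated$genes),
        detail = associated$detail[3:1, ])
    t2 <- panelTable(buildPanel(assocR, added[2:1, ], rev(ups),
        drugs[2:1, ]))
    rownames(t2) <- NULL
    expect_equal(t1, t2)
    # idempotence: rebuilding from the same inputs reproduces the table
    expect_equal(panelTable(buildPanel(associated, added, ups, drugs)), t1)
})

test_that("network-added members always record an associated partner", {
    study <- simulateStudy(simulationConfig(nGenes = 300L, nProteins = 200L,
        seed = 49L))
    truth <- study$truth
    ups <- lapply(depSets(truth), function(d)
        unique(d$gene_id[d$lfc > 0]))
    candidates <- sort(unique(unlist(ups)))
    associated <- filterDiseaseAssociated(candidates,
        gdaTable(study$annotations))
    added <- expandNetwork(associated$genes, candidates,
        networkEdges(study$annotations))
    panel <- buildPanel(associated, added, ups,
        drugTable(study$annotations),
        network = networkEdges(study$annotations))
    tab <- panelTable(panel)
    na <- tab[tab$provenance == "network-added", ]
    expect_true(all(nzchar(na$partners)))
    expect_setequal(tab$gene_id, expectedPanel(truth))
})
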
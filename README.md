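# fibroscore

Activation scoring and multi-omics target prioritization for cardiac
fibroblasts.

Cardiac fibrosis — excessive extracellular-matrix deposition that stiffens
the heart — is driven by the conversion of quiescent cardiac fibroblasts
(CF) into activated myofibroblasts. `fibroscore` is an R/Bioconductor-style
package for analyzing this transition from paired bulk transcriptome
(read-count) and proteome (DIA/SWATH intensity) matrices across several CF
sources (e.g. adult primary, fetal primary, hiPSC-derived), each profiled in
control vs TGF-β-treated conditions with replicates. It is aimed at
computational biologists comparing CF cell models and shortlisting
anti-fibrotic targets.

## What it computes

* **CF activation score** — for a 28-gene marker panel (bundled;
  `cfActivationPanel()`), per-sample sums of per-gene z-scores of log2
  (optionally size-factor-normalized) counts:
  S_j = Σ_{g∈panel} (L_gj − mean_g L) / sd_g L, with two-way ANOVA
  (source × condition) and Tukey HSD over the six cell means. The
  control-vs-control contrasts quantify basal quiescence differences between
  cell sources.
* **Differential expression** per source and omics layer: median-of-ratios
  size factors (transcripts) or total-area normalization (proteins), a
  moderated t with a pooled-prior empirical-Bayes variance (prior df 4), and
  the layer-specific decision rules: transcripts p < 0.1 & |FC| > 2;
  proteins FDR < 0.1 & |FC| > 1.5.
* **Cross-omics integration**: transcript–protein fold-change Pearson
  correlation (all pairs vs differential proteins only), cell-location
  prevalence, correlation-distance (1 − PCC, average linkage) clustering of
  samples on ECM/membrane differential proteins with Newick export, PCA.
* **Annotation**: hypergeometric term enrichment (GMT input, optional EASE
  variant) and upstream-regulator calls by the sign-consistency statistic
  z = (N⁺ − N⁻)/√N with the strict |z| > 3 rule and an overlap-p gate.
* **Target prioritization**: fibrosis disease-association filtering of
  upregulated differential proteins, one-hop network expansion at combined
  score ≥ 0.7, drug-availability annotation, cross-source Venn regions, and
  a deterministically ranked target panel.
* **Synthetic studies**: a seeded generator (`simulateStudy()`) emulating
  the 3-source × 2-condition × 3-replicate design with negative-binomial
  counts, coupled log-normal protein intensities, annotation tables, and a
  full planted-truth ledger, so the whole pipeline runs and is testable
  offline.

See `vignettes/fibroscore-methods.Rmd` for the model, parameter choices and
known limitations.

## Worked example

```r
library(fibroscore)

study <- simulateStudy(simulationConfig(nGenes = 300, nProteins = 180, seed = 7))
act <- testScoreDifferences(computeActivationScores(study$transcripts,
    sizeFactors = medianRatioSizeFactors(SummarizedExperiment::assay(study$transcripts))))
act
#> ActivationScores: 18 samples; 28 panel genes used, 0 dropped
#>     aHCF_control_1     aHCF_control_2     aHCF_control_3     aHCF_treated_1
#>             -7.459            -13.166            -11.972             16.926
#>     ...
#> hiPSC-CF_control_1 hiPSC-CF_control_2 hiPSC-CF_control_3 hiPSC-CF_treated_1
#>            -30.772            -37.096            -34.541             13.596
```

Treated samples score high, controls low, and the hiPSC-derived controls are
the most quiescent (most negative) — the basal contrast the score exists to
measure. Tukey confirms it:

```r
subset(tukeyTable(act), contrast == "hiPSC-CF:control-aHCF:control")
#>                       contrast      diff       p_adj
#>  hiPSC-CF:control-aHCF:control -23.27105 3.41831e-06
```

Differential proteins and the prioritization cascade:

```r
de <- deTest(study$proteins, source = "hiPSC-CF", layer = "protein")
de
#> DEResult [protein, hiPSC-CF]: 180 features; 15 up, 18 down (sig < 0.1, |fc| > 1.5)

ups   <- lapply(study$truth@depSets, function(d) unique(d$gene_id[d$lfc > 0]))
cand  <- sort(unique(unlist(ups)))
assoc <- filterDiseaseAssociated(cand, gdaTable(study$annotations))
added <- expandNetwork(assoc$genes, cand, networkEdges(study$annotations))
buildPanel(assoc, added, ups, drugTable(study$annotations),
           network = networkEdges(study$annotations))
#> PrioritizedPanel: 12 members (9 disease-associated, 3 network-added, 5 druggable)
#>  rank  gene_id         provenance n_sources_up max_gda_score drug_available
#>     1     CTGF disease-associated            3         0.881          FALSE
#>     2    ITGA1 disease-associated            2         0.386          FALSE
#>     3 SYNG0195 disease-associated            1         0.897          FALSE
#>     ...
```

Members upregulated in all three sources outrank the rest; genes with no
disease-association row but a high-confidence interaction to an associated
member enter as `network-added`. `runPipeline(pipelineConfig(...))` chains
all stages over TSV inputs and writes every artifact (scores, DE tables,
correlation report, dendrogram, Venn regions, ranked panel, manifest) to an
output directory; `inst/scripts/fibroscore.R` wraps the same functions as
shell subcommands (`simulate`, `score`, `de`, `prioritize`, `run`).

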
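---
title: "Methods: activation scoring and target prioritization for cardiac fibroblasts"
author: "fibroscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation scoring and target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscore)
```

# Scope and model

Cardiac fibroblasts (CF) convert from a quiescent to an activated,
myofibroblast-like state under TGF-beta stimulation; persistent activation
drives cardiac fibrosis. `fibroscore` implements a desk-scale analysis of this
transition over paired bulk transcriptome (count) and proteome (DIA/SWATH
intensity) matrices from several CF sources, each measured under control and
treated conditions with replicates. The stages are:

1. a marker-panel **activation score** per sample with two-way ANOVA/Tukey
   group testing,
2. per-source **differential expression** on both omics layers under
   layer-specific decision rules,
3. **cross-omics integration** (transcript-protein fold-change correlation,
   cell-location prevalence, correlation-distance clustering, PCA),
4. **annotation** (hypergeometric term enrichment; sign-consistency
   upstream-regulator calls), and
5. a **target-prioritization cascade** (fibrosis disease-association filter,
   one-hop high-confidence network expansion, drug annotation, ranked panel).

A seeded synthetic-data generator with a complete planted-truth ledger makes
every stage testable without any external download.

# The activation score

For counts $c_{gj}$ (gene $g$, sample $j$) and optional size factors $s_j$,
the score uses $L_{gj} = \log_2(c_{gj}/s_j + 1)$, per-gene z-scores across
*all* samples $z_{gj} = (L_{gj} - \bar L_g)/\mathrm{sd}_g$ (sample standard
deviation, $n-1$), and the per-sample sum over the marker panel
$S_j = \sum_{g \in \text{panel}} z_{gj}$. The bundled panel holds 28 canonical
CF-activation markers (ACTA2, collagens, integrins, MMP/TIMP machinery,
matricellular proteins; `cfActivationPanel()`).

Choices that the score definition leaves open, fixed here:

* **Log base 2, pseudocount 1.** The base is absorbed by z-scoring except
  through the pseudocount; base 2 matches fold-change conventions.
* **Global standardization.** z-scores are computed jointly over all sources
  and both conditions, because scores are compared across sources on one
  axis; per-source standardization would erase exactly the basal-activation
  contrast of interest.
* **Sample standard deviation ($n-1$).** Fixed for reproducibility.
* **Zero-variance or absent panel genes** are dropped, recorded, and
  contribute 0; the score proceeds on the intersection with a warning.
* **Size factors** are optional: raw counts are accepted, and the pipeline
  default feeds median-of-ratios factors computed on the full matrix.

Because each z row is centered, $\sum_j S_j = 0$: scores are relative within
the analyzed sample set, and only contrasts are interpretable. Group testing
fits `score ~ source * condition` (fixed effects) and runs Tukey HSD over the
source x condition cell means; the control-vs-control contrasts compare basal
quiescence between sources. Exactly zero within-cell variance makes the Tukey
p-values degenerate, so that case is rejected with an error rather than
reported as `p = 0`.

# Differential expression

Transcripts are normalized by **median-of-ratios** size factors
($s_j = \mathrm{median}_g\, c_{gj}/(\prod_k c_{gk})^{1/m}$ over genes positive
in all samples) and tested on $\log_2(c/s_j + 1)$; proteins are normalized by
**total area** (each column scaled to the mean column sum) and tested on
$\log_2$ intensities. Per feature, a two-group moderated t is used with a
deliberately simple empirical-Bayes scheme: the pooled prior variance is the
mean of per-feature pooled variances, blended with prior df $d_0 = 4$
(configurable),
$\tilde s^2_g = (d_0 \bar s^2 + d s^2_g)/(d_0 + d)$, and p-values come from
the t distribution with $d_0 + d$ df. This is an approximation of the
negative-binomial GLM machinery commonly applied to counts; equivalence with
such packages is not claimed, and the package's own validation is calibration
and recovery on synthetic truth.

Decision rules are intentionally asymmetric across layers, with the linear
signed fold change $\mathrm{fc} = 2^{\ell}$ for $\ell \ge 0$ and
$-2^{-\ell}$ otherwise:

* transcripts: raw $p < 0.1$ and $|\mathrm{fc}| > 2$;
* proteins: BH FDR $< 0.1$ and $|\mathrm{fc}| > 1.5$.

Known numerical properties, verified by the test suite:

* With the fixed pooled prior and the $t_{d_0+d}$ reference the statistic is
  **mildly conservative**: on null data at $n = 3$ vs 3 with near-homogeneous
  variances the empirical $P(p < 0.05)$ is about 0.031-0.037 rather than
  0.05 (the mixed denominator has roughly half the sampling variance its
  reference distribution assumes, and $\log_2$ negative-binomial counts are
  slightly skewed). Realized FDR at a nominal 0.1 is well below 0.1 and
  sensitivity for 4-fold effects at moderate expression is essentially 1.
* **Size-factor behaviour**: multiplying one sample's raw counts by $c$
  rescales all normalized counts by the geometric-mean shift $c^{1/m}$, so
  with the pseudocount the transcript p-values are invariant only up to
  $O(1/\text{count})$ (tested at $10^{-3}$ on realistic magnitudes); the
  pseudocount-free protein path is exactly invariant.
* **Total-area normalization is composition-sensitive**: planted effects are
  attenuated by the treated/control total-intensity ratio. With a perturbed
  mass fraction of a few percent (as in real DIA experiments) the bias is a
  few hundredths of a log2 unit; fixtures that plant effects on a large
  fraction of total intensity push true 2-fold changes visibly toward the
  decision boundary. This is a property of the normalization, not of the
  implementation.

BH adjustment is a validating wrapper over the standard step-up procedure and
is oracle-tested against a brute-force enumeration.

# Cross-omics integration

Protein-transcript pairs come from an explicit id mapping (duplicate protein
ids rejected; no fuzzy matching). The Pearson correlation of log2 fold
changes is reported for all matched pairs and for the subset whose protein
call is not `ns`; fewer than 3 pairs is flagged undefined rather than
returned as NaN. Correlations use log2 fold changes, not signed linear fold
changes, because the latter are discontinuous at $\pm 1$.

Sample-sample structure uses Pearson correlation on log2 values of a feature
subset (by default the differential proteins annotated to the extracellular
space or plasma membrane, the compartments where activation remodeling
concentrates), agglomerative clustering with **average linkage** on the
distance $1 - \mathrm{PCC}$, and Newick export. PCA is column-centered,
unscaled, SVD-based, on log2 size-factor-normalized counts.

# Annotation

Term enrichment is the one-sided hypergeometric tail over a stated universe,
with an optional EASE-style variant (observed overlap decremented by one,
floored at zero) available behind a flag; plain hypergeometric is the
default. Ranking is by p-value with ties broken by term id.

Upstream-regulator calls use a sign-consistency statistic over a regulator's
differentially expressed targets: $z = (N^+ - N^-)/\sqrt{N^+ + N^-}$, where
$N^+$ counts targets whose fold-change sign matches the signed regulatory
edge. Calls are strict: `activated` iff $z > 3$, `inhibited` iff $z < -3$
(so nine perfectly consistent targets, $z = 3$, remain `none`). A gate on
the one-sided overlap p (target set vs differential set within the tested
universe; default $p < 0.1$, i.e. $-\log_{10} p > 1$) suppresses calls for
regulators whose targets are not enriched among the differential features;
`maxOverlapP = Inf` disables it. Regulators without differential targets are
reported `untestable`.

# Target prioritization

The cascade mirrors the figure-level logic of multi-omics fibrosis studies:

1. candidates are the union over sources of upregulated differential
   proteins (as genes);
2. the **disease filter** keeps candidates with at least one association row
   for pulmonary, cardiac, hepatic or renal fibrosis; any positive score
   counts by default (`minScore = 0`), since curated resources keep
   low-score literature associations — the cutoff is configurable;
3. **network expansion** adds candidates (never outside genes) sharing at
   least one interaction edge with combined score $\ge 0.7$ with an
   associated gene — the 0.7 "high confidence" cutoff is *inclusive*, the
   expansion is exactly one hop, and unconnected candidates stay hidden;
4. **drug annotation** joins an availability table;
5. the **panel** is ranked by (number of sources upregulated, max
   association score, high-confidence degree to associated members, gene id)
   — a deterministic total order.

# The synthetic-data generator

`simulateStudy()` emulates a three-source (aHCF, fHCF, hiPSC-CF) x
{control, treated} x 3-replicate design:

* **Counts**: gene baselines $\mu_g$ log-normal (meanlog 5, sdlog 1.5 —
  median around 150 with a realistic bulk dynamic range); negative binomial
  with $\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.05$; per-sample
  library factors log-uniform in $[0.5, 2]$ so size-factor estimation is
  exercised non-trivially.
* **Planted program**: a fraction `fracDeg` (default 0.1) of non-panel genes
  per source receives $\pm$`lfcMagnitude` (default 2) under treatment; panel
  genes respond with `panelTreatmentLfc` (default +1, joining the "up" truth
  sets) so treatment raises the activation score; the control samples of the
  pre-activated sources (default aHCF and fHCF, mirroring the higher basal
  activation of primary cells in culture) carry a `panelOffset` (+0.5 log2)
  on panel genes only.
* **Proteins** map 1:1 to a gene subset, with 9% "orphans" mapped outside
  the transcript universe (emulating roughly 91% transcript coverage of a
  proteome). Protein log2 baselines track gene baselines at half strength
  plus unit log-normal spread, keeping any single protein from dominating
  column totals. For proteins of planted genes the true protein effect is
  $\rho\,\ell_t + \sqrt{1-\rho^2}\,\varepsilon$ (default $\rho = 0.8$,
  $\varepsilon \sim N(0, \texttt{lfcMagnitude})$), so coupling exists only
  where transcripts moved — which is what makes the DEP-restricted
  fold-change correlation exceed the all-pairs one. Measurement noise is
  log-normal (sd 0.3 log2 units); per-sample loadings are removed by
  total-area normalization. An optional missingness rate exists and is off
  by default.
* **Annotations**: fibrosis associations for ~25% of upregulated planted
  proteins plus background and decoy (non-fibrosis) rows; an interaction
  network whose background scores stay below 0.7 while a planted module
  wires 3 non-associated upregulated proteins to associated ones at 0.9;
  single-location assignments with differential proteins enriched for
  extracellular space/plasma membrane; a drug table; GMT term sets; and a
  regulator table with one planted activator and one planted repressor.
* **Truth ledger**: planted DEG/DEP sets with true effects, baselines, and
  an `expectedPanel` derived at generation time by an independent
  brute-force scan (set filter plus one-hop edge scan) that shares no code
  with the pipeline.

Identical configuration and seed give bit-identical output.

What the generator does **not** emulate: batch effects, gene-gene
correlation, dispersion trends, protein missingness structure, shared-peptide
ambiguity, and annotation noise. Passing tests therefore demonstrate internal
correctness and calibrated behaviour under a clean generative model, not
performance on the deposited datasets; dataset-specific headline numbers from
real studies additionally depend on external database versions and are out of
scope here.

## The bundled end-to-end fixture

`fixtureConfig()` (1500 genes, 750 proteins, `fracDeg` 0.04, $\rho = 1$,
protein noise 0.1) is designed so the planted protein truth is *exactly*
recoverable by the protein decision rule: effects sit several noise standard
deviations from both the fold-change and FDR boundaries, and the perturbed
mass fraction (~5%) keeps the composition bias of total-area normalization
far from the 1.5-fold cutoff. On this fixture the full pipeline's prioritized
panel equals the truth-derived expected panel, and reruns are byte-identical.

## Problem sizes used by the test suite

Simulation sizes were chosen as the smallest that keep Monte-Carlo bands
tight: score-recovery power uses 200 runs of a 60-gene design; DE calibration
uses 2000-gene single-source runs (10 null, 50 planted); the cross-omics
structure checks use 50 runs at 400 genes / 220 proteins; oracle equivalences
use 1000 random vectors (BH), universes up to 30 (enrichment), and random
graphs of 200 nodes (expansion).

# Known limitations

* The moderated t is conservative at small $n$ (see above); it approximates
  but does not reproduce NB-GLM count machinery.
* The transcript decision rule uses the raw p-value by design, so transcript
  DEG lists control per-comparison error, not FDR; the protein rule controls
  FDR.
* Total-area normalization transfers composition shifts into fold-change
  estimates; strongly unbalanced regulation biases protein fold changes.
* The activation score is relative to the analyzed sample set; scores from
  different runs are not comparable.
* The regulator statistic is a documented surrogate for proprietary causal
  networks; only the thresholded call logic and schema are reproduced.
* Gene identifiers are opaque strings; alias resolution (e.g. CTGF/CCN2) is
  the caller's responsibility.
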
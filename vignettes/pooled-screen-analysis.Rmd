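---
title: "Methods: pooled CRISPR fate-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled CRISPR fate-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprfate)
```

# The screen and its statistical model

crisprfate analyses pooled CRISPR/Cas9 screens in which a guide library —
several guides per target gene plus non-targeting scramble controls — is
delivered to a progenitor tissue, and the consequence of each perturbation
is read out by single-cell RNA-seq with guide capture: each cell yields a
transcriptome, a set of captured guide barcodes with UMI counts, and (after
upstream clustering, which this package consumes as input) a fate-cluster
label. The analytical questions are (i) which guide assignments are real,
(ii) which guides actually knocked their target down, (iii) whether the
cells carrying a guide are over- or under-represented in particular fate
clusters relative to scramble, (iv) what each perturbation does to the rest
of the transcriptome, and (v) how many cells and guides a screen of this
kind can support. A companion module quantifies per-cell measurements from
multiplexed in situ (HCR) imaging, the orthogonal readout usually paired
with such screens.

Throughout, the scramble guides play the role of the null: their
distribution across clusters defines the expected representation of a guide
with no fate effect, and scramble-bearing cells are the reference
population for expression comparisons.

# Ambient filtering of guide capture

Guide capture contains spurious low-UMI assignments from ambient guide
molecules. `filter_ambient()` implements a per-guide rule: over the cells
with at least one UMI of a guide, compute the mean $m$ and sample SD $s$ of
$\log_{10}(\mathrm{UMI})$ and discard assignments with
$\log_{10}(\mathrm{UMI}) < m - 2s$ (the multiplier is a parameter).
Decisions taken where the rule is underspecified:

* **Per-guide statistics** (default) rather than pooled over all guides,
  because ambient background scales with each guide's plasmid abundance.
  `pooled = TRUE` provides the pooled alternative.
* **Sample (n−1) SD**, appropriate for the small per-guide cell numbers.
* **Boundary retained**: values exactly at the threshold are kept; the rule
  discards strictly below.
* A guide with a single nonzero cell has zero spread and keeps that cell; a
  guide with no nonzero cell has an undefined threshold and is flagged
  `undetected` (guide dropout), not an error.
* The rule is a single pass. Re-filtering retained counts recomputes the
  statistics on a truncated distribution and can discard more; callers
  should filter once.

With a bimodal UMI distribution (true capture around the configured true
mean, ambient near 1) the rule removes the low mode. When the ambient
fraction for a guide is large, the mixture inflates $s$ until $m - 2s$
falls below $\log_{10}(1) = 0$ and everything is retained — a genuine
property of the rule worth knowing when capture depth is low.

# Successful-guide QC

`qc_guides()` compares the target gene's normalized expression
(counts scaled to 10,000 per cell, then $\log(1+x)$) between cells carrying
the guide and a comparator, with a two-sided Wilcoxon rank-sum test. When
the smaller group has ≤ 8 cells the null is enumerated exactly over all
assignments of the pooled midranks, which handles ties exactly; otherwise
the tie-corrected normal approximation is used. The fold change is
$\log_2$ of group means on the de-logged scale with pseudocount 1. BH
adjustment runs across all guides of the run, and "successful" requires
both a negative fold change and FDR below the threshold (default 5 %).

Two comparators are offered because the natural definitions differ:
scramble-bearing cells (the default) or all cells without a guide against
the tested gene. Cells carrying both a guide for the tested gene and a
scramble are counted in the guide group only, since any guide against the
gene may perturb it. Groups below `min_cells` give an indeterminate record
(`successful = NA`) rather than an error, mirroring real screens where
guides drop out. `summarize_success()` tallies guides per gene and flags
genes with no successful guide for exclusion from enrichment analysis.

# Enrichment and depletion statistics

Representation of guide $g$ in cluster $c$ is
$r_{gc} = n_{gc} / N_c$ with $N_c$ the cluster size over all labeled cells.

**Cross-validated scores.** Cells are split into $k$ folds (default 5)
stratified by cluster, with a seeded partition; per fold,
$\log_2\!\big[(r_{gc} + \varepsilon) / (\bar r_{\mathrm{scr},c} +
\varepsilon)\big]$ with $\varepsilon = 1/(\text{fold cluster size} + 1)$,
and the reported score is the mean over folds with its SD. The smoothing
guards empty cells of the table; one fold reduces to the whole-data log
ratio.

**χ² z-scores.** Each guide's cluster counts form a 2 × K table against a
reference row — scramble guide 1, or the average over all guides (both are
useful; the scramble is the biological null, the average is more stable).
The per-cluster "z-score" is the adjusted standardized residual
$(O - E)/\sqrt{E\,(1 - n_{g\cdot}/N)(1 - n_{\cdot c}/N)}$, which is
standard normal under independence, so the conventional $\pm 2$ cutoff has
its nominal meaning; raw Pearson residuals are available by flag. Counts,
not fold-wise representations, enter the table — χ² assumes counts.
Clusters whose expected guide count falls below 1 are pooled into a
remainder category that contributes to the statistic but gets no
per-cluster call; an all-zero guide row is untestable and flagged.

**KLD cross-validation test.** Because χ² is sensitive to small
populations, a divergence test confirms calls: the guide's cells are split
into folds, and the statistic is the mean over folds of
$D_{KL}(\hat p_{\mathrm{fold}} \,\|\, \hat q_{\mathrm{scramble}})$ in nats
(base configurable), both distributions smoothed by adding $1/K$ to each
cluster mass and renormalizing. The null is built by permutation: pooled
guide + scramble cells are randomly relabeled, and
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(B + 1)$. A permutation
null was chosen as the assumption-free construction for a CV divergence
statistic. Guides with fewer cells than folds are indeterminate. The
$1/K$ smoothing makes the test deliberately conservative for shifts
confined to a single cluster when per-guide cell counts are modest — the
χ² residuals are the sensitive per-cluster instrument; the KLD test is a
distribution-level confirmation.

**Pattern grouping and PCA.** K-means over the guides × clusters enrichment
matrix runs for $k = 1..k_{max}$ with ten restarts under a fixed seed; the
chosen $k$ maximizes the second difference of the total within-cluster SS
(the elbow). Degenerate inputs (identical rows, no interior elbow) fall
back to one group. PCA is column-centered, unscaled; loadings identify the
clusters driving each component.

# Perturbation expression signatures

`lr_scores()` regresses per-gene scaled expression (centered, unit
variance; constant genes zeroed) on an intercept plus one indicator column
per targeting guide, scramble cells being the all-zero reference, with a
ridge penalty on the guide columns (default 0.1; zero demands a nonsingular
design and the error says so). Cells carrying several guides contribute a 1
to each of their columns — the pooled-screen convention that a
perturbation's trend is maintained across all cells that received the
guide. The coefficient of a guide column is its per-gene lr score.

Significance is by permutation of the cell-to-guide labels. Permuting rows
of the design leaves $X^\top X$ unchanged, so the projector
$(X^\top X + \lambda D)^{-1} X^\top$ is factored once and each replicate is
a single matrix product — the permutation loop is linear algebra, not
refitting. $p = (1 + \#\{|\beta^{perm}| \ge |\beta^{obs}|\})/(B+1)$; BH
runs across genes within each guide. Gene-level membership of the
misregulated set uses raw $p < 0.05$ while term-level ORA uses adjusted
$p < 0.05$ — the asymmetry is intentional and follows the screen-analysis
convention this pipeline reproduces; the BH q is exported regardless.

Misregulated sets are compared by Jaccard overlap
($|A \cap B| / |A \cup B|$; the reported value is the overlap fraction) and
by over-representation: one-sided Fisher exact tests against a local GMT
annotation over a fixed universe, BH over terms. No online enrichment
service is contacted.

# Screen design

`cells_per_guide()` implements the two-sample difference-of-means sample
size $n = (Z_{1-\alpha/2} + Z_{\mathrm{power}})^2 (\sigma^2 +
\sigma_{AVG}^2)/\Delta^2$, where $\Delta$ is the detectable difference in
guide-detection cells, $\sigma$ the per-gene SD of guide detection and
$\sigma_{AVG}$ the average SD across target genes. Both the real value and
its integer rounding are returned. `guide_capacity()` floors
tissue cells × efficacy / cells-per-guide — a fractional guide cannot be
electroporated. `guide_detection_sd()` computes the σ inputs from pilot
data. With 6000–9000 target cells, 80 % efficacy and 240 cells per guide
this brackets 20–30 guides per embryo.

# HCR quantification

Per-cell "hood" averages (a slight dilation of the nuclear mask, proxy for
transcripts per cell) are divided by DAPI to correct imaging artefacts;
positivity is a strict comparison to the within-channel mean of the
normalized distribution, computed per table (a per-image flag would be the
alternative when pooling embryos; per-table is the default because the
normalization already absorbs per-image intensity scale). TBXT levels are
classed high (> 0.4), medium (> 0.3), else negative, with strict
inequalities so 0.4 is medium. Co-expression overlap divides co-positive
cells by the reference class size and returns coordinates for back-mapping.
Profile clustering is average-linkage Euclidean with rows pre-sorted by
cell id so ties break deterministically. Mask tortuosity is
perimeter/area with the perimeter as the 4-connectivity count of foreground
edges facing background or the grid boundary — image tools differ in
perimeter conventions, so this one is fixed and tested (a solid k × k
square scores 4/k).

# The synthetic screen generator

`simulate_screen()` provides the ground truth every stage is validated
against. Its generative model, and what each default emulates:

* **Clusters**: cells sample a cluster from a baseline probability vector;
  the default 14 clusters with proportions $\propto (K{:}1)^{0.7}$ emulate
  the uneven fate-cluster sizes of a subsetted embryonic dataset.
* **Library**: 25 target genes × 4 guides + 2 scrambles (102 guides), the
  screen-scale design.
* **Guide uptake**: a zero fraction (cells with no captured guide; default
  0.8 of cells) times a zero-truncated Poisson (rate 2) capped at 29
  guides — one-knob overdispersed electroporation uptake reproducing
  multi-guide cells in the observed 0–29 range.
* **Capture UMIs**: true assignments draw Poisson counts truncated at ≥ 1
  around a high mean (50); **ambient contamination** is an independent
  Bernoulli per (cell, guide) tuned so the expected ambient assignments per
  cell equal `ambient_rate` (default 0.5), with truncated-Poisson counts
  around a low mean (1). The configuration rejects ambient means that are
  not well below the true mean.
* **Knockdown**: the target gene's negative binomial mean is multiplied by
  `knockdown_fraction` in cells bearing one of its guides (default 0.2, an
  80 % knockdown; 1 gives a null screen).
* **Fate effects**: per (gene, cluster) multiplicative tilts on the
  cluster probabilities of guide-bearing cells, renormalized — valid for
  any factor ≥ 0.
* **Expression**: negative binomial per (gene, cluster), dispersion 0.5,
  lognormal baselines with mild cluster modulation — the standard scRNA
  count model at typical shallow-capture depth.
* All randomness flows through one seed; identical configurations and
  seeds are bit-identical, and the ground truth records every planted
  assignment and effect with true and ambient assignments disjoint.

What the generator does **not** emulate: doublets, batch and embryo
effects, cell-cycle structure, read-level errors, spatial expression
gradients beyond cluster structure, and correlated off-target
transcriptional programs. Tests passing on this generator therefore
demonstrate correctness and calibration of the statistics under a clean
generative model, not robustness to every artefact of real data.

`simulate_hcr_table()` plants per-channel positive populations at a
configurable mean above a negative baseline (default 0.3 of the positive
mean, noise SD 0.08 of it — well-separated bimodality typical of a clean
HCR channel) on a 2-D domain, with the planted labels kept for scoring.

# Numerical choices and problem sizes

Tolerances and conventions already noted: ε-smoothing $1/(\text{size}+1)$
for log-ratios and $1/K$ for KLD; natural-log KLD; exact rank-sum
enumeration bounded at 20,000 combinations; expected-count pooling
threshold 1 for χ²; k-means restarts 10; permutation defaults 999.

The validation suite exercises the pipeline at desk scale: null screens of
400 cells with a 10-guide library over 50 seeds for calibration of the
success, z and KLD calls (rejection rates are checked against a 7 % bound
at nominal 5 %); knockdown screens of 900 cells with ≥ 50 cells per arm
over 20 seeds for power; fate-shift screens of 1200 cells with ≥ 200 cells
per guide (χ² recovery) and 5500 cells at ≈ 300 cells per guide in a
26-guide library (CV-score recovery, evaluated on ground-truth assignments
to isolate the scoring stage from the filter). These sizes are the
package's own choices for a fast, reproducible suite; the statistics
themselves carry no size limits. KLD calibration runs 199 permutations,
which resolves p at 0.005 — ample for checking a 5 % level.

# Known limitations

* Cluster labels are consumed, not produced; errors in upstream clustering
  propagate untested.
* The χ² "average of all guides" reference includes the tested guide,
  which is slightly conservative; the scramble reference avoids this at
  the cost of a noisier reference row.
* The KLD test's $1/K$ smoothing dampens single-cluster shifts (see
  above).
* The lr-score permutation null permutes whole cells, preserving gene-gene
  correlation but not guide-guide co-occurrence structure within a cell.
* The power formula assumes approximate normality of per-guide detection
  counts and known σ; with pilot-estimated σ it is an approximation, and
  capacity arithmetic assumes uniform guide uptake.
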
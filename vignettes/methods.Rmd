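---
title: "Methods: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coexPK implements an integrated liver-transcriptome analysis for drug
pharmacokinetics (PK): count normalization and filtering, batch-adjusted
negative-binomial differential expression, unsigned weighted co-expression
networks with module detection, module–trait correlation with a joint
selection filter, per-condition scaled connectivity with hub calling and
Kolmogorov–Smirnov comparison, and term enrichment. This vignette explains
the statistical models, the parameters that matter, the synthetic-data
generator used for validation, and the numerical and design choices that
were genuinely open.

## Normalization model

Counts are assumed to be gene-level summaries of a bulk RNA-seq experiment
with widely varying library sizes and mild compositional differences.
`tmmFactors()` computes trimmed-mean-of-M-values factors (via edgeR):
gene-wise log ratios against a reference sample (the one whose
upper-quartile CPM is closest to the mean upper quartile) are trimmed 30%
by M and 5% by A and combined with inverse approximate-variance weights;
factors are rescaled to geometric mean 1, and effective library sizes
(library size × factor) feed every downstream unit:

* CPM(g, s) = count(g, s) / effectiveSize(s) × 1e6
* RPKM(g, s) = count(g, s) × 1e9 / (effectiveSize(s) × length_bp(g))

Two conventions were open and are recorded as arguments rather than
hard-wired: the log transform's prior count (default 1, which keeps zeros
at zero on the log2 scale) and whether RPKM uses raw or TMM-effective
library sizes (effective, so that CPM and RPKM differ only by the gene
length factor 1e3 / length).

The expression filter keeps genes with CPM strictly above 1 in at least 5
samples, applied to the full sample set before any per-arm analysis.

`batchAdjust()` removes batch effects from log expression by per-gene least
squares with sum-to-zero batch coding (via limma's removeBatchEffect),
subtracting only the fitted batch component; the biological design
(treatment) is preserved explicitly. Sum-to-zero coding keeps adjusted
values centred on the grand mean, and the adjustment is idempotent.

## Differential expression

Per gene the count model is negative binomial with log link and effective
library sizes as offsets. The original analysis delegates this stage to a
count-model tool whose exact dispersion flavour and test are not stated;
coexPK implements a defined simplification and validates it by simulation
rather than by coefficient-level equality with any tool:

* **Dispersions** (`estimateDispersionsMoM()`): a Poisson GLM initializes
  the mean; the gene-wise dispersion solves the pseudo-likelihood moment
  equation sum (y − mu)^2 / (mu + phi mu^2) = n − p, with one refit of the
  mean under the estimated NB weights. A plain Pearson/Poisson moment
  estimator underestimates phi noticeably at these sample sizes, which
  inflates the likelihood-ratio test; the NB-weighted equation is unbiased
  to first order. The common dispersion is a 10%-trimmed mean of the gene
  estimates; tagwise values shrink toward it on the log scale with a fixed
  weight of 0.7 (a fixed-weight stand-in for empirical-Bayes shrinkage,
  deliberate at n = 40), clamped at 1e-6.
* **Fits** (`fitNbGlm()`): IRLS at fixed dispersion via `glm.fit` with the
  MASS negative-binomial family, epsilon 1e-8, at most 50 iterations,
  warm-started from the Poisson fit. Genes whose NB iterations diverge
  fall back to the Poisson mean and are flagged, not fatal.
* **Tests** (`lrtContrast()`): the null model reparameterizes the design
  onto the orthogonal complement of the contrast; the statistic is twice
  the log-likelihood difference (clamped at 0) against chi-square with
  1 df, two-sided; `bhFDR()` applies Benjamini–Hochberg.

Validation is statistical: on 2000-gene null simulations (n = 20/20, five
batches, gamma-distributed dispersions) the empirical type-I error at
nominal 0.05 is computed by the acceptance suite, pooled over three
simulations to keep the Monte-Carlo error of the estimate small; power is
measured on planted log2 fold changes of 2 at mean count 100. The
measured type-I error sits in the upper half of the nominal band — the
plug-in of estimated dispersions into a likelihood-ratio test is known to
be slightly liberal at these sample sizes.

## Network construction

The network is unsigned: a_ij = |cor(x_i, x_j)|^beta, diagonal 1, on
(typically batch-adjusted log2 RPKM) expression; constant genes are
dropped with a warning. `pickSoftThreshold()` scans candidate powers 1–20:
connectivities are binned into 10 equal-width bins and log10 frequency is
regressed on log10 mean connectivity; the signed fit index is
−sign(slope) · R², and the chosen power is the smallest reaching the 0.90
target, otherwise the argmax (candidates with fewer than three nonempty
bins are flagged and excluded). The pipeline default is beta = 18, the
published power for this analysis; the scan remains available
(`beta = NULL`).

`tomSimilarity()` computes topological overlap with self-connections
excluded, TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij), and
clustering runs average linkage (UPGMA) on 1 − TOM.

**Tree-cut variant.** Module detection uses a static height cut: branches
below `cutHeight` (default 0.99 × the maximum merge height) with at least
`minModuleSize = 30` members become modules; everything else is grey.
This is the package's single largest methodological deviation from the
original toolchain's hybrid dynamic cut: the static variant is fully
specified by the dendrogram alone and is validated against planted truth
instead of against the original implementation. Its known weakness is the
interplay with the soft power: at low beta, weak background similarities
fall below a near-maximum cut and agglomerate; the validation experiments
therefore operate in the beta range where the cut's contrast assumption
holds (see below). Module labels are color names assigned by size rank
from a fixed palette, with ties broken by the lexicographically smallest
member gene, so labels are stable under gene reordering. The published
"reassignThreshold of 0" is read as "no post-hoc reassignment step".

Eigengenes are first right-singular vectors of the standardized module
blocks (unit norm, sign-aligned with the module's mean profile); modules
whose eigengenes correlate above 0.85 (merge height 0.15 on the 1 − cor
scale, average linkage) are merged iteratively to a fixed point, the
merged module keeping the largest member's label.

## Module–trait integration

Eigengene–trait correlations are Pearson, computed over the samples that
have both — in this design the treated animals, since untreated animals
have no PK estimates. P-values are two-sided via the Student-t transform
with n − 2 df (the reported study correlations, e.g. r = −0.42 with
P = 0.06 at n ≈ 20, are consistent with the two-sided choice). No
correction is applied across the module × trait grid, matching the
original analysis. A module is selected when, on its best trait
(largest |r|), |r| > 0.30 strictly and p < 0.10 strictly, and at least 10%
(inclusive) of its genes are DE at FDR < 0.05 in the arm's contrast; grey
is excluded. Module membership (kME) is the full gene × module correlation
grid against the eigengenes.

## Differential connectivity

Within a selected module, adjacency is recomputed per condition (treated
samples; untreated samples) with the same beta as the main network, and
scaled connectivity is k_i = sum_j a_ij / max_i sum_j a_ij, so each
condition's profile lies in [0, 1] with maximum exactly 1. The hub rule
applies the 0.6 threshold to |Δk| = |k_treated − k_untreated| (the
differential reading); the alternative reading — threshold on the raw
scaled connectivity — is exposed as `hubOn = "raw"`. Positive Δk means
more connected under treatment. Distributions are compared with a
two-sample Kolmogorov–Smirnov test: D is the supremum CDF gap on the
pooled support and the p-value is the asymptotic Kolmogorov series with
the standard effective-n correction; all-equal degenerate inputs yield
D = 0, p = 1 rather than NaN.

## Enrichment

One-sided hypergeometric upper-tail tests (Fisher-exact enrichment
direction) of each module against the expressed-gene background, after
intersecting the annotation with that background and dropping empty
terms. FDR is computed per module across its tested terms by default; a
global scope across all (module, term) pairs is available
(`fdrScope = "global"`) since the correction universe is not fixed by the
original description.

## The synthetic-data generator

`simulateDataset()` draws negative-binomial counts on top of log-scale
gene means: base log means N(log 150, 1.5²), gene-wise dispersions
gamma(shape 2, rate 20) (mean 0.1, a realistic bulk RNA-seq range),
gene lengths uniform on 300–10,000 bp. Genes of a planted module share a
per-sample latent factor scaled by the module's strength and a per-gene
loading U(0.8, 1.2); in treated samples the loading is multiplied by
(1 + connGain), which raises within-module co-expression — and hence
connectivity — under treatment without shifting means in expectation. A
per-module fraction of genes receives a log2 fold change in treated
samples. Batch effects are per-(gene, batch) log-normal multipliers
(SD 0.1 on the natural-log scale), removable exactly by the linear batch
adjustment. PK traits exist only for treated animals: a trait assigned to
a module is r · f + sqrt(1 − r²) · noise on the standardized scale, then
placed on plausible PK units (e.g. clearance mean 0.25 ± 0.08 L/h/kg);
unassigned traits are pure noise. Background genes carry independent
noise only, giving the tree cut an unambiguous "unassigned" truth. Term
annotations draw random gene sets per term and top up planted terms with
a configured fraction of a module's genes.

The generator's defaults mirror the study design: ~12,000 genes, 20
treated + 20 untreated animals per drug arm, five batches spanning both
groups, four planted modules sized like the reported PK-associated
modules (620/180/120/80 genes) with trait targets matching the reported
correlations (−0.44, 0.50, −0.42, −0.38).

What it does not emulate: isoform structure, read-level artifacts,
correlated trait families (each PK parameter is generated independently
given its module), gene-length/expression coupling, and outlier samples.
Passing tests therefore demonstrate the statistical contract of each
stage under a clean generative model, not robustness to every real-data
pathology.

## Validation experiment design

The acceptance experiments (shared by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) use these problem sizes:

* **Oracle agreement**: 100 random instances per kernel — TOM vs a
  triple-loop implementation (1e-12), TMM vs an independent
  trim-and-weight implementation (1e-10), UPGMA merge heights vs a naive
  agglomerator (1e-10), classical MDS inter-point distances vs an explicit
  double-centering eigendecomposition (1e-8), KS D and p vs a CDF-scan and
  an independently coded Kolmogorov series (1e-10), hypergeometric upper
  tails vs exact log-PMF summation (1e-12), BH vs a first-principles
  step-up (1e-12).
* **DE calibration**: three 2000-gene null simulations at study scale
  (n = 20/20, 5 batches) pooled for the type-I estimate; 1000 genes with
  200 planted log2FC = 2 effects for power.
* **Module recovery**: 25 seeds of the planted 50+50+100 design at
  strength 0.9, n = 40.
* **Selection recovery**: 100 seeds of one trait-linked (target r = 0.5),
  DE-rich (20% planted DE at log2FC 2) 80-gene module among three null
  60-gene modules and 160 background genes, n = 20/20.
* **Differential connectivity**: 100 seeds of a 160-gene module with
  connectivity gain 1.0 plus background, n = 20/20 — a point inside the
  regime (gain ≥ 0.5, size ≥ 80) where the treated-connectivity excess is
  expected; at the regime's weakest corner (gain 0.5, size 80) the KS
  signal at p < 0.001 is not reliably present at these sample sizes.

Two desk-scale choices deserve emphasis:

* **Fixed beta for network-stage experiments (beta = 10).** On a
  200-gene universe, half of it planted blocks, the scale-free criterion
  is not meaningful — its fit index never reaches the 0.90 target and the
  fallback argmax lands at the top of the candidate range, where the
  static cut dissolves modules into grey. Recovery was verified robust
  across beta 8–14; 10 is the midpoint. The pipeline itself defaults to
  the published beta = 18, appropriate at transcriptome scale.
* **Unnormalized log2 counts for the clustering/connectivity/eigengene
  steps of the desk-scale experiments.** Between-sample normalization
  assumes most genes are stable; with 20–60% of a small gene universe
  moving with planted factors, TMM/CPM division absorbs the factors into
  the library size and mixes them across modules, destroying exactly the
  structure under test. The full pipeline (`runArm()`) keeps the complete
  TMM/RPKM/batch-adjustment dialect, which is benign at its intended
  scale, where modules are a few percent of the transcriptome.

### A statistical limit of the selection filter

The three-part filter is applied to a module's best trait among seven PK
parameters. At n = 20 treated animals, p < 0.10 corresponds to
|r| > 0.378, so a module whose true trait correlation is 0.5 passes on
its own trait with probability ≈ 0.73–0.76 (Fisher-z sampling); one of
the six null traits rescues it part of the time (each passes at the
nominal 0.10 rate), giving ≈ 0.87 overall, while occasionally a null
module passes all three filters. Exact recovery of the planted module —
it and only it selected — is therefore bounded near 0.75–0.85 regardless
of implementation quality. The acceptance suite still asserts the 0.90
recovery level for this experiment, and that check documents the limit by
failing; the acceptance script reports the measured rate
(`selection_exact_recovery_rate`). At the study's own scale the same
arithmetic explains why a best-trait filter without multiplicity control
needs the DE-fraction condition to stay specific.

## Numerical choices and degenerate inputs

* Correlation p-values use the t transform; |r| = 1 maps to p = 0.
* `tomSimilarity()` requires symmetry within 1e-8 and returns a unit
  diagonal; UPGMA ties resolve deterministically (hclust's ordering).
* `cutModules()` validates the cut height against (0, max height];
  one-gene modules get unit variance explained; constant genes are
  dropped from eigengene blocks with a warning.
* `ksCompare()` evaluates both step CDFs on the pooled support, so tied
  and degenerate inputs are exact; the p series is truncated at 100 terms
  (alternating, geometrically decaying).
* The generator restores the caller's RNG state, and all pipeline
  randomness derives from the recorded seed, so reruns are byte-identical
  (asserted down to file bytes in the acceptance suite).

## Known limitations

* The DE stage is a defined simplification (fixed-weight shrinkage,
  plug-in LRT); its type-I error runs slightly above nominal within the
  validated band, and no quasi-likelihood or exact-test option exists.
* The static tree cut needs the adjacency contrast that moderate-to-high
  beta provides; it has no PAM-like stage to rescue borderline genes, so
  grey sets are larger than a hybrid dynamic cut would give.
* Networks are single-block; at transcriptome scale the dense TOM is
  O(p²) memory, so very large gene universes need prefiltering.
* PK traits are treated as exchangeable, independent readouts; real PK
  parameters are strongly inter-dependent (e.g. AUC and clearance), which
  a best-trait filter would exploit.
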
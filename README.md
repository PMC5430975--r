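# coexPK

Integrated co-expression network and differential-expression analysis of
bulk liver RNA-seq from drug-treated and untreated animals, linking gene
modules to pharmacokinetic (PK) phenotypes and testing how gene
connectivity changes under treatment.

## The scientific problem

Animals given the same dose of a drug (here the anthelmintic fenbendazole,
FBZ, or the anti-inflammatory flunixin meglumine, FLU) differ widely in how
fast they clear it. Those differences are summarized by PK parameters —
clearance (Cl), elimination half-life (T1/2), AUC0→∞, mean residence time,
Vdss, Cmax, Tmax — estimated from plasma concentration curves. The analysis
this package implements asks which liver transcriptional programs track
those PK differences, and whether drug exposure rewires the co-expression
of the genes involved.

The pipeline, per treatment arm (treated ∪ untreated):

1. **Filtering and normalization.** Genes with CPM > 1 in at least 5
   samples (across all arms jointly) are kept; libraries are normalized by
   the trimmed mean of M-values (TMM); expression is expressed as CPM for
   count modelling and as log2 RPKM (batch-adjusted) for networks.
2. **Differential transcript analysis.** Per gene, a negative-binomial GLM
   with log link and effective-library-size offsets; dispersions by a
   moment estimator with log-scale shrinkage toward the common value;
   treated-vs-untreated contrasts tested by likelihood-ratio chi-square
   (1 df) with Benjamini–Hochberg FDR. Breed × treatment and
   sex × treatment interaction contrasts of the form
   (Treated_A − Untreated_A) − (Treated_B − Untreated_B) are supported via
   cell-means designs.
3. **Unsigned weighted co-expression network.** Adjacency
   a_ij = |cor(x_i, x_j)|^β with β = 18 by default (or chosen as the
   smallest power whose signed scale-free fit R² ≥ 0.90); topological
   overlap TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij);
   average-linkage clustering of 1 − TOM; modules as branches below a
   static cut (0.99 × max merge height, minimum size 30); module eigengene
   = first principal component of the standardized module block; modules
   with eigengene r > 0.85 merged.
4. **Module–trait integration.** Pearson correlation of eigengenes with PK
   parameters over treated animals (untreated have no PK estimates);
   a module is carried forward when |r| > 0.30 with p < 0.10 on its best
   trait **and** ≥ 10% of its genes are differentially expressed at
   FDR < 0.05.
5. **Differential connectivity.** Within each selected module, scaled
   connectivity k_i = Σ_j a_ij / max_i Σ_j a_ij per condition; Δk =
   k_treated − k_untreated; |Δk| > 0.6 flags hub candidates; the two
   connectivity distributions are compared with a two-sample
   Kolmogorov–Smirnov test.
6. **Term enrichment.** Hypergeometric upper-tail tests of module gene
   sets against the expressed-gene background, BH-corrected.

Because the study data carry no public accession, the package ships a
synthetic-data generator (`simulationConfig()` / `simulateDataset()`) that
plants co-expression modules with latent factors, module-correlated PK
traits, treatment-DE genes, treated-condition connectivity gains and batch
effects — with full ground-truth access, so every stage is testable
offline.

## Worked example

```r
library(coexPK)

cfg <- simulationConfig(
  nGenes = 400, nTreated = 20, nUntreated = 20,
  moduleSpecs = data.frame(
    module = c("M1", "M2"), nGenes = c(70, 50), strength = 0.9,
    traitTarget = c(0.6, 0), trait = c("CL", "AUC"),
    connGain = c(0.5, 0), deFraction = c(0.25, 0)),
  deLog2FC = 2, nTerms = 40,
  termEnrichment = data.frame(module = "M1", term = "TERM001",
                              fraction = 0.4),
  seed = 1)
sim <- simulateDataset(cfg)

summ <- runArm(runConfig(arm = "FBZ", outputDir = "demo_out", seed = 1),
               dataset = sim$dataset)

read.delim("demo_out/module_selection.tsv")
#>      module best_trait     r        p de_fraction n_genes selected
#> 1      blue         CL 0.540 0.013882       0.000      46    FALSE
#> 2 turquoise         CL 0.728 0.000277       0.958      72     TRUE

read.delim("demo_out/ks_tests.tsv")
#>      module   D   pvalue mean_k_treated mean_k_untreated mean_diff
#> 1 turquoise 0.5 1.32e-08          0.652            0.334     0.318

head(read.delim("demo_out/enrichment.tsv"), 1)
#>      module term_id overlap module_size term_size   pvalue      fdr
#> 1 turquoise TERM001      31          72        62 1.54e-10 6.16e-09
```

The planted 70-gene module (M1) is recovered as `turquoise`: it correlates
with clearance on the treated animals (r = 0.73, p = 3e-4), nearly all of
its genes shift under treatment, its genes are more interconnected in the
treated network (mean Δk = +0.32; KS p = 1.3e-8, mirroring the elevated
treated connectivity the method is designed to expose), and its planted
annotation term tops the enrichment at FDR 6e-9. The trait-free,
gain-free module M2 (`blue`) is correctly rejected by the DE filter. Every
intermediate (DE table, module labels, eigengenes, kME, module–trait
matrix, connectivity, enrichment) is written as TSV beside a
machine-readable `summary.json`.

A thin command-line wrapper is available for the two end-to-end entry
points:

```sh
Rscript -e 'coexPK::pipelineCLI(commandArgs(TRUE))' simulate --seed 7 --out data/
Rscript -e 'coexPK::pipelineCLI(commandArgs(TRUE))' run-all --config run.yaml
```

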
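# evmorph

Single-cell morphological bioactivity profiling of microglia, with
companion secretome, lipidome and proteome analysis stages.

## The problem

Microglia — the immune cells of the central nervous system — change shape
with activation state: unstimulated cells in culture are small and round,
while cytokine-stimulated (IFN-γ + TNF-α) cells are larger, elongated and
ramified. That makes morphology a label-free, single-cell readout for the
bioactivity of candidate immunomodulatory therapeutics such as
extracellular vesicles from mesenchymal stromal cells (MSC-EVs): a
bioactive treatment shifts the stimulated phenotype back toward the
unstimulated one. evmorph is for assay developers and analysts who need
that readout as a tested, reproducible pipeline rather than a one-off
script: it covers shape/mitochondrial feature extraction from labelled
masks, single-cell QC, well-level scoring, assay-quality metrics,
dose–response, and the differential statistics used on the matched
secretion, lipid and proteome panels. A synthetic-data module generates
plates, images and omics tables with known ground truth so every stage is
validated without any external data.

## The model at the core

Per well, QC-passed cells are summarised by feature medians; features are
min-max normalized so the unstimulated control mean is 0 and the
stimulated control mean is 1 per feature
(x ↦ (x − μ₋)/(μ₊ − μ₋)); PC1 of the wells × 21-features matrix is the
composite morphology score, oriented so stimulated controls score higher;
anchoring PC1 to the control means gives the normalized bioactivity
readout, on which a treatment recovering a fraction δ of the morphology
gap scores 1 − δ. Assay quality is the Z′-factor

  Z′ = 1 − (3σ₊ + 3σ₋) / |μ₊ − μ₋|

over control wells (sample SDs; Z′ > 0.5 = optimized assay). The omics
stages provide Welch-test differential panels (raw p < 0.05, BH optional),
lipid class totals by ionization mode, empirical-Bayes moderated t
statistics with the joint |FC| ≥ 2 and p < 0.05 rule, gene set variation
analysis (kernel-ECDF rank random walk), per-set ANOVA/Tukey/BH, and
Ward.D2 clustering.

## Worked example

Simulate a full plate (8 wells per group, 700–1000 cells per well) where
EV treatment recovers 60% of the stimulation-induced morphology gap, then
score it:

```r
library(evmorph)
library(dplyr)

cfg    <- plate_config(ev_effect = 0.6, seed = 42)
cells  <- gen_feature_table(cfg)          # ~20,000 single-cell records
layout <- attr(cells, "layout")

res <- score_plate(cells, layout)         # QC -> medians -> min-max -> PCA
res$zfactor
#> Z' = 0.645 (optimized); mu- = 0.000, mu+ = 1.000, sigma- = 0.049, sigma+ = 0.069

glance(res$pca)[, 1:4]
#> # A tibble: 1 × 4
#>   n_wells n_features pc1_variance_pct pc2_variance_pct
#>     <int>      <int>            <dbl>            <dbl>
#> 1      24         21             94.8             4.82

res$scores |>
  group_by(group) |>
  summarise(score = mean(score_norm), sd = sd(score_norm))
#> # A tibble: 3 × 3
#>   group      score     sd
#>   <chr>      <dbl>  <dbl>
#> 1 NEG_CTL 2.43e-17 0.0490
#> 2 POS_CTL 1   e+ 0 0.0695
#> 3 POS_EV  4.01e- 1 0.0649
```

Reading the numbers: the controls anchor the normalized score at 0 and 1
by construction; the treated wells land at 0.40 ± 0.06, i.e. the pipeline
recovers the simulated 60% gap closure (1 − 0.6 = 0.4) from raw
single-cell records. Z′ = 0.645 > 0.5 says the control distributions are
separated well enough for screening. `autoplot(res$pca)` draws the wells
in PC space; `tidy(res$pca)` returns the loadings.

The omics stages run from generated (or your own) tables the same way:

```r
om <- gen_omics_tables(omics_config(seed = 1))
de <- differential_panel(om$secretion, om$secretion_groups, "NEG_CTL", "POS_CTL")
mod <- moderated_de(om$proteins, om$protein_groups, c("POS_CTL", "POS_EV"))
volcano_classify(mod)
es <- gsva_scores(om$proteins, om$gene_sets)
gene_set_anova(es, om$protein_groups)
```

`run_pipeline(run_config(seed = 7))` executes every stage and writes all
artifacts plus a manifest (seed, versions, config echo) into one
directory; identical configurations reproduce byte-identical outputs.

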
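---
title: "Methods: morphological bioactivity scoring and companion omics stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological bioactivity scoring and companion omics stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmorph)
```

# The assay

Microglia change shape when they change state. Unstimulated cells in culture
are small and round; after stimulation with IFN-γ and TNF-α they enlarge,
elongate and grow processes, which shows up in single-cell descriptors as
larger area, perimeter and major axis, higher aspect ratio, and lower form
factor (4π·Area/Perimeter², which is 1 for a circle). A candidate
therapeutic — here extracellular vesicles secreted by mesenchymal stromal
cells (MSC-EVs) — is scored by how far it shifts the stimulated phenotype
back toward the unstimulated one. evmorph implements that assay end to end
as a reusable, tested pipeline, together with the secretome, lipidome and
proteome analyses that accompany it, and a synthetic-data module that
emulates the assay's statistical structure so every stage can be validated
against known ground truth.

# The scoring model

The pipeline from segmented images to a bioactivity number is:

1. **Single-cell descriptors.** From labelled cell and nucleus masks,
   seven shape descriptors (Area, Perimeter, MajorAxisLength,
   MinorAxisLength, FormFactor, AspectRatio, PerimeterAreaRatio) for each
   of three compartments — cell, nucleus, and cytoplasm (cell minus
   nucleus) — giving the 21 canonical features, plus Solidity,
   Eccentricity and the nucleus:cell area ratio for quality control, and
   optionally 17 mitochondrial intensity/distribution/texture features
   from a mitochondria channel.
2. **QC.** Records with Solidity ≥ 1 (perfectly convex blobs: debris or
   collapsed segmentations of ramified cells) or nucleus:cell area ratio
   ≥ 0.85 (nucleus filling the cell: a segmentation error) are rejected;
   both rules are inclusive at the cutoff and independently toggleable.
   The ratio is interpreted as nucleus area over whole-cell area: the
   alternative (nucleus over cytoplasm-proper) can exceed 1, which would
   make 0.85 an odd place for a cutoff.
3. **Well medians.** Features are summarised per well by the median over
   its ~700–1000 cells, which makes the well summary insensitive to the
   outliers that survive QC.
4. **Control-anchored min-max normalization.** Per feature, the mean over
   unstimulated control wells (−CTL) maps to 0 and the mean over
   stimulated controls (+CTL) maps to 1; treatment wells are transformed
   by the same affine map and may land outside [0, 1].
5. **Composite PCA score.** PC1 of the wells × features matrix is the
   composite morphology score (`PC1_morpho` on the 21 cellular features,
   `PC1_mito` on the mitochondrial set). The sign is fixed so stimulated
   controls score higher, making "treatment lowers the score" the
   invariant reading. When the input is raw medians the features are
   z-scored first; min-max-normalized features are used as-is (both modes
   are available because both analyses occur in practice). The rotation
   is fit on all wells by default — treatment wells are plotted inside
   the same PC space — with a controls-only fit available as an option.
   Anchoring PC1 itself to the control means (`anchor_scores()`) yields
   the normalized bioactivity readout: a treatment recovering a fraction
   δ of the morphology gap scores 1 − δ.
6. **Assay quality.** `Z' = 1 − (3σ₊ + 3σ₋)/|μ₊ − μ₋|` over control
   wells, with sample (n − 1) standard deviations — the screening
   convention at 6–8 wells per group. Z' > 0.5 is an optimized assay;
   Z' is affine-invariant, so it is identical on raw and normalized PC1.
7. **Dose–response.** Per-dose mean ± sd of the normalized score and a
   Spearman rank correlation with a seeded permutation p-value
   (10,000 label permutations by default).

Batch structure (operator, experiment) is handled by the per-stratum
difference in group means (`delta_score()`), which cancels any shift that
moves both groups of a stratum equally.

# Shape measurement choices

**Perimeter.** Chain-code length along the traced boundary systematically
overestimates smooth outlines (~+5.5% for circles), and corrected
chain-code weights remain scale-dependent on block-upsampled masks.
evmorph instead traces the outer boundary (Moore neighbourhood), smooths
the pixel-centre path with a circular moving average whose window is
proportional to the boundary length (~1/40 of it), sums the full-resolution
polyline length, and adds π: the pixel-centre path sits half a pixel inside
the true outer boundary, and a closed curve offset outward by half a pixel
gains exactly 2π·½ in length. The window scaling makes the estimator
scale-invariant by construction; measured accuracy is better than 1% on
disks of radius ≥ 30 px and the form factor changes by ≤ 0.1% under 2× and
3× mask upsampling.

**Axes and eccentricity.** Major/minor axis lengths are 4√λ of the
eigenvalues of the pixel-coordinate covariance (the ellipse with matching
second moments), with the 1/12 unit-square term added so single-pixel
masks stay finite.

**Solidity.** Area over the pixelised convex hull area (pixel centres
inside or on the hull polygon of the mask's pixel centres, extreme points
only). This guarantees solidity ≤ 1 with equality exactly for convex
rasterised shapes — which is what makes "solidity = 1" usable as a debris
filter. One caveat: block-upsampled outlines are genuinely concave at
staircase corners, so solidity drifts by up to ~2.5% at 3× upsampling;
this is a property of the shape, not the estimator.

**Mitochondrial features.** Intensity statistics over the mask, mass
displacement (intensity-weighted vs binary centroid), the fraction of
intensity in four equal-width rings of normalized distance-to-edge
(ring 1 at the rim, ring 4 in the core; fractions sum to 1), and Haralick
texture (contrast, homogeneity, entropy, correlation) from symmetric
8-level co-occurrence matrices at offsets 1 and 3 px averaged over four
directions. An all-zero channel yields zero intensity statistics and
missing texture values.

# The synthetic-data module

The generator defines the study conditions under which the pipeline is
validated: three groups (NEG_CTL, POS_CTL, POS_EV), 8 replicate wells per
group, 700–1000 cells per well.

**Renderer.** Each cell is an ellipse body (semi-axes r√e and r/√e from a
latent radius r and elongation e) with a latent number of tapered Bezier
protrusions of latent length, placed without overlap; the nucleus is a
concentric scaled copy of the body ellipse with an area fraction drawn
from Beta(8, 12) clipped to (0.1, 0.8), guaranteed strictly inside; the
mitochondria channel is Gaussian puncta confined to the cell mask plus
background noise. Latent group parameters (defaults: unstimulated radius
18 ± 2.5 px, elongation 1.25, ~2 short protrusions; stimulated radius
27 ± 3.5 px, elongation 2.1, ~5 long protrusions) were chosen to reproduce
the qualitative contrast of the assay's two phenotypes at a 10×-objective
pixel scale; the source assay does not report numeric effect sizes, so the
defaults are calibrated to ordering and assay-quality behaviour, not to
absolute values.

**Image-free sampler.** `gen_feature_table()` draws per-cell descriptor
values directly: per-group mean vectors come from a deterministic shape
model of the latent means, each cell multiplies them by a shared
lognormal size factor (exponent 2 on areas, 1 on lengths, −1 on
perimeter:area, 0 on dimensionless ratios) and independent lognormal
jitter, both median-one so well medians are centred on the well mean.
Because the noise is multiplicative, derived identities such as
FormFactor = 4π·Area/Perimeter² hold only in location, not per cell —
the sampler reproduces marginal statistics, which is what the scoring
stages consume.

**EV-effect semantics.** The treated group's *feature-mean vector* is the
stimulated vector interpolated a fraction δ (`ev_effect`) toward the
unstimulated one, so δ is defined on the morphology scale the assay
actually reads out, and the normalized composite score estimates 1 − δ
without bias. The renderer interpolates the *latent* parameters instead
(the natural definition for image synthesis); the two definitions agree
at δ = 0 and δ = 1 and differ in between only through the curvature of
the latent-to-feature map. Parameter-recovery validation therefore runs
on the sampler, where the estimand is exact.

**Noise calibration.** Well-level random effects are additive in units of
the per-feature control gap with sd 0.04, shared across features within a
well; operator and experiment shifts (sd 0.10) enter the same way,
identically for all groups of a plate — level shifts with a preserved
group difference, which is the batch behaviour the assay reports. With
~800-cell medians the sampling noise adds little, so the per-group sd of
the normalized composite score is ~0.05 of the control gap, inside the
σ ≤ gap/12 regime that makes an optimized (Z' > 0.5) assay, and
comfortably reproducing "Z' > 0.5 in at least 7 of 8 experiments".
These values were fixed from the assay design before any validation was
run.

**Omics tables.** Abundances are log-normal with effects additive on the
log2 scale, so fold-change ground truth is exact. Defaults mirror the
assay's panel structure: 200 secreted analytes (94 detected; 38 up / 2
down on stimulation; 10 up / 14 down under EV treatment), 2662 proteins
(687 differential in the EV group vs the stimulated control: 258 up /
429 down, |log2 effect| drawn from 1.2–3), nine lipid classes split
between negative and positive ionization modes whose totals all rise on
stimulation except LPC (effect exactly 0), and a gene-set collection in
which the first five sets are enriched ~70% in direction-coherent
differential proteins (mixed-direction sets would cancel in a rank walk
and test nothing).

**What passing tests do and do not show.** The generator emulates group
structure, batch shifts, dose scaling and heavy-tailed per-cell noise; it
does not emulate segmentation errors beyond simple debris, illumination
or plate-position artifacts, correlated analyte panels, or missingness in
proteomics. Passing validation demonstrates the statistical machinery is
correct and calibrated under the assay's declared noise model, not that
any particular biological dataset will behave this way.

# Companion statistics

**Welch panels.** Secretion and lipid-class comparisons use the unpaired
Welch t-test on raw abundances with raw p < 0.05, as the assay reports
them; Benjamini–Hochberg correction is available by flag. Log2 fold
changes use group means with a pseudo-count of half the smallest positive
abundance. Note that with n = 6 log-normal samples the raw-scale test has
true size ~6% rather than 5%; calibration checks therefore run on the
log2 scale, where the null t distribution is exact.

**Moderated differential abundance.** Per-protein one-way linear model on
the treatment groups (residual variance pooled across all groups),
empirical-Bayes shrinkage of residual variances via moment matching of
log s² against a scaled-F prior — the prior degrees of freedom d₀ solve a
trigamma equation by Newton iteration (tolerance 1e−8), the posterior
variance is (d₀s₀² + d·s²)/(d₀ + d) and the moderated t has d₀ + d
degrees of freedom. When the moment equation has no positive solution the
d₀ = ∞ branch pools fully. Significance is the joint rule p < 0.05 and
|fold change| ≥ 2. The implementation is cross-checked against limma's
`lmFit`/`eBayes` to ~1e−8 in the test suite, which remains an independent
route: the estimator here is authored in-package.

**GSVA.** Per gene, a Gaussian-kernel CDF statistic across samples
(bandwidth s/4); per sample, genes ranked by the statistic, symmetrised
rank weights |p/2 − rank|, and a random walk that accrues |r|^τ
(normalised within the set) at members and 1/(p − |set|) elsewhere. The
enrichment score is the maximum positive plus minimum negative deviation
(`mx_diff = TRUE`, default) or the signed extreme deviation; τ defaults
to 1 and all knobs are exposed. Sets are intersected with the measured
matrix and filtered to 5–500 genes. Group comparisons use one-way ANOVA
per set, Tukey HSD for pairs, and BH across sets at q ≤ 0.05; a set with
zero within-group variance but separated means is reported with p = 0 and
flagged degenerate.

**Clustering.** Heatmap ordering uses row z-scoring and Ward.D2 on
Euclidean distances (`stats::hclust`); the tested artifact is the merge
tree, validated against an exhaustive centroid-formula Ward oracle.

# Numerical and degenerate-input conventions

* Min-max normalization refuses features whose control means coincide
  (|gap| ≤ 1e−12) rather than dividing by noise.
* The Z' denominator requires a non-zero dynamic range; equal control
  means are an error, not a 0/0.
* Welch tests resolve the zero-variance/zero-variance case to p = 1
  (equal means) or p = 0 with a warning (unequal means); analytes
  constant everywhere are flagged untestable instead of tested.
* PCA orientation ties (equal group means) keep the arbitrary prcomp
  sign; all scores are centred.
* Every stochastic operation takes an explicit seed, and the pipeline
  derives per-well and per-stage seeds deterministically from the run
  seed, so identical configurations reproduce byte-identical artifacts
  (audited by a test that diffs two same-seed runs).

# Problem sizes used in validation

The shipped validation suite simulates full-size plates (24 wells,
700–1000 cells per well) where the claim concerns the assay itself —
assay quality over 8 experiments and parameter recovery over 50 seeds per
effect size δ ∈ {0.25, 0.5, 0.75} — and small plates, toy matrices or
6-gene examples where the claim is algebraic or an oracle comparison.
Null calibrations use 100 simulation replicates (60-analyte panels,
300-protein matrices), sizes at which binomial error bounds are tight
enough to detect a miscalibrated test while keeping the whole suite
quick on a single CPU.

# Known limitations

* Segmentation itself is out of scope: masks are inputs, and the
  renderer provides ground-truth masks rather than realistic microscopy
  (no point-spread function, no illumination field).
* The renderer's cells are placed without overlap, so confluent cultures
  and touching-cell segmentation artifacts are not represented.
* No plate-position (edge-effect) correction; the assay design treats
  wells as exchangeable within a group.
* Raw-scale Welch testing of strongly skewed abundances at n = 6 is
  anti-conservative by about one percentage point; the flag for BH
  correction and the log-scale option in analysis code are the remedies.
* The GSVA implementation follows the published default algorithm; it
  does not implement the Poisson-kernel variant for counts or the
  rank-only variant.
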
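---
title: "Predicting geographic origin from small SNP panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting geographic origin from small SNP panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoaims)
```

## The problem

When genome-wide genotypes of individuals from a continent-scale cohort are
projected onto their top two principal components, the resulting scatter
famously mirrors the geographic map: PC1 and PC2 correlate with latitude and
longitude of reported ancestry. geoaims turns that observation into a
prediction pipeline. It selects small panels (hundreds) of
**PCA-informative markers** (PCAIMs) — SNPs that carry the
population-structure signal captured by the top principal components — and
predicts the latitude and longitude of origin of an unlabeled sample by
averaging the coordinates of its nearest training neighbors in PC space.
Small panels matter in practice: genotyping 500 markers is cheap and fast,
while the signal they summarise comes from hundreds of thousands.

## The model and procedure

Let $G$ be the $n \times p$ matrix of minor-allele counts (entries 0, 1, 2,
or missing) for $n$ samples and $p$ autosomal SNPs.

1. **Encoding.** Missing calls are replaced by the per-SNP mean of the
   non-missing entries; each column is then centered on that mean, so an
   imputed cell is exactly zero and contributes nothing to any inner
   product. (A $\{-1, 0, 1\}$ encoding differs by an affine map and leaves
   the PC geometry unchanged after centering.) Optionally columns can be
   rescaled by $1/\sqrt{p_j(1 - p_j)}$, the standard allele-frequency
   normalisation; this is off by default, and at the simulated
   allele-frequency spectrum it makes no qualitative difference.
2. **Decomposition.** The truncated SVD $X \approx U_k \Sigma_k V_k^\top$ is
   computed exactly via a symmetric eigendecomposition of the Gram matrix on
   the smaller side ($XX^\top$ when $n \le p$). $k = 2$ throughout: the two
   components that align with geography. No automatic choice of $k$ is
   attempted; it is a user parameter.
3. **Scoring.** Each SNP $j$ receives the leverage score
   $s_j = \sum_{i \le k} v_{ij}^2$, its squared contribution to the retained
   subspace. Orthonormality of $V_k$ forces $\sum_j s_j = k$, a conservation
   law the tests assert. Ties are broken lexicographically by SNP id so runs
   are reproducible. A variance-weighted variant
   ($\sum_i \sigma_i^2 v_{ij}^2$) is available behind a flag for sensitivity
   analyses.
4. **Pool and pruning.** The top `pool_size` SNPs by score (default 5,000)
   form the candidate pool. The pool is walked in score order and a SNP is
   accepted only if its squared Pearson correlation with every
   already-accepted SNP is at most `r2_threshold` (default 0.8), until
   `target_size` SNPs are accepted. Panels of several sizes (defaults 500,
   800, 1,000) are cut as prefixes of one pruned list, so they are nested.
5. **Prediction.** Training samples and test samples are placed in PC space
   (test samples centered with *training* means — a leakage guard, and also
   what makes a fully missing genotype project to the origin). For each test
   sample the `k_neighbors = 10` nearest training samples by Euclidean
   distance are found (ties broken by training sample id) and the prediction
   is the unweighted mean of their latitudes and longitudes. Values of
   $k$ between 10 and 20 and inverse-distance weighting are supported but
   showed no consistent advantage, so the simplest variant is the default.
6. **Error metric.** Per-axis absolute error in decimal degrees; longitude
   uses the minimal angular difference. Reports give per-population mean and
   standard deviation (population denominator $n$ — a fixed, documented
   choice since either convention is defensible) plus a count-weighted
   overall row, with kilometre equivalents
   ($1^\circ$ lat $\approx 111.32$ km, $1^\circ$ lon $\approx
   111.32 \cos(\text{lat})$ km) as convenience columns.

## Cross-validation designs

Two designs are implemented, and the distinction matters:

- **`loocv()`** re-selects the panels *from scratch* on every $n-1$ training
  subset before predicting the held-out sample. This is the honest design:
  the held-out genotypes cannot influence marker choice, column means, or
  the PCA. The package asserts this property directly — replacing the
  held-out sample's genotypes with arbitrary values leaves that split's
  selected panel and fitted model bit-for-bit unchanged.
- **`loocv(reuse_panels = TRUE)`** selects panels once on the full cohort
  and only re-fits the PCA per split. It is cheaper and optimistic (the test
  sample influenced marker choice); it is retained because the contrast
  between the two designs is itself informative — it measures how much of
  the reported accuracy is selection optimism.
- **`holdout_validate()`** trains on one cohort and predicts an external
  cohort, excluding test samples missing more than 10% of the panel first.
  When the external cohort has no accepted ground truth, predictions made
  from all shared SNPs serve as the reference, so the panel is judged
  against the best the full data can do. Test-cohort alleles are harmonized
  to the training encoding by ref/alt matching; strand-ambiguous A/T and
  C/G SNPs whose orientation cannot be resolved are dropped.

## The synthetic cohort generator

Real reference cohorts of this kind are access-controlled, so the package
ships a generator that emulates their statistical structure rather than any
particular dataset:

- **Demes on a grid.** Each population (deme) sits at fixed coordinates and
  every member inherits those coordinates as ground truth — the capital-city
  convention of real cohorts. The default is a 5×5 grid spanning 38–54°N and
  −5–23°E (a continental-European extent) with 40 samples per deme — 40
  being the population-size floor the cohort filter applies.
- **Clinal SNPs.** A minority of SNPs (default 2,000 of 20,000, i.e. 10%)
  have deme frequencies $p_d = \mathrm{clip}(p_0 + s_{lat}(\text{lat}_d -
  \overline{\text{lat}}) + s_{lon}(\text{lon}_d - \overline{\text{lon}}),
  0.01, 0.99)$, with the cline direction uniform on the circle and the
  frequency span drawn between half and all of `cline_strength` (default
  0.4). Linear clines with clipping are the simplest mechanism that produces
  the PCA–geography correlation the method exploits; no coalescent machinery
  is used.
- **Noise SNPs.** The majority share one baseline frequency with per-deme
  Balding–Nichols (beta) drift at a small $F_{ST}$-like dispersion (default
  0.01) — realistically non-identical across demes without being spatially
  informative.
- **Genotypes and missingness.** Two independent allele copies per sample
  ($\mathrm{Binomial}(2, p_d)$), then uniform masking at `missing_rate`
  (default 1%, a typical array call-failure rate). Everything is
  reproducible from the seed.
- Baseline frequencies are drawn from 0.2–0.8 so clines of span up to 0.4
  have room before clipping.

`europe_like_preset()` reproduces the *shape* of the published 11-population
European cohort (deme coordinates at approximate capitals, the published
per-population counts summing to 1,200, largest deme 219, ~20,000 SNPs) for
experiments that want that geometry.

**What the generator does not emulate:** linkage disequilibrium between
markers (every SNP is drawn independently), admixed individuals,
within-population substructure, non-linear clines, genotyping batch effects,
and platform-specific missingness patterns. Passing tests on these cohorts
therefore demonstrate that the pipeline recovers the kind of smooth spatial
structure it assumes; they do not certify accuracy on any real cohort, where
LD makes redundancy pruning far more consequential and structure is not a
clean grid.

## Numerical and design choices

- **Exact truncated SVD, not randomized.** At desk scale (up to a few
  thousand samples by tens of thousands of SNPs) the smaller-side Gram
  eigendecomposition is exact, deterministic and fast; randomized methods
  would only add an RNG dependency. Near-degenerate spectra (trailing
  singular values below $10^{-6}$ of the leading one) fall back to a dense
  LAPACK SVD so loading orthonormality survives rank deficiency.
- **Sign canonicalization.** Each loading column is flipped so its
  largest-magnitude entry is positive. k-NN predictions are provably
  invariant to per-component sign flips (they depend only on distances), so
  this is purely for reproducibility of serialized models.
- **Determinism.** Score ties break by SNP id; neighbor ties break by
  training sample id; identical inputs give byte-identical panel files.
- **Degenerate inputs.** Monomorphic SNPs center to all-zero columns, score
  zero leverage, and are treated as uncorrelated during pruning (their
  correlation is undefined). An all-missing SNP is an error; an all-missing
  *sample* projects to the PC origin and is predicted from the neighbors of
  the training centroid. If pruning exhausts the pool before reaching the
  target size, the shorter panel is returned with a warning.
- **Filter order** is fixed: SNP missingness, then sample missingness, then
  the population-size floor — markers are judged on the full cohort,
  samples on the surviving markers. The default per-SNP and per-sample
  missingness bounds are both 10% and configurable.
- **Longitude averaging** is arithmetic, valid for continental-scale
  cohorts far from the antimeridian; error computation nonetheless uses the
  minimal angular difference.
- **Redundancy pruning** is pairwise-correlation based. Other redundancy
  criteria (e.g. projection-residual methods) exist; the correlation bound
  was chosen because it yields a directly testable pairwise invariant on the
  emitted panel. It is isolated behind `prune_redundant()` so an alternative
  can be swapped in.

## Problem sizes used in the validation suite

The package validates itself at two scales, chosen so the full suite runs in
minutes on one core:

- **Reference scale** (the generator defaults: 25 demes × 40 samples,
  20,000 SNPs) for single-fit properties: pool enrichment of clinal SNPs
  and the PC–geography canonical correlation.
- **Scaled cohorts** (4×4 demes × 12 samples, 3,000 SNPs at the same 10%
  clinal fraction; 100-SNP panels from a 750-SNP pool) for the experiments
  that need hundreds of full re-selection fits: leave-one-out
  cross-validation across 10 simulation seeds against 10 random panels of
  equal size per seed. Re-selecting panels on every split of the reference
  cohort would cost thousands of large SVDs per seed; the scaled design
  preserves every structural ratio that matters (clinal fraction, samples
  per deme of the same order, pool-to-panel ratio) while keeping the honest
  per-split protocol.

On these scaled cohorts the PCAIM-panel LOOCV errors are a small fraction of
the grid extent per axis and consistently beat size-matched random panels on
both axes — the synthetic analogue of small, carefully selected panels
approaching all-marker accuracy. `scripts/acceptance.R` recomputes these
quantities end-to-end; the README shows a worked example with actual output.

## Known limitations

- No LD-aware quality control and no haplotype-based LD measure: pruning
  uses genotype correlation in the training cohort.
- Panels transfer across cohorts only as well as allele harmonization
  permits; strand-ambiguous SNPs that cannot be resolved are silently (but
  countedly) dropped.
- The k-NN predictor cannot extrapolate outside the convex hull of training
  coordinates; populations absent from training are mapped to their nearest
  represented neighbors.
- Per-split re-selection is quadratic-ish in cohort size times SVD cost; no
  SVD down-dating shortcut is implemented — correctness over speed.
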
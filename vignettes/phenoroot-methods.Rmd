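---
title: "Methods: from drone imagery to root haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from drone imagery to root haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenoroot` chains six components: a synthetic-data generator, per-pixel
vegetation-index (VI) extraction with soil masking, a spatial mixed model
for field trials, penalized-spline root-depth curves, PLSR/random-forest
trait prediction with variable selection, and a haplotype scan based on
local genomic estimated breeding values (LGEBVs). This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## The spatial mixed model

Plot observations in a replicated trial are modelled as

$$ y_{ijkm} = \mu + \mathrm{Rep}_m + R_j + C_k + G_i + e_{ijkm}, $$

with replicate, row ($R_j \sim N(0,\sigma^2_r)$) and column
($C_k \sim N(0,\sigma^2_k)$) effects random and residuals spatially
correlated: $e \sim N(0, \sigma^2\,\mathrm{AR1}(\rho_r) \otimes
\mathrm{AR1}(\rho_c))$, optionally plus an independent nugget
$\sigma^2_n I$ (on by default, `include_nugget`; the separable AR1
correlation between plots decays as $\rho_r^{|j-j'|}\rho_c^{|k-k'|}$).
Genotype is fixed for adjusted means (BLUEs, via generalized least squares
under the estimated covariance) or random for heritability.

REML estimation profiles the spatial variance out analytically and
optimizes the remaining variance *ratios* and the two autocorrelations
(on log and atanh scales) by bounded quasi-Newton (`L-BFGS-B`) from three
starting points, keeping the best optimum; the tolerance on the REML
criterion is about `1e-8`, and the fit is deterministic. Missing plots are
allowed — the covariance is built over observed cells only. Replicates are
crossed with rows and columns (not nested), which matches single-trial
layouts where replicate bands span the grid.

Heritability uses the line-mean definition
$H^2 = \sigma^2_g / (\sigma^2_g + (\sigma^2 + \sigma^2_n)/\bar n)$ with
$\bar n$ the harmonic-mean replicate count; no single standard definition
exists for spatial models, so the Cullis variant
($1 - \overline{\mathrm{PEV}}_\Delta / 2\sigma^2_g$, from the BLUP
prediction-error variances) is available via `method = "cullis"`.

Stage-1 "adjusted plot values" (`adjust_plot_values`) subtract the BLUPs
of replicate, row, column and the spatial field from each observation,
leaving genotype signal plus independent noise; the root-depth module
consumes these.

## Root-depth curves and AUC proxies

Core-break counts at 10–170 cm (10 cm steps) are smoothed per plot with a
cubic B-spline on the 10 cm knot grid and a second-order difference
penalty on adjacent coefficients (a P-spline). The smoothing parameter is
chosen by generalized cross-validation over a fixed log grid
(`10^seq(-6, 6, 0.25)`), making the fit deterministic; linear trends are
in the penalty nullspace, and noiseless polynomial data drive GCV to the
smallest smoothing and are reproduced essentially exactly. Counts are
treated as Gaussian: after stage-1 adjustment they are non-integer
adjusted values (negatives are clipped to zero before fitting). Negative
*fitted* values are retained during fitting and clipped only when
integrating.

The five proxy traits are trapezoid integrals of the clipped curve on a
0.5 cm grid: total area (0–170 cm) and the four soil-stratum areas 0–20,
20–60, 60–100 and 100–170 cm (the strata tile the profile, so they sum to
the total exactly; units are counts x cm). The hierarchical variant
(genotype-level mean curves with plot deviations) is collapsed to per-plot
fits followed by genotype averaging of the proxies, because the proxies
are the only downstream consumers and per-plot fits keep the two stages
cleanly separated.

## Vegetation indices and soil masking

The registry implements the indices that matter downstream (NDVI, OSAVI
with the 1.16 scaling, MSAVI, SAVI, MTVI1, NDRE, CLRE, ExG, VARIgreen,
raw band means and thermal), each documented by its formula string; it is
deliberately a small, extensible subset rather than an exhaustive index
catalogue. Vegetation/soil segmentation computes per-pixel OSAVI and
thresholds it by Otsu's method on a 256 equal-width-bin histogram,
breaking ties toward the lower threshold; the mask keeps the high-OSAVI
class. Degenerate single-population images (OSAVI range < 0.45, i.e. a few
times the single-class pixel noise but well under the ~0.7
vegetation-soil contrast) cannot be
thresholded and are classified wholesale by their OSAVI level against a
soil cutoff of 0.25 — a bare-soil plot gets coverage 0 and *missing*
masked statistics (never zeros), a closed canopy gets coverage 1. Per-plot
features are the unmasked mean, the masked mean and the coverage fraction
per index, suffixed by flight day (e.g. `osavimasked_mean_ndvi_88`);
per-index coverage variants from index-specific Otsu masks are available
behind a flag, since coverage can legitimately be defined per index.

## Trait prediction

PLSR is implemented in-repo (univariate NIPALS, predictors standardized
internally) so that variable importance exactly matches its stated
definition: $\mathrm{score}_j = \sum_a |w_{ja}| \cdot \mathrm{SSY}_a$,
the absolute component weights weighted by the response sum-of-squares
each component explains, normalized to a maximum of 100. At full rank the
model reproduces ordinary least squares, which the tests exploit as an
oracle. The component count is tuned by leave-one-out cross-validation
(ties to the smaller count).

Variable selection walks down the importance ranking; a candidate enters
only if its absolute Pearson correlation with *every already-selected*
variable is below 0.8 — a deliberately strict reading that guarantees a
pairwise-decorrelated final set, where filtering only against the next
best candidate would not. The stop rule quantifies the "point of
inflection" as: stop at the first set size after which two consecutive
additions each raise the multiple-regression $R^2$ by less than 0.01
(both thresholds configurable).

The random forest delegates to `ranger` behind a thin contract (variance
split rule, 150 trees, minimum node size 5, `mtry` tuned by 5-fold
cross-validated RMSE), since an ensemble implementation is standard
machinery rather than a contribution of this package. Biomass models use
flight-matched features only (the VI columns whose day suffix equals the
sampling day, renamed to a stage-agnostic schema and pooled across
stages, with raw plot biomass as the response); root models use the
full-season feature set. Metrics are $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/n}$ and
$\mathrm{rRMSE} = \mathrm{RMSE}/\bar y \times 100$.

Both PLSR and RF paths are provided; `plsr_topvars` is the pipeline
default for panel prediction, having the most consistent behaviour across
traits in this workflow.

## The haplotype scan

After QC (markers with MAF $\le$ 0.05 — inclusive — or heterozygote
fraction > 0.10 removed; missing genotypes are rejected, not imputed),
markers are chained into LD blocks per chromosome: the block anchor is its
first marker, a candidate joins while $r^2(\text{anchor},
\text{candidate}) \ge 0.7$, and up to 3 consecutive sub-threshold markers
are bridged if a later marker re-qualifies; otherwise the block closes
before the first sub-threshold marker. Anchoring LD at the first marker
(rather than all pairs) keeps the procedure deterministic and linear-time;
the published tooling this emulates does not document its exact chaining
semantics, so the tolerance interpretation here is a configurable reading,
not a claim about the original.

Marker effects come from ridge-regression BLUP: $y = 1\mu + Zu + e$ with
$u \sim N(0, \sigma^2_u I)$, $Z$ column-centered dosages, and
$\lambda = \sigma^2_e/\sigma^2_u$ estimated by REML through the spectral
decomposition of $ZZ'$ (one-dimensional profile optimization). The BLUP
$\hat u = Z'(ZZ' + \lambda I)^{-1}(y - \hat\mu)$ equals the closed-form
ridge solution by the Woodbury identity — an exact test oracle. One
variance ratio is fitted genome-wide; there is no per-block shrinkage.

Per block $b$ and line $i$, $\mathrm{LGEBV}(b,i) = \sum_{j \in b} z_{ij}
\hat u_j$ on centered dosages (consistent with how the effects were
fitted; centering shifts every line equally and leaves block variances
unchanged). Blocks whose across-line LGEBV variance reaches 0.2 of the
maximum block variance are selected, per trait, with no multiplicity
correction — the scan is descriptive. Because the scaled variance
normalizes by the maximum, the top block is always selected and a pure
noise phenotype still selects a baseline fraction of blocks; the
meaningful null statement, which the tests assert, is that the
selected-block count under a null phenotype matches the
phenotype-permutation expectation, while planted QTL blocks dominate the
selection as soon as the trait is heritable.

Population structure uses the modified Rogers distance
$\sqrt{\mathrm{mean}_j (p_{aj} - p_{bj})^2}$ (allele-frequency Euclidean
distance normalized to $[0,1]$), classical MDS, k-means on the leading
coordinates and Ward.D2 agglomeration as an alternative labelling.

## The synthetic-data generator

The generator emulates the study conditions the pipeline targets, with a
single seeded stream per stage (no global state leaks between stages) and
one set of per-line latent traits — four depth-stratum root intensities
plus one biomass scale, unit variance — feeding root counts, biomass *and*
VI features, so recovery is testable end to end.

* **Markers.** Near-inbred lines: each line carries a doubled haplotype
  per LD block, a small fraction (`het_rate`, default 0.03) two
  independent ones. Within-block latent normals are equicorrelated at a
  level solved numerically so the thresholded allele correlation matches
  the requested $r^2$ (`ld_within`, default 0.95); one target MAF per
  block keeps any requested LD attainable, and blocks whose realized MAF
  leaves `maf_range` are redrawn. Defaults give 7 chromosomes x 24 blocks
  x 3 markers = 504 SNPs for 200 lines.
* **QTL.** `n_qtl_blocks` (default 3) blocks per latent trait carry
  normal effects, each contributing an equal genic-variance share, scaled
  so the genetic fraction of the latent variance is exactly `qtl_h2`
  (default 0.6).
* **Field trials.** Complete replicates occupy consecutive runs of a
  rows x columns grid with genotypes randomized within replicate; each
  observation adds replicate, row, column, an AR1xAR1 spatial field
  (`rho_row` 0.5, `rho_col` 0.3, variance 1) and an iid nugget (0.25), in
  stage-scaled units.
* **Biomass.** Logistic mean trajectory
  $600/(1 + e^{-(t-72)/16})$ g m$^{-2}$ over days after sowing, sampled at
  tillering (25), stem elongation (55) and flowering (88); all random
  terms scale with 12% of the stage mean, so the genotypic coefficient of
  variation matches what replicated cereal trials typically show.
* **Root counts.** A declining exponential template (23.2 expected roots
  at 10 cm falling to ~0.4 at 170 cm) multiplied per stratum by
  $\exp(0.45\, g_s + 0.1\, d)$ — genotype latent and plot deviation — and
  drawn negative-binomial (`root_overdispersion` 20). The 0.45 scale
  reproduces the several-fold genotypic count ranges field coring studies
  report; the error law for core-break counts is not established, so
  overdispersed Poisson is the (configurable) default.
* **VI features.** `latents %*% loadings + N(0, 0.316^2)` (signal-to-noise
  ~10 on unit-norm loading columns), plus a deterministic
  canopy-development offset per column: a fixed per-index weight times the
  normalized logistic trajectory at the column's flight day. The offset is
  constant within a column — it vanishes under centering and leaves latent
  recovery untouched — but separates flight days the way real indices
  track canopy growth, which is what makes stage-pooled biomass models
  learnable at all.
* **Images.** Two exact pixel populations (vegetation: high NIR, low red,
  cooler by `canopy_temp_offset` = 6 °C; soil: flat 0.25 reflectance) at a
  known cover fraction; 16 x 16 pixels by default.

What the generator does *not* emulate: genotype-by-environment
interaction, phenology differences among lines (the real study controlled
these by design), spectral soil heterogeneity, radiometric calibration
error, and LD that decays smoothly with distance rather than in blocks.
Passing tests therefore demonstrate that the estimators recover the
structures they model, not that field data meet those assumptions.

## Numerical choices and degenerate inputs

* REML non-convergence from every start is an error; variance ratios are
  bounded in $[e^{-10}, e^6]$, autocorrelations in $[-0.98, 0.98]$.
* Otsu requires two distinct finite values; constant images are errors.
* All-zero root profiles return the zero curve with a warning; fewer than
  5 depths is an error; reversed AUC bounds are errors.
* PLSR refuses constant columns and `ncomp` beyond the predictor rank;
  LOOCV folds reduce `ncomp` automatically if a fold loses rank.
* `qc_markers` removing every marker is an error, as is a monomorphic
  marker in an LD computation or an empty block in the LGEBV sum.
* Ties: Otsu ties break toward the lower threshold; `tune_ncomp` ties
  toward the smaller count; k-means uses 25 seeded starts.

## Problem sizes

The reference configuration — 200 lines, 504 markers, a 20-line x 6-rep
coring trial (120 plots), a 240-plot yield trial, 16 x 16-pixel images —
runs the full pipeline in a few minutes on one core, and the recovery test
suites (50-seed spatial-correlation recovery, 100-seed heritability
recovery, 20-seed block-recovery and scan-power sweeps) are sized to stay
comfortably inside a desktop R session. These sizes are the package's
chosen study conditions for validation, scaled down from field reality
(hundreds of plots, thousands of markers) while keeping every structural
feature the estimators rely on.

## Known limitations

* The hierarchical (genotype-level) P-spline is approximated by per-plot
  fits plus averaging; a shared-curve variant would borrow strength at
  low replication.
* The spatial model fits one trial at a time; multi-environment analysis
  is out of scope.
* The LD-block tolerance semantics are one documented interpretation of
  an under-specified published procedure.
* rrBLUP's single genome-wide shrinkage underestimates large-effect loci;
  the scan compensates by working on block variance, not effect size.
* Predicted-trait heritabilities are optimistic relative to measured-trait
  heritabilities, because prediction removes plot-level measurement noise
  before the variance decomposition — a property shared by any
  predict-then-map design, worth remembering when comparing scans.
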
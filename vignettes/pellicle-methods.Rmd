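---
title: "Models and methods behind pellicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pellicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pellicle)
```

`pellicle` covers the full path from a tray photograph of walnut kernels
to QTL intervals and heritabilities. This vignette explains the models in
each stage, the tunable parameters and their defaults, the design choices
made where the design was genuinely open, what the synthetic generators do
and do not emulate, and the known limitations.

## 1. Color measurement

### Color space

All phenotypes are expressed in CIE L\*a\*b\* under the D65 illuminant
(2° observer): L\* is lightness on 0–100, a\* the green–red axis, b\* the
blue–yellow axis. Historical usage in the seed-quality literature mixes
"Hunter Lab" and "CIE Lab" terminology; this package standardizes on
CIELAB — the modern, near-perceptually-uniform choice — and records the
space in every calibration model (`model$color_space`). Color differences
are CIE76, the plain Euclidean distance ΔE = ‖Lab₁ − Lab₂‖. CIEDE2000
would weight the axes perceptually but adds complexity with no benefit
for thresholding and regression; it is deliberately out of scope.

The reference conversions `srgb_to_lab()` / `lab_to_srgb()` follow the
standard sRGB transfer function and the D65 XYZ matrix. Round trips of
in-gamut colors are accurate to well under 0.5 ΔE; out-of-gamut requests
are clipped to the sRGB cube and flagged.

### White balance

The camera's illumination field is captured by photographing a uniform
white reference. Three correction variants are offered
(`white_balance_correct`):

* `"flatfield"` (default): each pixel is divided by the locally smoothed
  white-balance value and rescaled, `out = in × 255 / wb(x, y)`. This is
  the only variant that removes a *spatial* illumination gradient, which
  is exactly the failure mode a dome-lit tray rig suffers from. The WB
  image is Gaussian-smoothed (σ = 3 px, tunable) first so sensor noise is
  not injected into the corrected image.
* `"global"`: a single gain `255 / max(wb channel)` per channel — the
  classic per-channel white-point normalization. For a spatially uniform
  WB image this coincides with flat-fielding.
* `"subtract"`: adds the offset `255 − max(wb channel)` per channel, the
  literal reading of subtract-the-channel-maximum macro recipes. Offsets
  do not preserve black, so gains are the default.

A WB channel whose maximum (or, flat-field, any pixel) is zero aborts
with a degenerate-calibration error rather than dividing by zero.

### Checker calibration

`fit_calibration()` averages the pixels of each checker patch and fits
ordinary least squares from patch RGB (scaled to [0, 1]) to the reference
Lab values. Degree 1 uses terms {1, R, G, B} — an affine map, recovered
exactly (≤ 1e-9) when the data were generated by one; degree 2 adds
squares and pairwise products (10 terms), needed because the true
sRGB→Lab map is curved. The training error, the mean CIE76 ΔE across
patches, is stored as `fit_error` and is the honest yardstick for
downstream accuracy claims.

Two practical notes. First, at least as many patches as polynomial terms
are required (4 or 10), and an all-identical patch set is rejected as
rank-deficient. Second, patch *placement in color space* matters more
than patch count: the bundled `default_checker_reference()` concentrates
18 of its 24 patches in the brown/amber/yellow region where kernels
actually live (plus a 6-step neutral ramp), which brings the degree-2
fit to ≈ 0.5 ΔE where a full-gamut lattice of saturated primaries
plateaus near 2–4 ΔE. Users with a physical chart can supply its true
regions and Lab values via `read_checker_reference()`.

Whether a physical chart's reference values are Hunter Lab or CIELAB is
often unstated on older charts; the package treats supplied references
as CIELAB and leaves any conversion to the user.

### Segmentation and measurement

Kernels must be separated from the tray for *both* light and dark
kernels, so a luminance threshold is not enough: a pale kernel on a pale
tray vanishes. Instead a pixel is foreground when its ΔE to the tray
background color exceeds a threshold (default 12), which also catches
kernels that differ from the background only chromatically. The
background color defaults to the channel-wise median Lab over the tray
bounding box — kernels occupy a minority of the area, so the median is
robust — and can be overridden when the tray material is known.

The mask is cleaned by a 3×3 morphological opening, labelled into
8-connected components (EBImage's 4-connected labelling plus a
union-find merge of diagonal neighbours), and components below
`min_area` (default 0.5% of a well cell, rejecting debris) are dropped.
Components are assigned to the well whose grid cell contains their
centroid; the grid is an equal subdivision of the tray bounding box (the
commercial trays are rigid and photographed in a fixed frame, so
fiducial detection is unnecessary). A centroid exactly on a cell
boundary goes to the lower-index cell; fragments in one well merge into
one kernel; centroids outside the grid are flagged, never silently
dropped. Each kernel is summarized by the 10%-trimmed mean of L\*, a\*,
b\*, which removes specular glare pixels without biasing the bulk color.

A 2000×2000 tray image processes in a few seconds end to end; the test
suite asserts the full pipeline stays under 30 s per image.

### DFA grading

The ordinal DFA chart has four patches (Extra Light, Light, Light Amber,
Amber). To automate the by-eye score, classes are cut on L\* alone at
the midpoints between adjacent chart-patch lightnesses; taking the
chart patches at L\* 77.5/62.5/47.5/32.5 gives default cuts 70/55/40. A
kernel exactly on a cut takes the lighter class, and the mapping is
monotone by construction. The cuts are a surrogate for a visual
standard, so they are user-overridable (`dfa_thresholds`). Lot grading
applies the commercial tolerances: Extra Light, Light and Light Amber
each tolerate 15% of kernels darker than the grade, Amber tolerates
10%, beyond which the lot is darker than Amber. Mean DFA per tree is the
arithmetic mean of the ordinal classes — statistically impure but the
field's convention for this trait.

## 2. Phenotype analysis

Multi-year data are analysed with the linear model

y = μ + family + genotype(family) + year + family×year + β·age + ε,

fitted by least squares with Type-II sums of squares (`fit_color_anova`).
Type II suits the unbalanced family structure of a breeding program;
on orthogonal designs it reduces to the sequential decomposition and the
SS add to the total. Genotype is nested within family, which makes the
family and nested-genotype columns jointly over-parameterized; the
aliased columns are pivoted out and, if the Type-II computation cannot
proceed, the function falls back to Type-I SS with a warning naming the
problem. The family-by-year interaction is the family × year crossing.

Adjusted genotype means over years use the least-squares-means
convention: the two-way interaction model y = μ + genotype + year +
genotype×year + ε is fitted and each genotype's cell means are averaged
over year levels with *equal* weights (via `emmeans`). On balanced data
this is the plain genotype mean; with unequal cell sizes it removes the
year imbalance. Genotypes missing a year entirely are averaged over
their estimable cells only and flagged `incomplete`. Trait correlation
matrices are Pearson correlations across genotypes of these adjusted
means; zero-variance traits yield flagged `NA`s.

## 3. QTL mapping

### Genotype probabilities

The mapping populations are outbred bi-parental crosses scanned one
parental map at a time (pseudo-testcross): each parent's heterozygous
markers segregate 1:1, so the progeny genotypes are two-state ("A"/"H")
and the chromosome is a two-state Markov chain. `genotype_probs()`
computes P(genotype = A | marker data) on a grid (every 1 cM plus all
marker positions) in closed form by conditioning on the nearest
non-missing flanking markers — for a no-error Markov chain this equals
full forward-backward, and the tests verify that equivalence against a
matrix forward-backward oracle. A fully untyped individual sits at the
0.5 prior. Where older workflows fill missing genotypes by multiple
imputation and average over replicates, the exact conditional
expectation used here is deterministic and identical in expectation —
a deliberate design choice.

Haldane's map function r = (1 − e^(−2d/100))/2 (no interference) is the
default, matching the convention of the standard scan software; Kosambi
is available by flag.

### Scanning and significance

Haley-Knott regression: at each grid position, regress the phenotype on
P(A) and form LOD = (n/2) log₁₀(RSS₀/RSS₁). At a fully typed marker
this equals single-marker regression exactly (asserted to 1e-10 against
an `lm()` oracle). Genome-wide significance comes from permuting the
phenotype against the genotype rows (default 1000 permutations,
α = 0.05, seeded): the threshold is the empirical 95th percentile of the
genome-wide maximum LOD, and p-values use the plus-one rule
p = (1 + #{perm ≥ obs}) / (n_perm + 1). The suite verifies the
threshold's type-I error calibration (0.05 ± 0.03 over 200 null scans).

### Localization and multi-QTL models

The Bayes credible interval treats the normalized 10^LOD profile on a
group as a posterior over position and returns the smallest contiguous
grid window containing the peak with ≥ 95% mass, by exact enumeration
(ties broken toward higher mass; peak ties toward the leftmost
position). Physical coordinates are linearly interpolated from the
map's cM→bp relation. Simulations in the acceptance suite show ≥ 85%
coverage for a 1-SD QTL at n = 200 — slightly conservative-liberal
trade-offs at this sample size are expected for profile-mass intervals.

`fit_multi_qtl()` fits all detected QTL jointly (regression on their
probability columns) and reports drop-one LOD, p and R² = SS_drop/SS_total
per QTL plus the joint R²; positions under 1 cM apart trigger a
collinearity warning. `refine_positions()` improves positions by
coordinate-wise grid search, one QTL at a time with the others fixed,
iterating to a fixed point; the joint LOD is non-decreasing by
construction.

## 4. Pedigree genetics

`amatrix()` builds Wright's numerator relationship matrix by the tabular
method after topologically sorting the pedigree (cycles are an error).
`reml_h2()` fits the animal model y = Xτ + Zu + e, var(u) = σ²_A·A,
var(e) = σ²_R·I, by EM-REML: the data are projected onto error
contrasts (the orthogonal complement of X) and rotated to the eigenbasis
of the projected Z A Z′, where the model is a set of independent scalar
variance components and each EM step costs O(n). Convergence is declared
at a relative change below 1e-6 (cap 500 iterations; hitting the cap
flags the fit — typical when the σ²_A = 0 boundary is the optimum, where
EM approaches geometrically). Standard errors come from the inverse
expected information in the rotated model, h² = σ²_A/(σ²_A + σ²_R) by
the delta method. EM was chosen over Newton-type (AI) updates for its
monotone likelihood and boundary safety; the cost is slower tail
convergence, immaterial at desk scale. An optional incidence matrix Z
supports repeated records or group designs; with A = I and a
group-incidence Z the estimator provably reduces to the balanced one-way
ANOVA variance partition, which the tests assert.

Breeding values are BLUPs from Henderson's mixed-model equations at the
estimated components; as σ²_A → 0 they shrink to zero.

SNP quality control mirrors the standard PLINK order — individuals with
call rate < 0.90, then SNPs with MAF < 0.05 (a SNP exactly at 0.05 is
retained: the rule is strict "less than"), then SNPs failing a 1-df
chi-square HWE test (no continuity correction) at p < 0.001 — with
counts reported per step. LD is the squared Pearson correlation of
dosages over shared non-missing individuals, invariant to allele
flipping. Candidate-gene scans report every annotated gene whose 1-based
inclusive span intersects the closed ±100 kb window around a SNP,
sorted by distance (0 inside a gene). The window is a hard rule: a gene
224 kb away is not reported, whatever its biological appeal.

## 5. Synthetic generators and what they show

All generators are pure functions of their parameters and a seed.

* `render_tray()` paints elliptical kernels of known Lab at well centers
  on a uniform tray (default Lab (45, 0, −15), a bluish-gray that
  contrasts both light and dark kernels), converts through the same
  sRGB model the calibration assumes, applies a shared multiplicative
  illumination gradient (default ±5%) to tray *and* WB image — so WB
  correction, not rendering luck, is what the tests exercise — and adds
  Gaussian 8-bit noise (default σ = 2). Ground truth is the painted
  (gamut-clipped) Lab per well.
* `simulate_cross()` draws two-state chromosomes by the Haldane Markov
  chain (n = 168 by default, the size of a typical walnut bi-parental
  population), plants additive QTL in residual-SD units and masks
  genotypes at a given missing rate.
* `simulate_pedigree_phenotypes()` breeds disjoint random pairs for a
  set number of generations from unrelated founders (defaults: 20
  founders, 2 generations, families of 10, true h² 0.56) under the
  additive infinitesimal model with Mendelian-sampling variance
  h²σ²/2.

What passing tests on these fixtures *show*: the calibration, geometry,
probability, scanning, interval, REML and QC code paths are correct
against independent oracles, and the statistical procedures are
calibrated under their own assumptions. What they *do not* show: real
kernels are not flat-colored ellipses (no veining, speckling, shadows or
shape variation), real maps have genotyping errors and segregation
distortion the no-error HMM ignores, and real pedigrees contain
inbreeding and assortative mating the generator omits (random sib
matings do occur in the generator and are one reason single-replicate
h² estimates sit slightly below the simulated truth). Accuracy on real
photographs depends on chart quality and illumination stability in ways
no simulation can certify.

## 6. Numerical and interface choices

* Thresholds and defaults: ΔE threshold 12, min_area 0.5% of a cell,
  DFA cuts 70/55/40, scan step 1 cM, 1000 permutations at α = 0.05,
  Bayes coverage 0.95, QC cuts 0.90/0.05/0.001, gene window 100 kb,
  EM tolerance 1e-6.
* Tie-breaks: boundary centroids to the lower-index well; boundary L\*
  to the lighter DFA class; LOD peak ties to the leftmost position;
  MAF exactly at the threshold retained; window intersection closed on
  both ends.
* Degenerate inputs fail loudly: zero WB channels, constant phenotypes,
  insufficient or collinear checker patches, cyclic pedigrees, empty
  lots, all-filtered SNP panels.
* Genomic coordinates are 1-based inclusive (GFF3 convention)
  throughout the genetics module; image coordinates are 0-based
  half-open rectangles.
* All tabular I/O is UTF-8 CSV with `#`-prefixed metadata headers
  (tool version, config hash, seed), JSON for models and specs, so runs
  are diffable and reproducible byte for byte given the same seed.

Problem sizes in the shipped tests and acceptance script (20 rendered
trays, 300-permutation thresholds in the suite and 1000 in the script,
200-replicate coverage studies, n ≈ 620 pedigrees) were chosen as the
smallest sizes at which the statistical assertions are stable; they are
the package's own test design, and all run on one CPU in minutes.

## Known limitations

Single-tray geometry is assumed rigid (no fiducial detection); JPEG
inputs are treated as sRGB without ICC profile handling; the DFA cuts
are a lightness-only surrogate for a visual standard; only two-state
pseudo-testcross segregation is supported (no four-allele F1 models);
EM-REML fits a single additive variance component (no dominance,
maternal or repeated-measure components); and GWAS-style mixed-model
association (kinship + structure covariates) is out of scope by design.
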
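---
title: "Layer-resolved OCT texture and thickness analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved OCT texture and thickness analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octtexture)
```

## Scope and rationale

`octtexture` quantifies *how retinal tissue looks*, not only how thick it
is. In coherent imaging such as optical coherence tomography (OCT), the
speckle pattern inside a tissue layer carries information about its
microstructure: subtle cellular or extracellular change can alter the
spatial statistics of the backscattered signal before any measurable
thinning occurs. The package operationalises this idea as a pipeline:

1. a segmented OCT volume (seven interface surfaces delimiting six
   retinal layers: NFL-GCL, IPL, INL, OPL, ONL, IS/OS) is collapsed,
   layer by layer, into **mean-value fundus (MVF) images** — en-face
   projections where each pixel averages the A-scan samples between the
   layer's two bounding interfaces;
2. each MVF image is summarised by a **20-feature grey-level
   co-occurrence matrix (GLCM) suite** (Haralick's thirteen, plus
   autocorrelation, maximum probability, cluster shade/prominence,
   INN/IDN, and dissimilarity);
3. per-layer **thickness** is measured as the distance between bounding
   interfaces, with the total retina being the exact sum of the six
   layers;
4. a **longitudinal two-group analysis** compares a diseased (T2D)
   group against controls at each follow-up week: texture endpoints by
   ANCOVA with the week-0 value as a quantitative covariate, and
   percent-of-baseline thickness by a Shapiro-Wilk-gated Student's
   t / Mann-Whitney test, at a 5% significance level.

Because no public data accompany this design, the package also ships a
first-class synthetic-data module: speckle phantoms and full two-group,
four-timepoint cohorts with exact ground truth, which every pipeline
stage is tested against.

## The MVF projection rule

The only substantive choice in the projection is which axial samples
belong to a layer bounded by sub-pixel interfaces $u \le l$. We include
the 0-based integer depths in the half-open interval
$[\lceil u \rceil, \lceil l \rceil)$, with no partial-voxel weighting.
Two properties motivated this rule:

* adjacent layers **partition** each A-scan — no voxel is counted twice
  and none is silently dropped at an interface;
* the rule is exactly reproducible across implementations, which
  fractional-weighting schemes tend not to be.

Pixels where a layer contributes fewer than `min_samples` (default 1)
samples are masked out rather than zero-filled, so texture statistics
never mix structural zeros with tissue signal. No lateral smoothing,
contrast normalisation, or vessel-shadow handling is applied to MVF
images before texture analysis: the least-intervention default makes
any preprocessing an explicit, visible configuration choice.

## GLCM construction and the 20 features

The GLCM $p(i,j)$ is the empirical probability of observing grey levels
$i$ and $j$ at the two ends of a fixed pixel offset, accumulated over
every pixel pair whose endpoints both lie inside the validity mask.
Defaults (all overridable in one `glcm = list(...)` argument):

| parameter | default | why |
|---|---|---|
| grey levels $N_g$ | 64 | standard compromise between sparsity and discriminability for images of $\ge$ a few thousand pixels |
| quantization | per-image min–max | makes every feature invariant to positive affine intensity transforms (gain/offset drift between sessions) |
| distance $d$ | 1 px | nearest-neighbour transitions carry most speckle information |
| directions | (0°, 45°, 90°, 135°), summed | orientation-averaged; with the symmetric option this covers all 8 neighbours |
| symmetric | yes | transpose added before normalisation, the common Haralick convention |

Levels are 1-based ($1..N_g$). Entropies are base-2 (bits) with
$0\log 0 := 0$. Three conventions keep the feature vector finite on
degenerate inputs, and are tested: `correlation` $:= 1$ and IMCI $:= 0$
when a marginal is constant (single-level image), and the IMCII
radicand is clamped at zero. Two formula ambiguities in the classical
feature tables are resolved the standard way: *sum variance* is centred
on the *sum average* (not the sum entropy — the well-known typo), and
*difference variance* is the variance of the difference distribution
about its own mean (not about zero). "Homogeneity" in the literature
can denote either the angular second moment or the inverse difference
moment; both are always computed under their canonical names, and the
alias map (`texture_feature_aliases()`) records the compound names.

The implementation is verified feature-by-feature against an
independent literal-loop brute-force oracle (in the test suite) to
below $10^{-10}$ relative error on random GLCMs at $N_g \in \{4, 16,
64\}$, and against fully hand-enumerated worked examples (a 4-pixel row
image and a checkerboard).

## Thickness and percent of baseline

Thickness maps are interface differences, so the six per-layer maps sum
*identically* (not approximately) to the first-to-last interface
distance — a telescoping identity the tests exercise on random valid
boundary sets. Per-eye summaries are unweighted means over the full
scanned region; no ETDRS-style sectorisation is applied, since the
study design images one predefined retinal region per eye.
Longitudinal thickness is expressed per animal as
$100 \times \mathrm{value}_t / \mathrm{value}_0$. Boundaries are
floating point (sub-pixel), because learned segmenters produce
sub-pixel interfaces and rounding would bias the thinnest layers.

## Statistical model

One model per (measure, layer, week) — mirroring a per-timepoint
analysis rather than a repeated-measures model:

$$y_{t} = \beta_0 + \beta_1\,\mathrm{group} + \beta_2\,y_{0} + \varepsilon,$$

group coded control = 0, T2D = 1, fitted by least squares; the reported
effect is $\hat\beta_1$ (the baseline-adjusted group difference) with
its $F = t^2$ statistic. Animals missing either timepoint are dropped
(complete case) and counted. With `baseline_week = NULL` the model
collapses to the pooled two-sample t-test, which the tests verify
numerically. Thickness-style endpoints use Student's t (pooled
variance) when both groups pass Shapiro-Wilk at 5%, otherwise
Mann-Whitney (exact when both $n \le 20$ without ties, else the
normal approximation with continuity and tie corrections). No
multiplicity correction is applied by default — matching a
per-comparison reporting style — with Benjamini-Hochberg available
behind `fdr = TRUE`. Both tests are calibrated by Monte-Carlo in the
tests: empirical type-I error within [0.04, 0.06] at $\alpha = 0.05$
over 2,000 null replicates each.

## The phantom model: what it emulates, and what it does not

Phantoms are stacks of six layers between seven interfaces, plus
background margins:

* **Geometry.** All seven interfaces share one smooth random undulation
  surface (bilinear interpolation of a coarse Gaussian grid, amplitude
  2 px by default). Because the undulation is rigid, configured layer
  thicknesses are reproduced *exactly* by the ground-truth boundaries —
  the generator is its own oracle for the thickness stage. Default
  test-scale geometry is 64×64×256 voxels (the full-acquisition
  512×512×1024 geometry is one configuration away); layer thicknesses
  default to retina-like proportions of the axial range, and
  reflectivities alternate bright/dark the way plexiform and nuclear
  layers do, so every interface carries axial contrast.
* **Speckle.** Within a layer, intensity = mean reflectivity × a
  unit-mean multiplicative field: gamma white noise, laterally smoothed
  with a Gaussian kernel of the configured correlation length, then
  re-standardised to the configured contrast (std/mean) and clipped at
  zero. The re-standardisation is deliberate: it decouples the
  first-order statistic (contrast) from the second-order one
  (correlation length), which are exactly the two axes GLCM features
  measure. The cost is that the smoothed field's marginal is no longer
  exactly gamma, and zero-clipping shifts the mean by $\ll 1\%$ at
  realistic contrasts — both acceptable for a validation phantom.
  Axial correlation is fixed at one pixel (each depth plane independent).
* **Not modelled.** No point-spread function, attenuation with depth,
  vascular shadowing, motion, or registration error between weeks.
  Passing tests therefore demonstrate that the pipeline recovers known
  texture/thickness effects under controlled speckle statistics — not
  that it is robust to every artefact of in-vivo acquisition.

A monotonicity property ties the phantom to the features: across a
5-point sweep of correlation length (20 seeds per point), GLCM
correlation and IDM increase and contrast decreases, monotonically.

## Cohort simulation

A cohort draws, per animal, persistent multipliers on layer thickness
(SD 3%), speckle correlation length (log-SD 0.10), contrast (log-SD
0.05) and reflectivity (log-SD 0.05). Persistence across weeks is what
makes the baseline covariate informative — without it the ANCOVA would
degenerate to a t-test. A small per-scan thickness jitter (SD 1%)
emulates repositioning and segmentation variability between sessions,
so week-to-week thickness ratios are non-degenerate. Group × week
effects multiply thickness and/or texture parameters of the T2D group
only; week 0 is pre-induction and carries no effects by construction
(enforced at configuration time).

`example_t2d_effects()` provides a ready-made pattern emulating early
diabetic retinal change: thinning of the inner/outer layers from week 4
to 12 (a few percent to ~14% of baseline, strongest in the INL and
IS/OS), an *increased* correlation length in the IPL and a *decreased*
one in the IS/OS from week 8 — producing opposite-signed texture
contrasts in the two layers, the qualitative signature the pipeline is
expected to recover. True in-vivo effect magnitudes on texture features
are not recoverable without raw scans and acquisition settings, so the
injected texture effects are calibrated to reproduce signs and
significance patterns, not absolute feature values.

## Problem sizes and numerical choices

The validation studies use deliberately modest sizes, chosen so that a
full run remains a desk-scale computation while keeping Monte-Carlo
noise well below the decision thresholds: directional-recovery and null
cohorts at $n = 15$/group on 64×64×256 phantoms, thinning recovery at
$n = 20$/group (boundaries only — thickness needs no speckle),
statistical calibration at 2,000 replicates with $n = 20$/group. With
2,000 replicates the standard error of an empirical rejection rate at
5% is about 0.5 percentage points. For the null-cohort significance
fraction, note that the 20 features of one layer are computed from the
same MVF image and are strongly correlated, so the effective number of
independent cells is close to layers × weeks rather than the nominal
feature count; the test band (fraction ≤ 0.15) accounts for that
clustering rather than assuming 360 independent tests.

Other numerical conventions: all randomness flows through explicit
seeds (generators are pure functions of configuration + seed; per-scan
seeds derive from the cohort master seed); intensities are rounded to
the configured bit depth so phantom volumes round-trip bit-exactly
through non-compressed TIFF; boundary CSVs store sub-pixel depths as
decimal text, exact for integer depths and to ~15 significant digits
otherwise; the boundary validator reports *all* ordering/range
violations rather than failing on the first.

## Known limitations

* The gradient-based `fallback_segment()` is a convenience for running
  phantoms "blind"; it is not a retinal segmenter and carries no claim
  about segmentation quality on clinical data. The pipeline's intended
  input is an externally produced segmentation.
* GLCM feature values depend on quantization depth, distance and
  direction set; comparisons against any published absolute values must
  sweep these settings. The defaults here are the field's common
  choices, not a claim about any particular study's settings.
* MVF images are not registered between timepoints; the longitudinal
  design assumes a consistent imaging region per animal.
* The statistics stage treats endpoints as exchangeable scalar
  measures; it does not model within-animal correlation beyond the
  baseline covariate.
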
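# octtexture

Layer-resolved texture and thickness analysis of volumetric retinal
OCT.

## The problem

Early retinal disease — diabetic retinopathy in particular — can alter
the microstructure of individual retinal layers before any clinically
visible lesion or measurable functional deficit appears. In optical
coherence tomography (OCT), that microstructure leaves a statistical
fingerprint in the speckle pattern of each layer. `octtexture` is for
researchers running longitudinal imaging studies (typically rodent
models: two groups, several timepoints) who want to quantify that
fingerprint, alongside conventional thickness measurements, and test
for group differences with baseline-adjusted statistics.

## What it computes

Given a segmented OCT volume (seven interface surfaces delimiting the
six structures NFL-GCL, IPL, INL, OPL, ONL and IS/OS), the package:

1. **Projects** each layer to a mean-value fundus (MVF) image: each
   en-face pixel is the mean of the A-scan samples between the layer's
   bounding interfaces (half-open interval
   $[\lceil u\rceil, \lceil l\rceil)$ on integer depths, so adjacent
   layers partition the A-scan).

2. **Quantifies texture** with a masked, direction-averaged symmetric
   grey-level co-occurrence matrix,
   $p(i,j)$ = probability of the grey-level pair $(i, j)$ at offset
   distance $d$, and computes 20 features from it: the Haralick set
   (angular second moment, contrast, correlation, sum of squares,
   inverse difference moment, sum average/variance/entropy, entropy,
   difference variance/entropy, IMCI, IMCII), autocorrelation, maximum
   probability, cluster shade and prominence, INN, IDN, and
   dissimilarity. Defaults: $N_g = 64$ levels, per-image min–max
   quantization (affine-invariant), $d = 1$, four directions summed,
   symmetric; entropies in bits.

3. **Measures thickness** per layer and for the total retina (exactly
   the sum of the six layers), and expresses follow-up values as
   percent of each animal's week-0 baseline.

4. **Tests group differences** per (measure, layer, week): ANCOVA
   $y_t = \beta_0 + \beta_1\,\mathrm{group} + \beta_2\,y_0 +
   \varepsilon$ for texture endpoints, and a Shapiro-Wilk-gated
   Student's t / Mann-Whitney test for percent-of-baseline thickness,
   at $\alpha = 0.05$ (Benjamini-Hochberg optional).

A synthetic-data module generates speckle phantoms and entire
two-group, four-timepoint cohorts with exact ground-truth boundaries
and configurable thinning/texture effects, so the whole pipeline can be
exercised and validated without animal data.

## Worked example

```r
library(octtexture)

# a 64 x 64 x 256 speckle phantom with known boundaries
ph  <- generate_phantom(phantom_config(n_bscans = 64, n_ascans = 64,
                                       depth = 256, seed = 42))

# mean-value fundus projection of the inner plexiform layer
mvf <- project_mvf(ph$volume, ph$boundaries, "IPL")

# GLCM texture
g <- compute_glcm(quantize(mvf, n_levels = 64))
g
#> <glcm> 64 x 64, d = 1, 4 direction(s), symmetric, 16002 pairs
f <- texture_features(g)
round(unclass(f)[c("contrast", "correlation",
                   "inverse_difference_moment", "entropy")], 4)
#>                  contrast               correlation
#>                   31.7521                    0.7862
#> inverse_difference_moment                   entropy
#>                    0.2007                    9.5425

# thickness: six layers plus their exact total
scan_thickness(ph$boundaries)
#>     layer mean_thickness
#> 1 NFL-GCL           15.0
#> 2     IPL           27.5
#> 3     INL           17.5
#> 4     OPL           10.0
#> 5     ONL           45.0
#> 6   IS/OS           22.5
#> 7   total          137.5
```

A GLCM contrast of ~32 with correlation ~0.79 reflects the phantom's
default speckle (contrast 0.3, lateral correlation length 1.2 px);
smoother texture drives correlation/IDM up and contrast down. The
thickness rows are exact because the generator's boundaries are ground
truth.

For a full longitudinal study, generate a cohort and run the pipeline:

```r
eff <- example_t2d_effects()   # thinning + IPL/IS-OS texture changes
cfg <- cohort_config(n_control = 10, n_t2d = 10, effects = eff, seed = 1)
coh <- generate_cohort(cfg, dir = "cohort_out")     # TIFF + CSV + manifest
res <- run_pipeline(coh$manifest_path, out_dir = "analysis_out")
subset(res$stats, significant)
```

`run_pipeline()` writes `features.csv` (GLCM settings echoed in the
header), `thickness.csv`, `stats.csv`, `summary.csv` and
`run_metadata.json`, and is deterministic given identical inputs.

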
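---
title: "Processing touch-based multispectral leaf images: from raw counts to treatment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing touch-based multispectral leaf images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(phenoleaf)
```

## The problem

Touch-based leaf imagers capture a single soybean leaflet held flat against
a grid of fine nylon threads, under controlled LED illumination, in four
bands (blue 460 nm, green 525 nm, red 630 nm, NIR 850 nm). Two artifacts
stand between the raw frames and a usable whole-leaf vegetation index:

1. the LED boards illuminate the field unevenly, and
2. the thread grid occludes a few percent of the leaf with bright,
   non-tissue pixels.

`phenoleaf` implements the full chain that removes both and extracts the
statistic of interest — whole-leaf mean NDVI — plus the group-comparison
layer used to ask whether the index separates experimental treatments
(typically nitrogen levels). Because the device imagery that motivated this
design is not public, the package ships a synthetic-scene generator with
complete ground truth, and every stage is validated against it.

## Stage by stage

### 1. Flat-field calibration

`flat_field()` divides each raw band by the matching band of a white-panel
image, pixel by pixel: `cal = raw / max(white, epsilon)`. The white image
captures exactly the illumination pattern (it is reusable across samples,
since the LEDs do not move). Two numerical guards that the idealized
quotient needs in practice:

* `epsilon` (default 1 count) floors the denominator so vignetted corners
  cannot amplify noise without bound;
* `clip_max` (default 2.0 reflectance) caps the quotient — specular thread
  highlights can exceed the white panel, and unbounded ratios destabilize
  the texture filtering downstream. Clipped pixels are counted and reported.

Calibration is exact up to sensor quantization: on noise-free synthetic
scenes the recovered reflectance is within `2 / 2^bit_depth` of truth
wherever the white signal is healthy, and the operation is exactly
scale-equivariant before clipping.

### 2. Leaf segmentation

The background felt is nearly black and spectrally neutral, so the ratio
`Greenness = green^2 / (red * blue)` sits near 1 on background and well
above 1 on green tissue. `greenness_map()` computes it with an `epsilon`
floor (default 0.01 reflectance) marking pixels whose denominator is too
dark to trust; `threshold_leaf()` cuts it — by default with Otsu's
criterion on the valid values, since the bimodal separation is wide and a
fixed cut would need per-setup tuning (a `fixed` method with threshold 1.5
is available). `refine_mask()` then applies a morphological closing (disc,
radius 2 px) and keeps the single largest connected component. Thread
pixels crossing the leaf are *not* excluded here: a Greenness cut harsh
enough to remove bright neutral threads would also bite into pale leaf
tissue, so thread handling is deferred to the dedicated detector. On
default synthetic scenes the leaf mask IoU against truth exceeds 0.99.

### 3. Thread detection with a Gabor filter bank

The grid runs at ±45° across the frame. A complex Gabor filter — a
sinusoidal carrier of wavelength 5 px under an elongated Gaussian envelope
(spatial aspect ratio 0.1) — responds strongly to line-like structure of
matching orientation and period. The envelope sigma follows the standard
1-octave closed form, sigma = lambda (1/pi) sqrt(ln2/2) * 3 ≈ 2.81 px. The
implementation correlates via FFT with symmetric boundary padding and is
tested to 1e−6 against direct spatial correlation; with DC correction the
response to constant input is zero to machine precision.

`thread_mask()` runs the filter on the calibrated NIR band (the strongest
leaf/thread contrast) at both grid orientations, thresholds each magnitude
map at `rel_threshold` (default 0.25) times its 99th percentile, unions the
two, and dilates by 1 px. The threshold is *relative* because an absolute
magnitude cut is tied to one intensity scale; a relative cut transfers
across bit depths and reflectance-scale input.

**Known limitation at simulation scale.** The filter's parameters are
calibrated to device-resolution imagery (~1920×1200, grid period of order a
hundred pixels). The synthetic scenes are deliberately small (480×600,
grid period 24 px), and at that scale the filter's geometry is coarse
relative to the grid: the lateral response band around a 1.4-px thread is
~9–11 px wide at a quarter-peak cut, and the envelope extends ±84 px along
its orientation, so leaf-edge responses reach deep into the frame. The
consequences, measured and accepted rather than hidden: detection *recall*
on threads is essentially 1.0 (which is what NDVI accuracy requires — a
missed thread pixel biases the index, an over-masked tissue pixel is merely
re-synthesized from tissue), but the mask is several times wider than the
true grid, so its IoU against the (1-px-dilated) truth plateaus near 0.5,
and on thread-free scenes the leaf-edge response marks an appreciable
fraction of the leaf. At device resolution the same configuration is
proportionally ~4× tighter. Users working at small scales can raise
`rel_threshold` (higher precision, lower recall) or enlarge the simulated
grid period; the package keeps recall-favoring defaults because the
downstream index is copy-inpainted from true tissue either way.

### 4. Exemplar-based inpainting

Masked pixels are reconstructed by priority-ordered patch copying, the
classic exemplar scheme: confidence `C(p)` (how much of the patch around a
front pixel is already known) times a data term `D(p)` (how strongly an
image isophote hits the fill front) decides which pixel to fill next; the
best-matching fully intact 9×9 source patch — minimum SSD over the already
known pixels of the target patch — is then copied into the unknown
positions. Two data terms are provided: the default `gradient` form uses
the strongest isophote among known patch pixels; the `tensor` form uses the
minor eigen-direction of the patch's structure tensor scaled by the root of
its dominant eigenvalue. They order straight-edge fills identically; the
tensor form is smoother on noisy texture.

Three design choices matter for spectral integrity:

* **All four bands fill jointly** — one fill order, one SSD summed across
  bands. Filling bands independently could pair a red value from one spot
  of the leaf with a NIR value from another and corrupt the NDVI of the
  synthesized pixels.
* **Sources come only from intact leaf tissue** (`leaf AND NOT target`),
  never from background or masked pixels, and candidate patches must be
  entirely intact — every filled value is verifiably a copy of real tissue.
* **Thread pixels far from the leaf are not synthesized** — targets outside
  the leaf's `patch_size` neighbourhood are set to background 0.

The search is exhaustive over admissible source centers (ties broken at
the smallest row-major index, making runs reproducible), with the inner
loop in C++. A guard errors out if iterations exceed the number of target
pixels, which would indicate a front-update defect; the remaining-pixel
count strictly decreases each iteration.

Patch size 9 is the cost/quality point the exemplar literature and the
device workflow both use; it also sets the feasibility constraint: a
source patch must fit between masked grid lines. At the default synthetic
grid (period 24 px) combined with the wide detected mask, only a handful of
admissible patches remain — the package raises a clear "mask too dense"
error rather than degrading silently. The end-to-end validation therefore
runs at a grid period of 40 px on 256×320 frames (~10% true occlusion),
where thousands of source patches are available.

### 5. NDVI and aggregation

`ndvi_map()` computes `(NIR − red) / (NIR + red)` over the leaf mask
(denominator floored at 1e−6, values clamped to [−1, 1]);
`mean_index()` averages valid pixels into one number per leaf;
`aggregate_ndvi()` averages leaves per plant (top + bottom leaf) or per
plot (four leaves), mirroring the experimental designs this device serves.

### 6. Treatment statistics

`two_sample_ttest()` defaults to the pooled-variance Student test — the
conventional reading of an unqualified "two-sample t-test" — with Welch
available; p-values are two-sided and reported raw (single comparisons, no
multiplicity correction). Degenerate inputs follow fixed conventions:
both samples constant and equal gives p = 1; constant but different gives
p = 0 with a `degenerate` flag. `ols_fit()` regresses the index on a
laboratory reference (e.g. measured nitrogen content) and reports slope,
intercept and R². Both return broom-style objects with `tidy()` /
`glance()` methods and `autoplot()`s.

The field-trial comparison unit is the plot by default
(`stats$level = "plot"`): four leaves per plot are averaged before testing,
matching how such trials are laid out; `leaf` and `plant` levels are
config choices.

## The synthetic-scene generator

`scene_params()` + `render_scene()` emulate what the device sees:

* an ovate leaf outline (tapered half-width profile with a tip), seeded
  jitter of position/aspect/rotation, area ≈ a third of the frame;
* a smooth multiplicative illumination field — a centered Gaussian plus a
  linear ramp, normalized to unit mean, amplitude `illum_strength`
  (default 0.25) — standing in for two diffused LED boards;
* mean band reflectances (defaults: blue 0.10, green 0.24, red 0.12,
  NIR 0.60 — plausible green-leaf values, config-exposed rather than
  asserted as biology) with a smooth multiplicative texture field
  (sd 0.04) *shared across bands*;
* a ±45° thread grid (period 24 px, width 2 px, reflectance 0.85) drawn
  over leaf and background alike;
* additive Gaussian read noise (sd 80 counts at 16-bit, ≈0.1% of full
  scale) and quantization at 8 or 16 bits.

Because the texture field is shared across bands, per-pixel NDVI is
constant over the leaf and the scene's true mean NDVI is controlled
exactly. `generate_experiment()` uses that: it draws each leaf's true NDVI
from `Normal(group mean, between_sd)` and solves the red reflectance with
NIR fixed (`red = nir (1 − d) / (1 + d)`), defaulting to the two-treatment,
10-replicate design with means 0.55 / 0.70 and between-leaf sd 0.05.

What the generator does *not* emulate — venation with band-dependent
spectra (so within-leaf NDVI structure), specular highlights, optical
blur, leaf curvature, multi-leaf scenes — bounds what passing tests show:
they validate the processing chain's correctness and calibration, not its
performance on real tissue heterogeneity. In particular, with uniform
per-pixel NDVI the end-to-end recovery error (≤ 1e−4 observed) mostly
reflects that copy-inpainting from correct tissue cannot bias a spatially
constant index; on real leaves the inpainting error would scale with the
local NDVI variation under the grid.

## Numerical choices and degenerate inputs

* Validation problem sizes: 50 default scenes for segmentation, 5 + 10 for
  thread detection, 20 scenes at 256×320 for end-to-end recovery, 500
  scalar replicates for null calibration of the t-test and 200 for power.
* Otsu's threshold maximizes between-class variance over a 256-bin
  histogram; between well-separated clusters the maximizer is a plateau,
  so only the achieved variance (not the cut position) is meaningful.
* Ties everywhere break toward the smallest row-major linear index.
* Calibrated rasters are written as genuine 32-bit-float TIFFs by a small
  internal writer, since values may exceed 1; reading uses the `tiff`
  package throughout.
* Per-seed determinism is end to end: scenes, the fill order, and the
  records CSV are byte-stable across reruns.

## A minimal session

```{r example, eval = FALSE}
library(phenoleaf)

base <- scene_params(height = 256, width = 320, thread_spacing = 40)
design <- generate_experiment(n_per_group = 10, base = base, seed = 1)
dir <- tempfile()
write_experiment(design, dir)

cfg <- pipeline_config(stats = list(variant = "student", level = "leaf"))
res <- run_experiment(file.path(dir, "manifest.csv"), cfg)

res$records      # one row per leaf: mean NDVI, area, thread coverage
res$stats        # treatment contrast: t, df, p
plot_ndvi_groups(res$records)
```
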
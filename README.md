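# phenoleaf

Image-processing and statistics toolkit for **touch-based multispectral
leaf phenotyping**. Devices of this class hold a single soybean leaflet
flat against a grid of fine nylon threads and image it in four bands
(blue 460, green 525, red 630, NIR 850 nm) under LED illumination. Turning
those frames into a per-leaf nitrogen proxy requires a processing chain,
which this package provides end to end:

1. **Flat-field calibration** — `cal = raw / white`, cancelling the uneven
   LED illumination with a white-panel reference;
2. **Leaf segmentation** — threshold the ratio
   `Greenness = green² / (red · blue)` (≈1 on the neutral black felt, ≫1 on
   tissue; Otsu by default), then morphological closing and
   largest-component selection;
3. **Thread detection** — a complex 2-D Gabor filter bank (wavelength 5 px,
   spatial aspect ratio 0.1, orientations 45°/135°) whose response
   magnitude flags the thread grid, cut at a relative threshold
   (0.25 × the 99th-percentile magnitude);
4. **Exemplar-based inpainting** — priority-ordered (confidence × data
   term) copying of best-matching intact 9×9 leaf patches into the masked
   pixels, all four bands jointly, so the occluded tissue is re-synthesized
   from real tissue;
5. **Whole-leaf NDVI** — `NDVI = (NIR − red) / (NIR + red)` averaged over
   the leaf, aggregated to plant or plot level;
6. **Treatment statistics** — pooled two-sample *t* tests between
   treatment groups and OLS regression of the index against laboratory
   reference measurements, returned as broom-style objects
   (`tidy()`, `glance()`, `autoplot()`).

Because device imagery of this kind is typically confidential, the package
includes a **synthetic-scene generator** (`scene_params()`,
`render_scene()`, `generate_experiment()`) that produces raw/white image
pairs with complete ground truth — leaf mask, thread mask, per-band
reflectance, true mean NDVI — so every stage and the statistics layer are
testable and every headline number below is reproducible from a seed.

## Worked example

Simulate a two-treatment experiment (true NDVI means 0.55 vs 0.70,
between-leaf sd 0.05), run the full pipeline per leaf, and test the
contrast:

```r
library(phenoleaf)

base <- scene_params(height = 256, width = 320, thread_spacing = 40)
design <- generate_experiment(n_per_group = 3, base = base, seed = 1)
dir <- tempfile()
write_experiment(design, dir)

cfg <- pipeline_config(stats = list(variant = "student", level = "leaf"))
res <- run_experiment(file.path(dir, "manifest.csv"), cfg)
res$records
#> # A tibble: 6 × 8
#>   sample_id mean_ndvi leaf_area_px thread_coverage treatment plot_id plant_id
#>   <chr>         <dbl>        <int>           <dbl> <chr>     <chr>   <chr>
#> 1 low_01        0.519        25655           0.511 low       low     low_01
#> 2 low_02        0.559        22791           0.504 low       low     low_02
#> 3 low_03        0.508        23798           0.513 low       low     low_03
#> 4 high_01       0.780        22982           0.520 high      high    high_01
#> 5 high_02       0.716        23972           0.496 high      high    high_02
#> 6 high_03       0.659        22634           0.510 high      high    high_03
res$stats
#> # A tibble: 1 × 10
#>   kind  level group_a group_b statistic    df p_value estimate   n_a   n_b
#> 1 ttest leaf  high    low          4.97     4 0.00767    0.190     3     3
```

Each `mean_ndvi` is the whole-leaf average after calibration,
segmentation, thread removal and inpainting; it lands within ~1e−4 of the
scene's known true NDVI. `thread_coverage` is the fraction of leaf pixels
the Gabor detector masked (the detector favors recall — see the vignette
for why the mask is wide at simulation scale). The *t* row reports the
pooled-variance contrast between treatments: here the 0.15 NDVI group
shift is detected at p ≈ 0.008 with only three leaves per group.

The classic textbook pair gives the expected test behaviour:

```r
two_sample_ttest(c(1, 2, 3, 4), c(3, 4, 5, 6))
#> Two-sample t-test (student): t = -2.1909, df = 6, p = 0.07099, diff = -2.0000
```

A thin CLI over the same functions ships in `inst/scripts/phenoleaf`
(subcommands `simulate`, `calibrate`, `segment`, `threads`, `inpaint`,
`ndvi`, `stats`, `run`; YAML config via `pipeline_config()` /
`write_config()`).

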
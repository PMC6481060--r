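# brightseg

Total cell area segmentation in brightfield microscopy images.

Quantitative fluorescence microscopy often needs the **total area occupied
by cells** — for mean fluorescence intensity per cell area, integrated
density, and similar statistics — but the usual segmentation route
(thresholding a fluorescence channel) fails when no whole-cell label is
present. `brightseg` separates cells from background using **only the
brightfield channel**, exploiting the fact that cell interiors are rich in
intensity edges (organelles, membrane rims) while a well-illuminated
background is smooth.

The pipeline is a fixed chain of classical operations:

1. **Histogram equalization** (square-root–weighted CDF by default, 0%
   saturation) to normalize contrast;
2. **Canny edge detection** — Gaussian-derivative gradient with
   σ = *gaussian kernel radius*, non-maximum suppression, dual-threshold
   hysteresis (defaults low = 0.1, high = 8.0; the high threshold is the
   most influential tunable);
3. **Circular maximum filter** (radius from the calibration table) that
   fuses the dense intracellular edge map into solid regions;
4. **Binary closing** (10 iterations, count 3, padded) to fill remaining
   holes;
5. **Binary opening** (10 iterations, count 3) to remove debris;
6. optional **erosion** (2 iterations, count 3, padded) compensating the
   dilation introduced by the maximum filter.

The morphology uses ImageJ-compatible *count* semantics: a pixel flips
only when at least `count` of its 8 neighbors differ. The two
resolution-dependent radii are selected from the pixel calibration
(nm/pixel):

| Pixel size (nm/px) | Gaussian kernel radius | Maximum filter radius |
|--------------------|------------------------|-----------------------|
| 90–180             | 1.75                   | 5                     |
| 180–270            | 1.5                    | 2.5                   |
| 270–360            | 1.25                   | 1.67                  |
| 360+               | 1                      | 1.25                  |

The result is one foreground mask of the total cell area (not per-cell
instances), usable directly as a region mask for fluorescence
quantification. A synthetic scene generator with ground truth and
evaluation metrics (Dice, IoU, signed area difference) supports testing
and calibration.

## Worked example

```r
library(brightseg)

# a synthetic 256x256 brightfield field of view with known ground truth
sc  <- generate_scene(scene_params(), seed = 7)

# configuration for a 63x water objective sampling at 110 nm/pixel
cfg <- default_config(110, preset = "high_mag")
res <- segment(sc$image, cfg)
print(res$mask)
#> <bf_mask> 256 x 256, 11646 foreground px (17.8%)

dice(res$mask, sc$truth)
#> Dice vs ground truth: 0.876
area_difference_percent(res$mask, sc$truth)
#> Signed area difference: +15.9%

# quantify a co-registered fluorescence channel under the mask
fluor <- bf_image(matrix(120L, 256, 256), nm_per_pixel = 110)
quantify_fluorescence(res$mask, fluor)
#>   area_px area_um2 mean_intensity integrated_density
#> 1   11646 140.9166            120            1397520
```

The Dice coefficient (0.876) says the mask overlaps the known truth
closely; the signed area difference (+15.9%) shows the method's
characteristic *lenient* bias — edge dilation and contrasting debris make
the automated area slightly larger than the reference, with the relative
excess shrinking as cells get larger. `area_um2` converts the pixel count
through the 110 nm/pixel calibration.

For real images: `read_image("cells.tif", nm_per_pixel = 110)`, then
`segment()` as above; inspect with `overlay_outline()` and, if the cell
borders are faint, raise or lower `high_threshold` first.

## Command line

A thin wrapper is installed at `inst/cli/brightseg`:

```sh
brightseg segment input.tif --pixel-size 110 --preset high_mag -o mask.tif
brightseg quantify mask.tif fluor.tif
brightseg synth --out scenes/ --n-scenes 5 --seed 1
brightseg evaluate --auto-dir auto/ --ref-dir ref/
```

Every output is accompanied by a plain-text manifest recording the fully
resolved configuration; re-running from a manifest reproduces the mask
bit-exactly.

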
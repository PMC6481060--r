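---
title: "brightseg: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brightseg: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brightseg)
```

## The problem and the model

Fluorescence-based segmentation needs a whole-cell label; many
experiments label only specific organelles, or none at all. `brightseg`
segments the **total area occupied by cells** from the brightfield
channel alone. The model behind the method is simple and explicit: in a
well-acquired brightfield image, *cell interiors are texture-rich*
(organelles, vesicles, membrane rims produce dense intensity edges)
while *background is smooth* apart from sensor noise and slow
illumination drift. Edge detection therefore produces a dense scribble
inside cells and almost nothing outside; a circular maximum filter fuses
the scribble into solid regions; count-based morphology fills holes,
removes debris, and shaves off the dilation the filter introduced.

The output is a single binary mask of total cell area — deliberately
**not** per-cell instances — intended as a region mask for fluorescence
statistics (`quantify_fluorescence()`: area, mean intensity, integrated
density).

### Assumptions

* The image was acquired on a properly set-up microscope with decent
  contrast and even illumination. Underexposed or out-of-focus input
  makes equalization amplify noise into false cellular texture; the
  package deliberately does **not** attempt to detect such inputs (no
  automatic quality gate), it documents the caveat instead.
* The pixel calibration (nm/pixel) is known. Both pipeline radii are
  keyed on it.
* If fluorescence is quantified, the channels are co-registered with
  identical dimensions and pixel size.
* Scale bars or other burned-in annotations are absent (they segment as
  contrast structure).

## Pipeline stages and their tunables

| Stage | Parameter (units) | high_mag | low_mag | Why |
|---|---|---|---|---|
| Equalize | `classic` (flag) | FALSE | FALSE | sqrt-weighted CDF softens the dominant background mode |
| Canny | `gaussian_kernel_radius` (px, = σ) | from table | from table | match smoothing to pixel sampling |
| Canny | `low_threshold` | 0.1 | 0.1 | keep weak edges connected to strong ones |
| Canny | `high_threshold` | 8.0 | 9.0 | **first knob to adjust**; seeds the edge map |
| Maximum | `max_filter_radius` (px) | from table | from table | bridge gaps between intracellular edges |
| Close | iterations / count / pad | 10 / 3 / yes | 2 / 3 / yes | fill remaining holes |
| Open | iterations / count | 10 / 3 | 10 / 3 | remove debris-sized structures |
| Erode (optional) | iterations / count / pad | 2 / 3 / yes | 2 / 3 / yes | compensate maximum-filter dilation |

`select_parameters()` implements the resolution table (90–180 →
1.75 / 5, 180–270 → 1.5 / 2.5, 270–360 → 1.25 / 1.67, 360+ →
1 / 1.25 nm/px). Printed band boundaries are shared between rows, so the
bands are frozen here as half-open `[lo, hi)` with the boundary
belonging to the upper band; values below 90 nm/px clamp to the first
band with a warning — a total function with no silent failure.

The low-magnification preset exists because at coarse sampling a single
cell spans far fewer pixels: the high threshold rises to 9 (cells are
small, edge contrast per pixel is higher) and closing drops to 2
iterations (10 iterations would weld neighboring cells together).

One documented ambiguity: the opening stage is described in the source
protocol's prose with 10 iterations but its macro line reads 20. The
default here follows the prose (10); passing
`morph_options(20L, 3L)` reproduces the macro variant.

## Conventions frozen where the protocol is silent

Several low-level conventions affect bit-level output but are not
specified by the protocol. Each is frozen, documented, and pinned by an
oracle test:

* **Equalization mapping** — cumulative histogram *inclusive* of the
  current bin, scaled by 255/total, rounded half-up. Square-root
  weighting of counts is the default (the behavior of the ImageJ
  "equalize" option this stage mirrors); `classic = TRUE` uses raw
  counts. The saturation setting is accepted and ignored during
  equalization, again mirroring the reference behavior.
* **Threshold units for Canny** — the protocol gives threshold numbers
  (0.1, 8.0) without units. Magnitude is multiplied by a frozen
  `MAGNITUDE_SCALE = 100/255` (relative to raw 8-bit gradient units)
  before comparison, placing the defaults sensibly between
  smooth-background response and cell-texture response on equalized
  8-bit input. The constant is exported and visible, not hidden.
* **Gaussian kernels** — half-width `ceil(4σ)`, truncated tails
  renormalized, border handling by edge replication.
* **Non-maximum suppression tie-break** — a pixel survives when its
  magnitude is `>=` the interpolated forward neighbor and strictly `>`
  the backward one. An ideal 0|255 step produces *exactly equal*
  magnitudes on the two columns flanking the step; a symmetric `>=`
  rule would keep both and report a two-pixel-wide edge. The asymmetric
  rule keeps exactly one pixel of such a plateau (single-pixel ridges
  and isolated peaks still survive), so step edges come out one pixel
  wide, which the test suite asserts.
* **Hysteresis connectivity** — 8-connected, implemented as connected
  components of the pixel adjacency graph; an independent queue-based
  flood fill serves as the test oracle.
* **Rank-filter kernel** — offsets with `dy² + dx² ≤ r² + 1`. This
  reproduces the reference rank-filter footprints for the fractional
  radii in the calibration table (e.g. radius 2.5 → the 5×5 square
  minus its corners, 21 offsets; radii 1–1.67 → the full 3×3). Borders
  use shrinking windows (no padding).
* **Count morphology** — erosion removes a foreground pixel iff at
  least `count` of its 8 neighbors are background; dilation mirrors
  this. With `pad = TRUE` out-of-image neighbors count as foreground
  during erosion (borders protected — the closing and erosion stages use
  this); dilation always treats out-of-image as background. All four
  operations are verified against brute force on *every* 4×4 mask for
  counts 1, 3 and 8.
* **16→8-bit conversion** — min–max display-range scaling; a constant
  16-bit image maps to 0. RGB collapses through ITU-R 601 luminance.
* **Empty-mask statistics** — the mean fluorescence over an empty mask
  is `NA`, never 0, to keep downstream statistics honest.
* **Masks on disk** — 8-bit, foreground 255 / background 0.

## The synthetic scene generator

`generate_scene()` emulates the imaging situation the pipeline is
designed for, with ground truth known by construction:

* **cells** — random ellipses (default 5 per 256×256 frame, semi-axes
  18–32 px) with a ~2 px rim darker by `border_contrast` (60) and an
  interior textured by organelle-scale blobs (radius 1–3 px, amplitude
  ±50) plus fine noise. Ground truth is the union of the ellipses.
* **background** — level 180 with a linear illumination gradient
  (peak-to-peak 12) and Gaussian sensor noise (SD 3).
* **debris** — small dark discs (default 2, radius 2–4 px) *excluded*
  from ground truth: real impurities contrast enough to be detected but
  a human annotator would not mark them, which is exactly the mechanism
  that makes automated area estimates lenient.

Scenes are bit-reproducible: generation runs under a named portable RNG
(Mersenne–Twister, inversion normals) seeded explicitly, and the
caller's RNG state is restored afterwards.

The defaults are a deliberate compromise stated once: the bodies are
smaller than typical adherent mammalian cells at 63× sampling
(radius ~25 px instead of 100+ px) so that several fit in a frame small
enough for fast tests. That choice has one visible consequence: the
pipeline's boundary growth (maximum filter minus final erosion, ~+3 px)
is a fixed length, so its *relative* area contribution scales inversely
with cell radius. On the default scenes the measured bias is roughly
+15 to +25% of reference area; on real, larger cells the same growth
corresponds to a single-digit percentage. The regression suite therefore
pins, from the first verified run under these defaults: median Dice
≥ 0.8 over seeds 0–19 (measured 0.875) and a mean signed area
difference that is positive and below 35%.

What the generator does **not** model — and what passing tests therefore
do not show: optics (point-spread function, defocus), phase-contrast
halos, confluent sheets without visible borders, faint-bordered cell
types such as fibroblasts, vignetting, or the specific morphologies of
real cell lines. Results on real data still require the visual check
that `overlay_outline()` supports.

## Numerical and size choices

Everything is deterministic: identical input and configuration give
bit-identical masks across runs and platforms (asserted down to file
bytes in the tests). Problem sizes in the shipped tests are chosen for
thorough-but-fast coverage: exhaustive 4×4 enumeration (65,536 masks)
for morphology, 32×32 random rasters for filter oracles, 256×256 scenes
(20 seeds) for end-to-end recovery; the acceptance script re-runs the
20-scene sweep in a few seconds.

## Known limitations

* Total area only; touching cells are never separated.
* No automatic rejection of poor-quality input; underexposed images
  yield confident-looking nonsense after equalization.
* The evaluation statistics on synthetic scenes characterize the
  implementation, not agreement with human annotators on real images.
* Multi-page TIFFs and proprietary microscope formats are out of scope;
  convert upstream.
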
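---
title: "Models, parameters and numerical choices in ifcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and numerical choices in ifcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ifcyto` converts multi-channel immunofluorescence images into single-cell
cytometry tables. This vignette documents the model behind each stage, the
parameters that matter, and every numerical decision that was genuinely
open, so that results can be interpreted and reproduced without reading
the source.

## The processing model

The pipeline assumes a 2D multi-channel image in which one channel (a
nuclear stain such as DAPI, or a membrane dye) carries the morphological
signal used for segmentation, and the remaining channels carry marker
intensities to be quantified inside each segmented cell. Three corruptions
are modeled and corrected before segmentation, in a fixed order:

1. **Additive slowly-varying background** (uneven illumination,
   autofluorescence haze) — removed by rolling-ball subtraction: the
   background is the grayscale opening of the image by a ball-shaped
   (spherical-cap) structuring element, and `x − opening(x)` is kept,
   clipped at 0. Opening with any structuring element satisfies
   `opening(x + c) = opening(x) + c`, so flat offsets are removed exactly;
   gradients slower than the ball curvature are removed up to border
   effects. The ball radius (`rolling_ball_params(radius_px = 50)`) must
   exceed the radius of real objects; 50 px is the common
   particle-analysis default and is deliberately exposed because no single
   value suits all magnifications.
2. **Locally poor contrast** — corrected by CLAHE
   (`clahe_params(block_size_px = 30, histogram_bins = 256,
   max_slope = 3)`; defaults as published for this workflow). Per-block
   histograms are clipped at `max_slope × block_px / bins`, the clipped
   mass is redistributed uniformly (a single pass; the redistribution may
   marginally re-exceed the clip, which is the standard fast behavior),
   and the per-block equalization mappings are applied with bilinear
   interpolation between block centers (the "fast" variant). Edge blocks
   are taken from a mirrored image so all histograms are full-size.
3. **Noise at scales below the cell radius** — suppressed implicitly by
   the band-pass Difference of Gaussians used for detection.

All channels are preprocessed the same way, and intensities are measured
on the preprocessed channels (a `measure_raw` switch preserves the
alternative), so CTCF values refer to the corrected signal.

## Segmentation

Detection runs on `DoG = G(σ_low) − G(σ_high)` with
`σ_high = σ_low × sigma_ratio`. Gaussian kernels are sampled, truncated at
4σ and normalized; borders are mirrored. The DoG response is thresholded
with the ISODATA intermeans rule on a 256-bin histogram of the response —
starting from the histogram midpoint, `t ← (mean(v ≤ t) + mean(v > t))/2`
until the change is under one bin width — keeping the positive band
(`response ≥ t`). Holes are filled (4-connected background flood fill, the
dual of the default 8-connected foreground), components are labeled in
deterministic raster order, and objects below `min_area_px` are removed
before dense relabeling.

Two parameter choices deserve comment:

* **σ from the cell radius.** The relation used to derive `σ_low` from a
  mean cell radius is typeset ambiguously in the source material
  (`r = σ·sqrt(2·ln(255) − 1)` is the adopted natural-log reading, giving
  σ = 2.362 for r = 7.5 px; a base-10 reading gives 3.841, and neither
  reproduces the printed 2.13 without knowing the pixel size). The
  constant is therefore a named, overridable argument of
  `sigma_from_radius()`, and passing `sigma_low` directly is the
  recommended path.
* **σ ratio.** 1.4 is the default; ratios well above 2 turn the band-pass
  into a broad high-pass and are reported to segment poorly on tissue.
  Both 1.4 and the extreme 10 are exercised by the acceptance suite on
  synthetic data.

No watershed splitting of touching nuclei is attempted: the upstream
workflow describes none, and the package reproduces its behavior.

## Measurement conventions

Coordinates are 0-based pixel centers, x = column (rightward), y = row
(downward), origin top-left; centroids are reported in pixels so that FCS
X/Y scatter plots reproduce the image layout. Areas, perimeters and axes
are calibrated by `pixel_size_um` (default 1, which keeps areas in px² and
makes `IntDen == RawIntDen`, a tested identity).

* **Perimeter** is the 8-connected outline chain length (straight steps 1,
  diagonal steps √2) from Moore boundary tracing; a single pixel counts as
  its unit-square outline (4). No corner-cutting correction is applied —
  the convention is simple and oracle-testable, at the cost that small
  digitized disks reach the circularity clamp of 1 (circularity is
  `min(1, 4πA/P²)` because digitization can push the raw ratio above 1).
  Consequently circularity of digitized disks is *not* monotone in the
  radius; the tests assert the honest property (disks stay in [0.9, 1]).
* **Ellipse axes** come from the moment-matched ellipse: axes
  `4√λ` from the population covariance eigenvalues, then both axes
  rescaled so the ellipse area equals the pixel area. Degenerate objects
  (zero minor axis or perimeter) yield `NA` metrics and are flagged, never
  dropped.
* **Convex area** is the number of pixels whose centers fall inside the
  convex hull of the object's pixel centers (collinear objects fall back
  to their pixel count). This pixel-count convention guarantees
  solidity ≤ 1, which hull-polygon areas do not (a hull through pixel
  centers *under*-covers the union of pixels; a hull through pixel corners
  *over*-covers it).
* **Background AOI.** The CTCF reference is a rectangle that must not
  intersect any labeled object: either given explicitly (the reproducible
  analog of drawing it by hand) or chosen automatically as the
  `window_px × window_px` window minimizing summed intensity across
  channels (exhaustive scan via summed-area table; row-major tie-break).
  The selected region is recorded in the output metadata.

## Benchmarking

Matching is one-to-one over pairs with `IoU ≥ t` **and** `IoU > 0` — mere
coexistence never matches, including at t = 0. The default method is the
**maximum-cardinality matching** (augmenting paths, deterministic order).
A greedy descending-IoU matcher (ties: smaller reference label, then
smaller predicted label) is provided as `method = "greedy"`, but it is
provably not always optimal: when one prediction overlaps two references
it can steal the partner another reference needs, under-counting TP. The
test suite demonstrates this on random mask pairs and validates the
default matcher against brute-force enumeration (500 pairs × the full
21-point grid), which is why optimal matching — the convention of standard
instance-segmentation benchmarks — is the default rather than greedy.

TP is non-increasing in t for both methods (the admissible edge set only
shrinks), which proves the monotonicity of all four metric series:
precision `TP/n_pred`, recall `TP/n_ref`, Jaccard
`TP/(n_ref + n_pred − TP)` and F-measure `2TP/(n_ref + n_pred)` have fixed
or TP-monotone denominators. 0/0 cases are 0 by convention (documented
because the source material is silent). `percent_detected()` counts **all**
predicted objects relative to the reference count (so over-segmentation
can exceed 100%); a matched-only mode exists behind a flag. Efficacy
aggregation averages the five measures; percent evolutions
`(b/a − 1) × 100` are reported to 2 decimals, and reproducing the
published table requires applying them to averages rounded to their
printed 4-decimal precision (the tested convention).

## The synthetic fixture

`generate_fixture()` emulates the benchmark's crop regime: nuclei as
Gaussian-profile disks (profile sd = radius / √(2·ln 10), so the
ground-truth footprint at 10% of the amplitude has exactly the nominal
radius) on a constant background, with optional linear flatfield gradient,
Gaussian noise, 16-bit quantization, and Bernoulli marker positivity with
lognormal amplitudes. LD mode enforces a hard-core minimum spacing of
2.5 × radius; HD mode draws clustered centers (parents + Gaussian
offspring) with overlaps allowed, in which case occluded cells stay in
the truth table but may merge or vanish in the rendered mask. Defaults —
400×400 px, 100 cells, radius 7.5 ± 0.75 px, amplitude 1000 over
background 100 with noise sd 100 (SNR 10), gradient 0 — were fixed once
as a realistic clean LD crop and are not tuned per test.

What a green test on this generator does establish: the full chain
(preprocessing → DoG/ISODATA → measurement → export) recovers known
objects and known intensity contrasts under realistic noise. What it does
not establish: performance on real tissue — autofluorescence texture,
spectral crosstalk, densely touching heterogeneous nuclei and staining
artifacts are not simulated, so absolute benchmark figures from real
slides cannot be reproduced here.

## Numerical and I/O choices

* CLAHE histograms span the occupied data range (not the dtype range):
  16-bit microscopy data typically occupies a small fraction of
  [0, 65535], and binning the dtype range would collapse the signal into
  a few bins. Output therefore stays within the input dtype range. A
  degenerate block (single occupied bin) maps identically.
* Histogram equalization uses the classical cdf-minimum anchoring; with
  one block and an unbounded slope CLAHE reduces exactly to global
  equalization (tested against an independent oracle).
* ISODATA on a constant response errors ("degenerate histogram") and the
  segmenter converts that into an empty mask with a warning.
* TIFF: a minimal grayscale codec (8/16-bit unsigned, 32-bit float;
  single- and multi-page; strips; LZW) is built in because no
  TIFF-capable R package is available in the target runtime. The LZW
  codec implements the TIFF variable-width variant with early code-width
  change and is cross-validated in both directions against
  libtiff-compatible reference streams. Channel names and the pixel size
  ride in each page's ImageDescription. Horizontal-predictor LZW files
  are readable; the writer does not emit predictors.
* FCS 3.1 is written as list-mode little-endian float32
  (`$DATATYPE/F`, `$BYTEORD/1,2,3,4`, `$PnB/32`, `$PnE/0,0`) for widest
  third-party compatibility; values are therefore preserved to float32
  precision, which the round-trip tests assert via an independent parser.
* XLSX export bridges to the system `python` + `openpyxl` rather than
  reimplementing the zip/XML container.
* Determinism: the fixture generator seeds its own RNG stream and
  restores the caller's; pipeline reruns on identical inputs produce
  bit-identical integer artifacts (tested).

## Known limitations

* Only abutting, non-overlapping tiles are stitched; no overlap
  registration or seam correction.
* Segmentation is tuned for nucleus-scale blob detection; membrane-stain
  segmentation is untested, and touching nuclei are not split.
* The rolling ball is applied at full resolution (no large-radius
  downsampling shortcut), which is exact but O(image × ball area).
* IM3/CZI inputs, spectral demultiplexing, texture features and spatial
  statistics are out of scope.
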
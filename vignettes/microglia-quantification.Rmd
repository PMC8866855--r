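---
title: "Quantifying myeloid cell morphology and marker loss after brain injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myeloid cell morphology and marker loss after brain injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iba1quant)
```

## The measurement problem

After a cortical contusion, brain myeloid cells (resident microglia and
infiltrating macrophages) change shape as they activate: surveilling
microglia are *ramified* (small soma, long thin processes), activated cells
become *hypertrophic* (enlarged soma, thick processes) and, at the lesion
itself, *ameboid* (compact, round). Because the pan-myeloid marker Iba1
cannot distinguish microglia from macrophages, morphology is used as a
proxy for the activation state, and the microglia-specific marker Tmem119
is quantified inside each Iba1-derived outline to ask whether its
immunoreactivity tracks those states. This package implements that entire
per-cell measurement chain, plus the relative qPCR arithmetic used for the
companion transcript-level question, and a synthetic scene generator so
every stage can be validated against ground truth without microscope data.

## The image-processing chain

Input volumes are two-channel confocal stacks (channel 1 Tmem119, channel
2 Iba1) with known pixel size; the reference geometry is 210 × 210 × 12 µm
at 0.2 µm/pixel and 1.13 µm z-step, 12-bit gray levels (0–4096). The chain
is:

1. **Maximum-intensity projection** per channel (`max_project()`).
2. **Iba1 channel**: rolling-ball background subtraction with radius 50 px
   (`subtract_background_rolling()`), one pass of a 3 × 3 mean filter
   (`smooth_mean()`), then an unsharp mask
   (`unsharp_mask()`, sigma 2 px, weight 0.6):
   `out = (I − w·G(I)) / (1 − w)`, negatives clipped.
3. **Segmentation** at a constant gray-level cut-off applied unchanged to
   every image of a study (`segment_cells()`), 8-connectivity, debris
   below 20 µm² discarded, border-touching components excluded.
   The cut-off itself is a study-level analyst choice; `suggest_threshold()`
   derives one as a high quantile of a preprocessed control field.
4. **Morphometry** per cell (`shape_descriptors()`): area (pixel count ×
   pixel size²), traced-boundary perimeter, circularity
   `4π·area/perimeter²` clipped at 1.
5. **Classification** (`classify_morphology()`): hypertrophic if area
   ≥ 250 µm²; otherwise ameboid if circularity > 0.16, else ramified;
   cells with circularity > 0.5 are flagged as putative infiltrated
   myeloid cells.
6. **Marker quantification** (`cell_records()`, `decompose_intensity()`):
   the Tmem119 projection receives only a rolling-ball subtraction with
   radius 20 px, then the mean gray value is measured inside each Iba1
   outline; the soma outline is obtained by cutting all ramifications with
   a 2 µm disc opening, and the ramification signal is reported both as
   the direct mean over process pixels and as the literal difference
   `total − soma` of means.

### The rolling ball

The background under a structure is estimated as the grayscale opening of
the image with a ball-shaped (non-flat) structuring element: the surface a
ball of the stated radius traces when rolled under the intensity
landscape. We compute the exact opening (compiled erosion/dilation over
the ball's offset-height list) for radii ≤ 16 px; larger radii use the
standard large-ball approximation — block-minimum reduction (factor 2, 4
or 8 by radius), exact opening on the reduced image, bilinear enlargement
clamped under the image. Constants map to zero exactly, the output is
non-negative everywhere, and narrow bright structures are preserved
regardless of their amplitude because the ball cannot enter them.

### Perimeter estimation near the 0.16 gate

Circularity near the ramified/ameboid gate is sensitive to the perimeter
estimator. The default traces the 8-connected outer boundary through
pixel centres and sums step lengths with the standard corrected chain-code
weights (straight 1, diagonal 1.340). The common raw √2 diagonal weight
overestimates smooth outlines by ≈ 5 %, which would push a digital disk's
circularity to ≈ 0.90; the corrected weights keep a radius-50 disk at
≈ 0.96 while leaving axis-aligned rectangles at their exact geometric
perimeter (a 40-px square measures ≈ 0.83, near the analytic π/4). A
4-direction Cauchy–Crofton estimator is available via
`pipeline_config(perimeter_method = "crofton")` for sensitivity analyses.
Single-pixel masks are assigned the perimeter of their pixel boundary
(4 px) so circularity is always defined.

### Boundary conventions

Gates partition exactly: area exactly 250 µm² is hypertrophic (≥),
circularity exactly 0.16 is ramified (strict >). The infiltration flag is
set whenever circularity > 0.5, independent of class, and the three-class
taxonomy is unchanged by it. Coordinates are reported 0-based as (x, y)
with y increasing downward; areas convert via pixel size².

## The synthetic scene generator

`scene_spec()` / `render_scene()` emulate the acquisition the chain
expects. Defaults are the reference geometry above with 20 cells per
class. Morphologies are drawn so classes sit clearly inside their gates:

* ramified — soma 6–8 µm diameter, 5–8 tapering processes 10–25 µm long
  and ≤ 1 µm wide;
* hypertrophic — soma 16.5–19 µm, 4–6 thick (2.4–3 µm) processes
  9–14 µm long;
* ameboid — smooth ellipses (circularity > 0.5) or rough star shapes
  (0.16 < circularity ≤ 0.5), areas 80–230 µm², mixed 50/50 by default.

Placement works in two phases, mimicking how microglial territories
interdigitate: somata are placed by rejection sampling with a 2 µm
clearance (ramified/hypertrophic somata additionally reserve a 5 µm ring
of breathing room at placement time), then each process stroke is grown
individually, re-sampled and finally shortened until it clears every other
cell; cells stuck in crowded pockets are relocated. Each placed process
must contribute genuinely new pixels, and ramified (hypertrophic) cells
keep at least 3 (2) processes, so footprints stay in their intended gates
at a ≥ 90 % rate even in dense scenes. Footprints of distinct cells never
share a pixel.

Intensities encode the biological contrast the measurement should recover:
Iba1 is uniform over every footprint (1200 gray levels above background —
the assumption that Iba1 staining does not differ between classes is a
deliberate simplification, as nothing in the measurement model depends on
it); Tmem119 is painted per class with the process signal exceeding the
soma signal in ramified (900 vs 300) and hypertrophic (700 vs 250) cells,
and ameboid cells near background (60), reflecting the marker
concentrating on processes and collapsing in ameboid cells. Cells span a
few z-slices; each slice receives a planar background gradient (offset
100, amplitude 30), Gaussian PSF blur (σ 0.15 µm, the lateral resolution
of a 0.75-NA objective), then Poisson shot noise (photon scaling 0.25,
i.e. gain 4) and Gaussian read noise (SD 20), rounded and clipped to
12 bits. These are standard fluorescence noise assumptions; none of them
are fitted to data. What the generator deliberately does *not* emulate —
true 3D arborization, touching/overlapping cells, staining heterogeneity
within a cell, photobleaching — means that passing recovery tests
demonstrates the correctness and robustness of the measurement chain, not
that the pipeline would segment arbitrarily hard real tissue.

## Numerical choices and degenerate inputs

* Painted values are background + signal, so in the noiseless, blur-free,
  background-free setting per-region means equal painted means exactly —
  the identity the decomposition tests assert.
* The pixel-weighted reconstruction
  `n_soma·mean_soma + n_ram·mean_ram = n_total·mean_total` holds exactly
  for every cell; the literal `total − soma` difference of means is also
  reported because it is the simpler published arithmetic, but it is not
  a per-pixel mean, so the direct process-pixel mean is the primary
  output.
* Opening a digitized disk with a digitized disc can nick single boundary
  pixels, so "a pure disc is its own soma" holds up to a Jaccard of
  ≥ 0.99 rather than pixel-exactly; cells whose soma vanishes under the
  opening (thin fragments) report soma fields as missing rather than
  erroring.
* An empty segmentation result is a valid empty table, not an error.
* ROI membership is decided by the cell centroid, so adjacent windows
  never double-count a cell.
* With smoothing and unsharp masking in the chain, segmented outlines are
  not pixel-identical to painted footprints even without noise (thin
  process tails lose roughly half their width to the 3 × 3 mean); exact
  footprint recovery is therefore asserted for thresholding alone, and
  the full chain is held to count- and fraction-level recovery instead.

## qPCR arithmetic

`fold_changes()` implements relative quantification with multi-reference
normalization: per sample, `CT_ref` is the mean CT of the reference genes
(Hprt1, Gapdh, Ppia in the bundled synthetic example);
`ΔCT = CT_ref − CT_goi` (reference minus gene of interest, so higher
expression means higher ΔCT); `ΔΔCT = ΔCT − aggregate(ΔCT_control)` with
the control aggregate being the mean by default (median available);
fold change = `E^ΔΔCT` with amplification efficiency E = 2 by default and
any E > 1 supported (measured primer efficiencies are typically
1.95–1.99). Technical replicates are averaged per sample × gene before
any Δ. Swapping group labels inverts the group-level fold exactly; note
that per-sample folds change baseline under the swap, so the inversion
identity is a group-level property.

## Sample size

`sample_size()` exposes the pre-hoc two-group normal-approximation
formula `n = 2σ²f(α, β)/Δ²` with `f = (z_{1−α/2} + z_{1−β})²`. For
σ = 18.42, Δ = 42, α = 0.05, β = 0.2 this gives f ≈ 7.85 and n ≈ 3.02.
Published uses of this formula sometimes quote slightly smaller f factors
(e.g. values consistent with n ≈ 2.9 for the same inputs); since the
convention behind such factors is not always stated, `f` is an explicit
overridable argument rather than a hidden constant.

## Problem sizes used in validation

The test-suite recovery experiments use full-size 210 µm scenes: one
60-cell scene for segmentation recovery, five scenes totalling 300 cells
at class fractions 35/37/28 % for end-to-end fraction recovery (the
acceptance script repeats this configuration), and 105 µm scenes for the
exactness and determinism checks. These sizes keep the whole suite at a
few minutes while leaving every spatial parameter at its reference value.

## Worked example

```{r example, eval = FALSE}
spec <- scene_spec(seed = 1)
scene <- render_scene(spec)
cfg <- pipeline_config(threshold_gray = 300)
run <- run_pipeline(scene$stack, cfg)

population_fractions(run$records)
plot_gate_scatter(run$records)
plot_marker_by_class(run$records)

ev <- evaluate_run(run, scene$truth)
glance(ev)
```

## Known limitations

Touching cells are not split (no watershed), matching the single-threshold
design; heavily overlapping real tissue would need an instance-aware
segmenter. The soma operationalization ("cut all ramifications" as a 2 µm
disc opening) is one reasonable reading of a verbal protocol; the radius
is exposed in `pipeline_config()`. Circularity values within ≈ 0.03 of the
0.16 gate are estimator-sensitive; treat class assignments there with
care, or compare both perimeter estimators.
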
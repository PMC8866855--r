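# iba1quant

Per-cell quantification of brain myeloid cells (microglia and macrophages)
in two-channel confocal fluorescence stacks, built for the question of how
the microglia-specific marker Tmem119 behaves across activation states
after traumatic brain injury.

After a cortical contusion, Iba1-positive cells shift from a *ramified*
(surveilling) morphology toward *hypertrophic* and *ameboid* (activated)
ones, and Iba1 alone cannot separate resident microglia from infiltrating
macrophages. The package implements the standard image-analysis chain that
turns raw stacks into per-cell measurements:

* maximum-intensity projection and channel splitting;
* rolling-ball background subtraction (grayscale opening with a ball
  structuring element; radius 50 px for Iba1, 20 px for the marker
  channel), 3 × 3 mean smoothing and unsharp masking (σ = 2 px,
  weight 0.6) on the Iba1 channel;
* segmentation of Iba1⁺ cells at a constant gray-level cut-off;
* shape descriptors per cell — area *A* (µm²) and circularity
  *C* = 4π·*A*/*P*², with *P* the traced-boundary perimeter — and the
  morphology gates

  | class        | gate                      |
  |--------------|---------------------------|
  | hypertrophic | *A* ≥ 250 µm²             |
  | ameboid      | *A* < 250 µm², *C* > 0.16 |
  | ramified     | *A* < 250 µm², *C* ≤ 0.16 |

  plus a flag for putative infiltrated myeloid cells at *C* > 0.5;
* Tmem119 mean gray value inside each Iba1 outline, decomposed into soma
  (2 µm disc opening of the outline) versus ramifications;
* analysis windows at stated distances from a lesion edge (edge /
  intermediate at 350 µm / distant at 700 µm);
* relative qPCR quantification by the ΔΔCT method with multi-reference
  normalization: CT_ref = mean CT of the reference genes,
  ΔCT = CT_ref − CT_goi, ΔΔCT = ΔCT − mean ΔCT_control, fold = E^ΔΔCT
  (E = 2 by default, any E > 1 supported);
* the pre-hoc group-size formula n = 2σ²·(z₁₋α/₂ + z₁₋β)²/Δ².

Because raw study images are rarely desk-available, the package ships a
synthetic scene generator (`scene_spec()`, `render_scene()`) producing
two-channel 210 × 210 × 12 µm volumes at 0.2 µm/pixel with per-cell ground
truth (footprint, soma and process masks, painted intensities), so the
whole chain is testable end to end.

## Worked example

```r
library(iba1quant)

scene <- render_scene(scene_spec(seed = 7))   # 60 cells, 20 per class
cfg   <- pipeline_config(threshold_gray = 300)
run   <- run_pipeline(scene$stack, cfg)

population_fractions(run$records)
#> # A tibble: 3 × 3
#>   class            n percent
#>   <fct>        <int>   <dbl>
#> 1 ramified        20    33.3
#> 2 hypertrophic    20    33.3
#> 3 ameboid         20    33.3

glance(evaluate_run(run, scene$truth))
#> # A tibble: 1 × 7
#>   n_matched n_missed n_spurious mean_jaccard class_accuracy ...
#> 1        60        0          0        0.897              1
```

All 60 painted cells are recovered one-to-one (mean Jaccard overlap 0.90
against the ground-truth masks) and classified into the correct gate; the
per-cell table in `run$records` carries the shape descriptors, class,
infiltration flag and the Tmem119 total/soma/ramification means, e.g.
ameboid cells showing near-background marker signal while ramified cells
measure several hundred gray levels. `plot_gate_scatter(run$records)` and
`plot_marker_by_class(run$records)` draw the standard stratification
views.

For qPCR tables (`sample_id, group, gene, role, ct`; see
`inst/extdata/synthetic_ct_example.csv`, a synthetic example with a
programmed 4.36-fold increase):

```r
ct <- read_ct_table(system.file("extdata", "synthetic_ct_example.csv",
                                package = "iba1quant"))
glance(fold_changes(ct))$fold_change_group
#> [1] 4.00
```

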
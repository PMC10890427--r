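# microfract

Automated detection, measurement and statistical summary of fatigue
**microfractures** in micro-CT slice stacks of small material specimens —
cortical bone first, but the workflow applies equally to metals, polymers,
composites and stone. Microfractures are crack-like voids below the ~1 mm
macrofracture scale that accumulate under cyclic loading; counting and
measuring them by hand, slice by slice, takes weeks per specimen. This
package automates the whole chain at the level of a research pipeline:

* **Preprocessing** — Otsu (or fixed) binarization, isolated-region removal,
  pixel-gap filling, and a second isolated-region pass.
* **Detection** — morphological region extraction (default) or Canny
  edge-contour regions (Gaussian-derivative gradients in four directions,
  non-maximum suppression, hysteresis); features typed as *microfracture*,
  *pore* or *artifact* by a minimum extension of 5 px plus
  circularity/eccentricity rules.
* **Morphometrics** — per-feature area, perimeter, characteristic length
  (maximum Feret diameter), circularity `4πA/P²`, eccentricity and
  orientation, in pixels and (via the μm/pixel factor) microns.
* **Weibull statistics** — the two-parameter characteristic-length model

  `P = 1 − exp[−(a/a₀)^α]`,   linearized as   `ln[−ln(1−P)] = α ln a − α ln a₀`,

  fitted by median-rank probability-plot regression; `α = 1` is the
  exponential (constant-hazard) special case, `α > 1` increasing and
  `α < 1` decreasing failure rate.
* **3D reconstruction** — 26-connected components across slices, voxel
  volumes in μm³, microfracture volumetric density, and FE-prep helpers
  (uniform per-element load partition; export of microfracture-only binary
  images with a JSON manifest).
* **CNN pre-screen** — a compact 15-processing-layer convolutional network
  (4 × conv/batch-norm/ReLU with max pooling, global max pool, softmax)
  trained with stochastic gradient descent with momentum, classifying slices
  as with/without microfracture; implemented natively in R on BLAS matrix
  products, fully reproducible under a seed.
* **Synthetic generator** — parametric CT phantoms (specimen cross-section,
  pores, Weibull-distributed crack lengths, osteon-like texture, noise) with
  exact planted ground truth, so every stage is benchmarkable without
  proprietary scan data.

Results come back as tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## A 60-second tour

```r
library(microfract)

# a synthetic 8-slice stack with planted ground truth (use read_stack() for
# real data; the um/pixel factor is a mandatory user input)
gen <- generate_stack(synth_spec(n_slices = 8, seed = 1))
det <- detect_stack(gen$stack)

dplyr::count(det$records, type)
#> # A tibble: 3 × 2
#>   type              n
#>   <chr>         <int>
#> 1 artifact          2
#> 2 microfracture    15
#> 3 pore             61

fit <- fit_weibull(det$records$char_length_um[det$records$type == "microfracture"])
fit
#> Two-parameter Weibull fit (rank regression, median_rank)
#>   shape alpha = 2.3260
#>   characteristic length a0 = 25.0866
#>   R^2 = 0.9794 on n = 15

comp <- volumetric_density(components_3d(det$fracture_masks),
                           det$specimen_masks, gen$stack$meta)
comp
#> <fracture_3d> 15 components (26-connected), 607 voxels
#>   total volume 1666 um^3, volumetric density 0.001889
```

The fitted shape (`α ≈ 2.3` on 15 detected cracks) is the rank-regression
slope of the linearized probability plot (`autoplot(fit)` draws it); `a₀` is
the length at which the cumulative probability reaches `1 − e⁻¹ ≈ 0.63` —
here about 25 μm, at the upper end of the 4–30 μm range typical of these
specimens (detection censors sub-5 px cracks, which shifts the fitted scale
of a small sample upward). The
volumetric density is the fraction of specimen volume occupied by detected
microfractures. On a noise-free calibration fixture, the smallest feature
extent the pipeline reports as a microfracture is 5 px, i.e. 7 μm at the
finest 1.4 μm/px tomography resolution:

```r
fx <- extension_fixture()
d <- detect_microfractures(fx$image, meta = fx$meta)
min(d$records$char_length_px[d$records$type == "microfracture"])
#> [1] 5
px_to_um(5, stack_meta(um_per_px = 1.4))
#> [1] 7
```

A thin command-line wrapper for shell use lives at
`inst/scripts/microfract.R` (subcommands `simulate`, `detect`, `weibull`,
`reconstruct`, `run`).

## Package layout

| Area | Functions |
|---|---|
| I/O | `read_stack`, `write_stack`, `write_mask_stack`, `write_metrics_table`, `read_metrics_table`, `stack_meta` |
| Preprocess | `preprocess_config`, `binarize`, `remove_small_regions`, `fill_gaps`, `preprocess_slice`, `segment_voids` |
| Detect | `detect_config`, `canny_edges`, `regions_from_edges`, `classify_region`, `detect_microfractures`, `detect_stack` |
| Morphometrics | `region_metrics`, `label_image_metrics`, `px_to_um`, `summarize_slice` |
| Weibull | `weibull_cdf`, `weibull_quantile`, `weibull_hazard`, `linearize`, `plotting_positions`, `fit_weibull`, `fit_weibull_mle` |
| 3D / FE prep | `components_3d`, `volumetric_density`, `per_element_load`, `export_fe_inputs` |
| Classifier | `classifier_config`, `augment_dataset`, `train_classifier`, `classify_image`, `evaluate_accuracy`, `save_classifier`, `load_classifier` |
| Synthetic data | `synth_spec`, `generate_stack`, `generate_labeled_dataset`, `extension_fixture` |
| Pipeline | `run_config`, `run_pipeline` |

The methods vignette (`vignettes/microfracture-analysis.Rmd`) documents the
models, estimator choices, generator realism and limitations in detail.
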
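# spinemark

Vertebra landmark detection and Cobb angle estimation for scoliosis
assessment, in R.

Automated scoliosis grading from an anterior–posterior spinal radiograph
works by detecting 68 landmarks — the four corners of each of the 17
annotated thoracic/lumbar vertebrae — and measuring the Cobb angle from
them: the angle between the endplates of the two most-tilted vertebrae of a
curve. `spinemark` implements the computational core of a keypoint-style
detection pipeline for this task, aimed at researchers building or
evaluating such detectors:

* **Dual-coordinate ground-truth codec** — vertebra centres as a Gaussian
  heatmap plus Cartesian sub-pixel offsets on a stride-`k` grid; corners as
  polar offsets `(r, θ)` about each centre (`x = x_ct + r cos θ`,
  `y = y_ct + r sin θ`); exact decoding via 3×3 non-maximum suppression and
  fixed top-k or intensity-thresholded (adaptive) centre selection.
* **Inter-vertebral interval targets** — CPIE (vector between adjacent
  centres) and AVIE (offsets from a vertebra's bottom corners to the next
  vertebra's top corners), auxiliary supervision that encodes the spatial
  structure between vertebrae.
* **Sparse-to-dense vertebral lines** — an interpolating cubic spline
  through the left corners, centres, or right corners, resampled at 100
  arc-length-equidistant points.
* **Composite loss** — focal heatmap loss plus masked L1 terms,
  `L = Σ αᵢ Lᵢ` with `α₁..α₅ = 1`, `α₆ = 0.05` for the dense line term.
* **Reference network** — a compact encoder–decoder with the six output
  pathways, written (with its backprop) directly in R, for CPU-scale
  end-to-end verification.
* **Evaluation suite** — Cobb angles (PT/MT/TL) from 68 landmarks with the
  AASCE-style regional partition; MDE (mean detection error, px); SMAPE
  over the three angles (%); and self-adaptive MDE, which decodes an
  adaptive number of centres and Hungarian-matches them to the ground
  truth to separate localization error from vertebra-ordering error.
* **Spine simulator** — parametric scoliotic spines on a sinusoidal
  centerline with analytic true Cobb angles, rendered as pseudo-radiographs
  with heavier clutter in the lower image half.

## Worked example

```r
library(spinemark)

# simulate a scoliotic spine with known true Cobb angles
case <- generate_case(spine_sim_params(seed = 52))
case$true_cobb
#> # A tibble: 1 × 3
#>      pt    mt    tl
#>   <dbl> <dbl> <dbl>
#> 1  12.8  29.2  24.4

# measure the Cobb angles from the 68 corner landmarks
cobb_from_landmarks(case$annotation)
#> # A tibble: 1 × 3
#>      pt    mt    tl
#>   <dbl> <dbl> <dbl>
#> 1  12.8  29.2  24.4

# encode supervision targets, then decode them back to landmarks
cc <- codec_config()
tg  <- encode_all(case$annotation, cc)
ctr <- topk_centers(tg$heatmap, tg$center_offset, cc)
lm  <- decode_landmarks(ctr, tg$corner_polar, cc)
nrow(lm)                                  # 68 landmarks, 17 vertebrae
max(abs(as_landmark_matrix(lm) -
        as_landmark_matrix(case$annotation)))
#> [1] 2.84e-14                            # the codec is exactly invertible

# metrics: displace every landmark by (3, 4) px and evaluate
shifted <- dplyr::mutate(lm, x = x + 3, y = y + 4)
tidy(evaluate_case(shifted, case$annotation))
#> # A tibble: 9 × 2
#>   metric      value
#>   <chr>       <dbl>
#> 1 mde             5      # each landmark is exactly 5 px away
#> 2 mde_upper       5
#> 3 mde_lower       5
#> 4 mde_centers     5
#> 5 smape           0      # a rigid shift leaves all angles unchanged
#> ...
```

The PT/MT/TL angles are the proximal thoracic, main thoracic and
thoracolumbar Cobb angles in degrees; `mde` is the mean Euclidean landmark
error in pixels (upper = vertebrae 1–10, lower = 11–17); `smape` is the
symmetric mean absolute percentage error over the three angles.

Training the toy network end to end (about a minute on one CPU core):

```r
cases <- lapply(1:2, function(s) generate_case(toy_sim_params(seed = s)))
fit <- train_toy(build_model(model_config("toy"), seed = 0), cases,
                 steps = 500)
glance(fit)          # final loss ≈ 4% of the initial loss
out <- predict(fit$model, cases[[1]]$image)
mde(decode_prediction(out, fit$codec), cases[[1]]$annotation)  # ≈ 1 px
```

A command-line interface over the same functions is installed at
`system.file("scripts", "spinemark", package = "spinemark")` with
subcommands `simulate`, `encode`, `decode`, `lines`, `cobb`, `evaluate`
and `train-toy`.

## Scope

The package provides the label codecs, losses, metrics, simulator and a
desk-scale reference network. It does not ship trained weights, clinical
data, or a full-scale training harness; reproducing challenge-grade
detection numbers requires the AASCE radiographs and GPU training, which
are out of scope.
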
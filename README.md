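# echosnake

Coarse-to-fine left-ventricle (LV) segmentation for 3D echocardiography
(3DE), as an R package. It is aimed at researchers in cardiac image
analysis who want a fully testable, dependency-light reference
implementation of the classic two-stage recipe:

1. **Coarse stage** — a small fusion fully-convolutional network (FCN)
   with residual skip streams labels every 2D short-axis slice,
   trained with the class-balanced weighted cross-entropy loss
   `L = -a Σ_fg log P(y=1) - (1-a) Σ_bg log P(y=0)`, `a = Y₋/(Y₊+Y₋)`.
2. **Geometric initialization** — per-slice foreground centroids, a
   quadratic center-curve correction `x(z), y(z)`, the 8-ray average radius
   `R = (R₁+…+R₈)/8` under a circular cross-section assumption, contour
   resampling at interval `k`, and reconstruction of a stacked-ring tube
   mesh with an apex cap.
3. **Fine stage** — a spatially regularized 3D snake evolved by gradient
   descent on
   `E = Σ ( ½α|X′|² + ½β|X″|² + δ·E_ext(X) + η·|X − X_init|² )`
   with `E_ext = −‖∇(G_σ∗I)‖²`; the `η` term anchors the surface to its
   initialization and prevents boundary leak from the LV into the left
   atrium. Defaults: `α = 0.1, β = 0.2, δ = 0.1, η = 0.1, k = 10`.
4. **Evaluation** — mean surface distance `d_m = d̄(S,Sₜ) + d̄(Sₜ,S)`,
   Hausdorff distance `d_h`, modified Dice `D* = 1 − 2|V∩Vₜ|/(|V|+|Vₜ|)`,
   cavity volumes, ejection fraction `EF = (EDV − ESV)/EDV`, Bland-Altman
   agreement, and pixel metrics (accuracy, mean accuracy, mean IOU).

No imaging data is required: a synthetic phantom module generates
3DE-like volumes (dark half-ellipsoid LV cavity, bright myocardial shell,
adjacent atrium behind a mitral opening, multiplicative speckle) with
analytic ground-truth masks and meshes, so the whole pipeline runs and is
tested end-to-end from code.

## Worked example

A training-free run (the coarse stage emulated by degrading the analytic
mask, which is the fastest way to exercise the geometry and the snake):

```r
library(echosnake)

ph     <- generate_phantom(phantom_spec(seed = 7))
coarse <- degrade_mask(ph$mask, seed = 8)
stack  <- slice_volume(ph$volume, coarse)
init   <- initialize_lv_mesh(stack, k = 10)
fit    <- evolve_snake(init$mesh, ph$volume, snake_params())
report <- evaluate_segmentation(fit$mesh, ph$mesh,
                                mask   = voxelize_tube_mesh(fit$mesh, ph$mask),
                                mask_t = ph$mask)
tidy(report)
```

which prints (numbers from this exact session):

```
<lv_volume> 64 x 64 x 80 voxels, spacing 1 x 1 x 1 mm
<lv_initialization> 5 rings (k = 10), apex toward low_z, basal plane 46.0 mm
<snake_fit> 73 iterations (converged), total energy 7.9922, 0 clamped vertices
# A tibble: 1 × 5
    d_m   d_h  dstar volume_ml volume_t_ml
  <dbl> <dbl>  <dbl>     <dbl>       <dbl>
1  2.00  3.02 0.0847      20.9        21.3
```

Reading the row: the refined surface sits on average about 1 mm from the
analytic truth in each direction (`d_m` sums the two directed means), its
worst local disagreement is 3 mm, the voxel overlap dissimilarity `D*` is
0.085 (0 = perfect), and the enclosed cavity volume is 20.9 ml against
21.3 ml truth. `ejection_fraction(100, 60)` returns `0.4`.

Everything composes from tidy pieces: `tidy()`, `glance()` and
`autoplot()` methods exist for training histories (`fcn_fit`), snake
energy traces (`snake_fit`) and Bland-Altman analyses; `plot_slice()`
overlays masks and mesh cross-sections on a slice.

The full pipeline (phantom → coarse → init → refine → eval, with an
artifact manifest of MD5 hashes) is one call:

```r
run <- run_pipeline(run_config(seed = 1, mode = "degraded-truth"))
```

and `mode = "fcn"` trains the toy fusion FCN on the phantom slices first.
A thin command-line front end with subcommands
`phantom | coarse | init | refine | eval | run` is installed at
`inst/cli/echosnake.R`.

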
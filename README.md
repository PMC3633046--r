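# gcvolumes

Automatic extraction and quantification of germinal-center (GC) volumes
from calibrated 3D fluorescence z-stacks.

## The problem

Germinal centers — the lymphoid micro-structures where B cells proliferate
and affinity-mature — appear in confocal z-stacks of immunolabelled tissue
as bright, roughly ellipsoidal volumes separated from moderately bright
tissue background by a *dark halo* of unlabelled cells pressed against the
GC border. Measuring their volumes by tracing contours slice by slice is
slow and subjective. `gcvolumes` replaces that with an automatic pipeline:

1. **Segmentation** — every maximal 26-connected cluster of voxels with
   intensity `>= th`, keeping clusters of at least `smin` voxels
   (`segment_spots()`, flood fill in C++).
2. **Self-tuning of `lambda = (th, smin)`** — the dark halo makes correct
   segmentations *stable under threshold perturbation*. For each cluster
   matched between the segmentations at `lambda` and at
   `lambda' = (th + 1, smin)` the pipeline scores

   ```
   L_j = sum_n exp(alpha * D_n) / (epsilon + beta * sum_n A_n)
   A_n = (|a_n + a'_n| - |a_n - a'_n|) / |a_n + a'_n|
   ```

   with `D_n` the Bhattacharyya distance between the per-slice intensity
   histograms and `a_n, a'_n` the per-slice areas; slices whose contour
   vanishes at `lambda'` contribute `D_n = 1, A_n = 0`. The total
   `sum_j L_j` is minimized over `lambda` by seeded simulated annealing
   with deterministic tie-breaking (`optimize_params()`); defaults
   `alpha = 0.001`, `beta = 1`, `epsilon = 1e-9`.
3. **Quantification and export** — per-GC voxel counts and calibrated
   volumes (`voxels * dx*dy*dz`), per-slice convex-hull contours with
   optional outlier pruning, closed triangulated surfaces in Geomview OFF
   format, label volumes as TIFF, and CSV reports (`gc_report()`,
   `build_surface()`, `run_extract()`).
4. **Mosaics** — overlapping stage tiles are registered by Fourier phase
   correlation, exposure-matched by a per-tile gain, and blended with a
   Laplacian pyramid (`stitch_tiles()`, `run_stitch()`).

A synthetic-phantom generator with analytic ground truth
(`make_phantom()`) supports validation of the whole pipeline without
microscope data.

## Worked example

```r
library(gcvolumes)

# a 16 x 64 x 64 phantom: one ellipsoidal GC (plateau 200) in a dark halo
# (10) on tissue background (80), Gaussian noise sigma 5
ph <- make_phantom(phantom_spec(
  shape = c(16, 64, 64),
  gcs = list(gc_blob(center = c(8, 32, 32), semiaxes = c(5, 12, 12)))))
ph$stack
#> <image_stack> 16 x 64 x 64 (z,y,x), 8-bit, channel ch0
#>   spacing (dx,dy,dz): 1 x 1 x 1.43 um; intensity range 0..217

# tune (th, smin) from a rough initial guess
fit <- optimize_params(ph$stack, segmentation_params(th = 120, smin = 40),
                       seed = 1)
fit
#> <anneal_state> lambda* = (th = 88, smin = 96), objective = 1
#>   1000 proposals, 941 distinct lambda evaluated, seed 1

# segment at lambda* and quantify
seg <- segment_spots(ph$stack,
                     segmentation_params(fit$par[["th"]], fit$par[["smin"]]))
gc_report(seg[[1]], spacing = c(1, 1, 1.43))
#> <gc_report #1> 2971 voxels = 4248.53 um^3, slices 3..13
ph$truth$true_volumes_vox
#> [1] 3015.929

# closed surface export
mesh <- build_surface(seg[[1]], spacing = c(1, 1, 1.43))
euler_characteristic(mesh)   # 2 = watertight genus-0 surface
#> [1] 2
write_off(mesh, "gc_001.off")
```

The selected threshold (88) sits just above the tissue background (80), at
the lower edge of the halo's stability basin — the segmentation border
rests against the dark halo, which is exactly where the model wants it. The
recovered voxel count (2971) is within 1.5% of the analytic ellipsoid
volume (3016 voxels) at noise sigma 5.

A command-line front end is provided in `exec/gcvol`
(`gcvol extract --input 'stacks/*.tif' --outdir out --seed 1`, plus
`stitch`, `phantom` and `sweep` subcommands).

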
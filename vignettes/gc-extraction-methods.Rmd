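---
title: "Self-tuning extraction of germinal-center volumes from 3D z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-tuning extraction of germinal-center volumes from 3D z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gcvolumes)
```

## The measurement problem

Germinal centers (GCs) are transient micro-anatomical structures in lymphoid
tissue where B cells proliferate and mature. In confocal or two-photon
z-stacks of immunolabelled tissue a GC appears as a bright, roughly
ellipsoidal volume of labelled B cells, separated from moderately bright
tissue background by a *dark halo* — a shell of unlabelled follicular and
T-zone cells pressed against the GC border. Quantifying GC volumes by hand
(tracing contours slice by slice) is slow and subjective; the goal of this
package is a fully automatic pipeline: segment every GC in a calibrated
stack, choose the segmentation parameters from the data themselves, and
export per-GC volumes, per-slice contours and closed polygon surfaces.

The pipeline makes three structural assumptions, all of which come from the
staining morphology rather than from any particular instrument:

1. GC voxels are brighter than a global threshold `th`; background and halo
   are not. A single global threshold per stack is adequate because the
   plateau/halo/background ordering holds throughout a well-stained section.
2. A GC is one 3D-connected cluster of above-threshold voxels (26-neighbour
   connectivity by default, so diagonal contact in any direction connects),
   with at least `smin` member voxels; smaller clusters are debris.
3. The dark halo makes correct segmentations *stable*: moving the threshold
   by one intensity level inside the halo's intensity gap barely changes the
   segmented region, whereas a threshold cutting into the GC interior or the
   background changes it abruptly.

Assumption 3 is what allows the parameters to be chosen automatically.

## Segmentation

`segment_spots()` labels every maximal connected component of
`{voxels >= th}` with an explicit-stack flood fill (implemented in C++; the
threshold is inclusive, so `th` is the lowest admitted intensity), discards
components with fewer than `smin` voxels — a cut on the *total 3D* count,
not on per-slice areas, so thin z-columns survive if they are long enough —
and decomposes each surviving cluster into per-slice regions, pixel areas
and intensity histograms. Histograms use 64 bins spanning the full dtype
range `[0, 2^bits)`: coarse enough to be populated by small per-slice
regions, fine enough to separate plateau from background intensities.

## The stability objective

Write `lambda = (th, smin)` and let `lambda'` be the neighbouring parameter
vector `(th + 1, smin)`. After matching the clusters of the two
segmentations by maximal voxel overlap, each matched pair j is scored

```
L_j(lambda, lambda') = sum_n exp(alpha * D_n) / (epsilon + beta * sum_n A_n)
```

where the sums run over the slices carrying a region on at least one side,
`D_n` is the Bhattacharyya distance between the unit-normalized slice
histograms (`D = 1 - sum_k sqrt(Ha_k * Hb_k)`, 0 for identical and 1 for
disjoint histograms), and

```
A_n = (|a + a'| - |a - a'|) / |a + a'|
```

is the similarity of the slice areas: 1 when the areas are equal, 0 when
exactly one side has vanished. On a slice where the cluster vanished at
`lambda'` we set `D_n = 1` and `A_n = 0`, so vanishing contours inflate the
numerator while contributing nothing to the denominator. The defaults
`alpha = 0.001`, `beta = 1`, `epsilon = 1e-9` make the objective of a
perfectly stable cluster with N populated slices equal `N / (epsilon + N)`,
slightly below 1, while a cluster that disappears between neighbouring
thresholds scores on the order of `1/epsilon`. The stack objective is the
sum over matched clusters; it is infinite when nothing segments at
`lambda`.

### Shape of the landscape, and three numerical guards

On phantoms with the canonical intensities (plateau 200, halo 10,
background 80, noise sigma <= 5) the landscape over `th` has a
characteristic shape: a high wall below the background intensity (where the
tissue percolates into one giant cluster that disintegrates between
neighbouring thresholds), a wide flat basin across the halo's intensity gap
(where the segmentation is threshold-invariant, so the objective is exactly
tied), and a steep rise where the threshold cuts into the GC plateau. Three
deliberate numerical choices deal with the flat and degenerate parts:

* **Threshold range.** Candidate thresholds default to
  `[min(voxels) + 1, max(voxels)]`. A threshold at or below the stack
  minimum admits *every* voxel; the resulting whole-image "cluster" is
  perfectly stable and would be a spurious global optimum.
* **`smin` window.** Free `smin` proposals are bounded to
  `[seed/4, 4 * seed]` around the user's initial value. The seeded minimum
  size encodes prior knowledge of the GC scale; without the bound the
  optimizer can inflate `smin` past the GCs themselves, leaving only the
  (stable) tissue background segmented — a solution that is numerically
  optimal by a margin of order `epsilon` but scientifically meaningless.
* **Tie polishing.** After annealing, exact ties (within 1e-12) are
  resolved deterministically toward the smallest `th`, then the smallest
  `smin`: among equally stable solutions the one with the largest admitted
  areas — the border resting against the halo — is preferred. This makes
  `lambda*` a deterministic function of the stack rather than of the
  annealing trajectory, which is what makes reruns and differently seeded
  runs agree.

## Simulated annealing

`optimize_params()` minimizes the stack objective with simulated annealing:
geometric cooling (factor 0.95), 20 proposals per temperature, initial
temperature set to the objective spread of a few probe evaluations around
the seed, stopping when the temperature falls below 1e-3 of its initial
value or after 50 temperatures without improvement. Proposals move `th` by
±1..5 grid steps and scale `smin` by a uniform factor in [0.8, 1.25]
(rounded), clipped to the window above. Acceptance is Metropolis. The run
is fully deterministic given its seed, all evaluations are memoized, and
segmentations are cached per threshold so neighbouring proposals are cheap.
The returned `anneal_state` carries the full proposal history for
inspection.

Annealing rather than grid search is a scale decision: the grid is
`O(intensity range x smin range)` per stack, each cell costing two
segmentations of the full volume, while the annealer typically touches a
few hundred distinct parameter vectors.

## Geometry and export

Volumes are voxel counts times the calibrated voxel volume
`dx * dy * dz` (default `1 x 1 x 1.43` µm, the anisotropy of a typical
confocal z-step). Per-slice contours are convex hulls of the slice regions
(`grDevices::chull`), with the shoelace area; degenerate slices (a single
pixel, or collinear pixels) report their pixel count. `prune_outliers()`
optionally removes contour points beyond `mean + k * sd` of the
center-distance distribution (at most 20% per pass) before hulling, against
staining artifacts. `build_surface()` lofts consecutive slice hulls into a
closed triangulated surface — rings are zipped by polar angle about their
own centroids, fan caps close the ends, single-slice clusters become a
prism of thickness `dz`, and degenerate slices are represented by the
half-pixel corner ring of their bounding box so the mesh stays a closed
2-manifold (Euler characteristic 2, which the tests assert). Surfaces are
written in the Geomview OFF format.

## Mosaics

Fields larger than one stage position are assembled by
`stitch_tiles()`: integer-pixel phase correlation (normalized cross-power
spectrum via `stats::fft` on the maximum-variance z-slice, peak searched
within a window around the stage prior; low peaks fall back to the prior
with a warning), a single multiplicative exposure gain per tile from the
ratio of overlap means, and Laplacian-pyramid blending of overlap strips
(nearest-neighbour up/down pair, so the pyramid reconstructs exactly and
identical overlap content passes through unchanged; overlaps narrower than
16 px use a linear feather). Pixels covered by one tile only are copied
verbatim.

## The phantom generator, and what the tests do and do not show

`make_phantom()` produces stacks with analytic ground truth: ellipsoidal
plateaus (default 200) wrapped in a dark halo ring (default 10, 3 voxels
thick) on tissue background (default 80), plus clipped Gaussian read noise
(default sigma 5) — the staining morphology the pipeline is designed for,
at realistic 8-bit intensities. The test suite asserts, among others, that
the C++ clustering is exactly equivalent to an independent brute-force
flood fill; that the objective obeys its closed forms; that annealing
attains the exhaustive-search minimum on a parameter grid; that optimized
segmentations recover phantoms with Dice >= 0.95 from any initialization;
that volumes are exact for cuboids and within 10% for a digital ball of
radius 10; and that registration recovers known shifts exactly.

Passing these tests shows that the implementation does what the model says
on data satisfying the model's assumptions. It does not show that the model
fits any particular microscope: phantoms have homogeneous plateaus, sharp
halos, stationary Gaussian noise and no attenuation with depth, no vignette
and no touching GCs. On real tissue the threshold stability argument
degrades gracefully with halo contrast, but segmentation of *touching* GCs,
depth-dependent gain and non-ellipsoidal shapes are outside what the test
suite certifies.

## A minimal run

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(
  shape = c(16, 64, 64),
  gcs = list(gc_blob(center = c(8, 32, 32), semiaxes = c(5, 12, 12)))))

fit <- optimize_params(ph$stack, segmentation_params(th = 120, smin = 40),
                       seed = 1)
fit

seg <- segment_spots(ph$stack,
                     segmentation_params(fit$par[["th"]], fit$par[["smin"]]))
gc_report(seg[[1]], spacing = c(1, 1, 1.43))

mesh <- build_surface(seg[[1]], spacing = c(1, 1, 1.43))
euler_characteristic(mesh)   # 2: closed surface
```
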
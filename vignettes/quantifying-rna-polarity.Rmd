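---
title: "Quantifying mRNA polarization at the invasive front: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mRNA polarization at the invasive front: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotfront)
```

## The measurement problem

Leader cells at the tip of collectively invading strands in 3D cancer
spheroids polarize parts of their transcriptome: some mRNAs accumulate in
the invasive protrusion, others stay near the nucleus. With single-molecule
FISH each mRNA appears as one diffraction-limited spot in a confocal
z-stack, so the question "is RNA species A more invasively localized than
species B?" becomes a geometry problem: where do the spots of each species
sit between the nuclear and the invasive edge of the leader-cell front?

`spotfront` implements that measurement end to end:

1. **Masking.** The user outlines the front of the leader cell (from the
   center of the nucleus to the front edge) on one slice; all signal
   outside the outline is cleared in every channel and every slice
   (`apply_front_mask()`).
2. **Spot detection.** Each RNA channel is detected separately
   (`detect_spots()`), giving sub-voxel spot coordinates.
3. **Boundary partition.** Four clicks, clockwise starting from the
   nuclear side, split the outline into *nuclear*, *side1*, *invasive*,
   *side2* segments (`snap_anchors()`); clicks snap to the nearest outline
   vertex, so clicking exactly on the boundary is not required.
4. **Distances.** Every in-outline spot gets its nearest Euclidean
   distance to each of the four segments (`measure_all_spots()`).
5. **Normalization and statistics.** Per image, distances are normalized
   by a cell-specific length scale and the two RNA species are compared
   across images (`run_study()`).

## The normalization model

For one image with $n$ spots (both RNA types pooled), each spot $i$ has a
nuclear distance $Nd_i$ and an invasive distance $Id_i$. The per-cell
total length is

$$L = \frac{1}{n} \sum_{i=1}^{n} (Nd_i + Id_i),$$

and for each RNA type separately, with $n$ now the number of spots of that
type, the mean normalized distance is

$$M = \frac{1}{n} \sum_{i=1}^{n} \frac{Id_i}{L}.$$

$M$ lies in $[0, 1]$ for typical cell shapes: 0 means the species sits at
the invasive edge, 1 at the nuclear edge. Because $L$ rescales with the
cell, $M$ is invariant under uniform rescaling of all distances — cells of
different sizes are comparable. Individual spots in irregular cells can
have $Id_i/L > 1$; these are reported as-is (clipping would bias the
histograms), and a per-image $M$ outside $[0, 1]$ triggers a warning, not
an error.

Cross-image comparison uses **one $(M_{RNA1}, M_{RNA2})$ pair per image**,
never the pooled per-spot values, so a cell with many spots does not
dominate the result. The paired comparison is a two-sided Wilcoxon
matched-pairs signed-rank test. Zero differences are dropped and ties
receive midranks; the null distribution is exact (computed by a
generating-function convolution over the ranks, which remains valid under
ties) for up to 25 usable pairs, and a normal approximation with
continuity and tie correction beyond that. The per-image $M$ values of
each type are also summarized as a Gaussian-kernel density estimate and
the per-spot normalized distances as histograms.

## Spot detection

The detector reproduces a classic single-molecule pipeline:

1. Separable Gaussian pre-smoothing (`smoothing_sigma`, default 1 voxel,
   isotropic in voxel units). Defaults deliberately do **not** rescale the
   z sigma by the voxel anisotropy — behavior stays transparent, and the
   user can pass per-axis sigmas when the anisotropy warrants it.
2. Candidate voxels are strict 3×3×3 local maxima inside the mask — the
   one-voxel image border is excluded, since smoothing there relies on
   replicated padding and its maxima are unreliable — whose smoothed
   intensity exceeds the larger of two thresholds:
   * the **isodata threshold** of the masked voxels — the fixed point
     $T = (\mathrm{mean}(v < T) + \mathrm{mean}(v \ge T))/2$, iterated
     from the global mean until the change is below 0.5 intensity levels;
   * a **robust noise floor** `median + noise_k * scale * ||k||₂`, where
     `median` and `scale` ($1.4826 \times \mathrm{MAD}$) are measured on
     the masked voxels of the *raw* channel and $||k||_2$ is the
     smoothing kernel's white-noise attenuation factor (the product of
     the three 1-D kernel norms), converting the raw noise scale to
     smoothed units. Measuring on the raw volume matters in spot-dense
     cells: after smoothing, every spot's halo covers hundreds of voxels
     and the halos can blanket the whole mask, inflating any smoothed-
     volume estimate, whereas raw spot footprints stay a small minority
     against the unsmoothed noise. `noise_k` defaults to 5.
   The isodata threshold adapts to bright in-cell structure; the noise
   floor protects against the no-signal case, where isodata would happily
   split pure noise in half.
3. Peaks closer than `min_separation` voxels (per-axis, default 3) are
   pruned, keeping the brighter; equal-intensity plateau ties resolve to
   the voxel earliest in (z, y, x) scan order, which makes detection fully
   deterministic.
4. Centers are refined by an intensity-weighted centroid over the in-mask
   3×3×3 window, after subtracting the window's minimum so that a constant
   intensity offset cannot pull the centroid toward the window center
   (detection is then exactly invariant to adding a constant to the whole
   image). No Gaussian fitting is attempted — centroid refinement is
   accurate to well under a voxel at the SNRs where detection is reliable,
   and keeps the detector free of optimizer tuning.

Coordinates are 0-based voxel indices with spot positions at voxel
centers; distances are reported in pixels by default (`units = "um"`
converts using the lateral voxel size, 0.1 µm by default).

## Distance geometry

Distances are **2-D**, in the x–y plane: the outline is drawn on one slice
and applied through the whole stack, so the boundary is a vertical prism
wall and the 3-D distance to it equals the 2-D distance. The z coordinate
is carried through the output tables but never enters a distance.
Distances go to segment *edges* (perpendicular foot or nearest endpoint),
not merely to the vertex set — strictly more accurate for coarsely drawn
outlines. Spots exactly on the outline count as inside; the four segments
share only their anchor vertices, so the minimum of the four distances
equals the distance to the whole outline.

Polygon orientation is normalized by signed area before the clockwise
anchor check, so outlines may be supplied in either orientation; the
anchor *click order* is what must be clockwise, and a counter-clockwise
click sequence raises an error telling the user to re-click.

## What the synthetic scenes emulate — and what they do not

`make_scene()` builds a 4-channel stack (nuclear, cell mask, RNA1, RNA2)
at the assay's anisotropic sampling: an elongated capsule-shaped cell with
a nuclear disc at the rear, spots rendered as anisotropic Gaussian PSFs
(σ ≈ 1.3 px laterally, 1.5 px axially — roughly a confocal PSF sampled at
half its width), Poisson shot noise on top of a constant background
(100 counts) and Gaussian read noise (σ = 2 counts). Spot axial positions
follow a truncated-exponential law tilted toward the invasive pole:
density ∝ exp(r·u) on u ∈ [0, 1], with rate r = 8β for bias β ∈ [0, 1],
so β = 0 is uniform (M ≈ 0.5). `bias_for_shift()` inverts the
rectangle-limit expectation E[u] = 1/(1−e^{−r}) − 1/r to hit a requested
M shift. Planted spots of the same species keep a minimum 3-D spacing
(default 3 voxels; the generator errors when the cell cannot host the
request) — emulating resolvable single molecules.

The scenes are deliberately idealized: the PSF is Gaussian rather than
measured, the noise is spatially homogeneous, there are no follower cells,
no autofluorescent matrix, no transcription-site clusters, and the outline
is known exactly rather than hand-drawn. Passing tests on these scenes
therefore validates the *computations* — detection at a stated SNR,
distance geometry, normalization and the paired test — not robustness to
every artifact of real spheroid imaging; segmentation of the leader cell
itself remains a manual, expert step, as in the original workflow.

Two details of the generator matter when interpreting simulation results.
First, the realized M shift of a tilted species is attenuated relative to
the rectangle-limit target (the curved caps and the pooled normalization
both pull M toward 0.5; a planted target shift of 0.25 realizes as roughly
0.13 in the default capsule). The study-level tests are defined in terms
of the planted generator conditions. Second, uniform placement in the
capsule yields M just below 0.5 (≈ 0.48–0.50) because off-axis spots have
$Nd_i + Id_i$ slightly above the axial length, inflating L.

## Numerical choices and degenerate inputs

* **Isodata** iterates at most 500 times with a 0.5-level convergence
  tolerance; a constant volume has no threshold and raises an error. In
  `detect_spots()` a constant masked region simply disables the isodata
  branch (the noise floor remains).
* **Noise scale** requires ≥ 100 masked voxels; `mad()`'s normal-consistent
  constant 1.4826 is used throughout.
* **KDE**: Gaussian kernel, Silverman's rule-of-thumb bandwidth (`nrd0`),
  512 grid points on [−0.2, 1.2]; the bandwidth is floored at twice the
  grid step so the grid always resolves the kernel (otherwise
  near-identical M values collapse the density between grid points), and
  the bandwidth used is recorded in the output metadata. Fewer than two distinct M values skip the KDE with a warning;
  histograms (20 bins on [0, 1]) are still produced.
* **Paired test**: fewer than two usable pairs is an error (all-zero
  differences — e.g. comparing a vector with itself — has no usable
  pairs).
* **Ties** in snapped anchors (two clicks on one vertex) and
  counter-clockwise click order are errors that name the fix.
* **TIFF layout**: stacks are written 16-bit, one page per z-slice with
  channels as samples per pixel. Grayscale-page (planar) stacks are read
  assuming ImageJ hyperstack order (channel fastest); a page count not
  divisible by the channel count is ambiguous and rejected rather than
  guessed. Voxel size comes from configuration, as TIFF metadata for it
  is not portable.

## Problem sizes in the test suite

The suite runs entirely on synthetic scenes: detection tests use
8×64×64-voxel stacks with ≤ 25 spots per channel; statistical calibration
uses tabular (unrendered) studies of 12 images × 40 spots per type —
100 null studies for the type-I check and 50 studies at a planted effect
for the power check; geometry oracles use 10⁴-point dense boundary
sampling. These sizes were chosen so that every property has comfortable
statistical resolution at interactive runtimes.

## Limitations

* Distances are 2-D by design; a cell whose protrusion bends sharply in z
  would need a per-slice outline, which the workflow (like the original)
  does not attempt.
* The four-segment partition relies on the user's four clicks; there is no
  automatic detection of the nuclear or invasive side.
* Only two RNA species are compared; multi-species omnibus testing and
  mixed-effects modeling across spheroids are out of scope.
* Lateral (side1/side2) distances are recorded in every table but not
  summarized — only nuclear and invasive distances enter L and M.
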
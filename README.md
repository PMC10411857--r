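# spotfront

Quantifying mRNA polarization at the invasive front of leader cells in 3D
cancer spheroids.

## The problem

In collectively invading spheroids, the leader cell at the tip of a strand
localizes some mRNAs to its invasive protrusion and keeps others near the
nucleus. With single-molecule FISH, every mRNA is one diffraction-limited
spot in a multi-channel confocal z-stack (channel 1 nuclear stain,
channel 2 whole-cell stain, channels 3–4 the two RNA species). `spotfront`
turns those stacks into a per-cell polarity statistic and a cross-cell
comparison of the two species. It is written for microscopists running
smFISH on 3D invasion models who want a reproducible, scriptable
replacement for a manual click-through analysis.

## The measurement

Per image (one leader-cell front, outlined by the user and split by four
clockwise clicks into *nuclear*, *side1*, *invasive*, *side2* boundary
segments), every in-outline spot *i* gets its nearest distance to each
segment. With *Nd*ᵢ and *Id*ᵢ the nuclear and invasive distances, the
cell's length scale is

    L = (1/n) Σᵢ (Ndᵢ + Idᵢ)        (n = all spots, both species)

and each species' mean normalized distance is

    M = (1/n) Σᵢ Idᵢ / L            (n = spots of that species)

M runs from 0 (at the invasive edge) to 1 (at the nuclear edge). Across
images, the per-image (M₁, M₂) pairs — never the pooled spots, so
spot-rich cells don't dominate — are compared with a two-sided Wilcoxon
matched-pairs signed-rank test, plus kernel density estimates of M and
per-spot histograms.

Spot detection per RNA channel: Gaussian smoothing, then 3×3×3 local
maxima above max(isodata threshold, median + k·MAD·1.4826 noise floor),
minimum-separation pruning, and intensity-weighted centroid refinement.

## Worked example

```r
library(spotfront)

# a synthetic leader cell: 4-channel 8x64x64 stack, 15 spots per species
scene <- make_scene(n_spots = c(15, 15), min_spacing = 5, snr = 10, seed = 42)
scene
#> synthetic_scene: 8x64x64 (z,y,x), 30 planted spots (15/15), snr 10, seed 42

# single-image pipeline: mask -> detect -> partition -> measure -> tables
res <- run_image(scene$stack, scene$polygon, scene$anchors, "out_demo")
head(res$records[, c("x", "y", "z", "d_nuclear", "d_invasive", "type")], 3)
#>        x     y     z d_nuclear d_invasive type
#> 1 52.812 39.80 2.953    35.276      2.529    1
#> 2 55.284 32.89 2.999    39.357      3.574    1
#> 3  8.112 37.80 3.077     2.223     37.684    1

# a 12-image study in which RNA1 is shifted toward the invasive edge
study <- make_study(n_images = 12, effect = 0.25, seed = 7)
cmp <- run_study(study$pooled, "out_study")
cmp
#> comparison_result: 12 images
#>   mean M: RNA1 0.347, RNA2 0.518
#>   signed-rank V = 0, p = 0.0004883 (exact, n = 12)
```

The spot rows show each detected molecule's sub-voxel position (0-based
pixels) and its nearest distances to the nuclear and invasive boundary
segments; spot 3 sits 2.2 px from the nuclear segment, 37.7 px from the
invasive one. In the study, RNA1's mean normalized distance (0.347) is
below RNA2's (0.518) in every one of the 12 images, so the signed-rank
statistic is 0 and the exact two-sided p-value is 2/2¹² ≈ 0.00049: RNA1 is
significantly polarized toward the invasive front. `out_study/` holds the
per-image `summary.csv`, `stats.json`, and the KDE/histogram TIFFs.

For real data the entry points are the same: `read_stack()` +
`read_polygon()` (ImageJ `.roi` or CSV) + four anchor clicks into
`run_image()` per image, then pool the per-image tables into one CSV with
an `image` column and call `run_study()`. A thin command-line wrapper with
`simulate` / `detect` / `analyze` subcommands is installed at
`inst/cli/spotfront.R`.

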
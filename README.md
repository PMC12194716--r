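# cassfcm

Content-aware image smoothing by spatial fuzzy c-means clustering, with a
local-homogeneity framework for evaluating the result.

## The problem

Smoothing regularizes an image before analysis. Content-unaware smoothers
(Gaussian blur, and diffusion-style methods at their limit) treat every
pixel alike and eventually blur region boundaries away — a real problem
for imagery such as immunohistochemistry patches, where brown-stained
protein deposits must be homogenized internally *without* bleeding into
the textured tissue background. `cassfcm` implements a content-aware
smoother built on soft clustering: it regularizes tones inside the
distinct regions of an image while preserving the boundaries between
them, and it converges to a non-trivial state (a piecewise-homogeneous
image, not a flat one).

## The method

Every pixel of an image `I : Ω → T` becomes an instance
`(x, y, t1, …, tk)` in the joint spatio-tonal universe `Ω × T` (positions
normalized by `max(M, N)`; tones in CIELab). Fuzzy c-means is run on this
dataset with `r` clusters (the number of distinct regions you see in the
image), under the convex spatio-tonal metric

```
d_ψ(a, b) = α · d_τ(â, b̂) + (1 − α) · d_ω(ã, b̃),   α ∈ [0, 1],
```

where `d_τ` is the Euclidean distance on CIELab tones, `d_ω` the
Euclidean distance on positions, and `α` weighs tonal against spatial
information (`α = 1`: cluster purely by color; `α = 0`: purely by
position, i.e. content-unaware). Centroids start as `r` random instances
(Forgy initialization). At every iteration `t` the algorithm updates the
centroids `C_t` and memberships `μ_{t,i}` (standard fuzzy c-means updates
under `d_ψ`; the memberships form a Ruspini partition), then paints the
iteration image

```
I_t(x, y) = Σ_i μ_{t,i}(q) · Ĉ_{t,i}
```

from the centroid *tonal* parts `Ĉ_{t,i}`. The loop stops when the mean
per-pixel tonal difference between consecutive images,
`Φ(I_t, I_{t−1}) = |Ω|⁻¹ Σ d_τ(I_t(x,y), I_{t−1}(x,y))`, falls below a
tolerance `δ` — so the sequence `I_0, I_1, …` is progressively smoother
and ends at `r` stable region tones.

For evaluation the package computes local homogeneity maps
`H(x, y) = 1 − max_window + min_window` on unit-normalized channels
(1 on flat patches, 0 across full-contrast edges; multichannel maps
average the per-channel ones), and summarizes them per ground-truth
region and over a boundary band — the diagnostic used to verify that
interiors get flatter while boundaries do not.

## Worked example

Smooth a synthetic immunostain-style fixture (textured light-blue
background, two darker brownish deposits, 30 CIELab units of contrast)
and check what happened to the homogeneity:

```r
library(cassfcm)

fx <- blobFixture(size = 128, contrast = 30, seed = 7)
tr <- runSfcm(fx$image, smoothingConfig(r = 2, alpha = 0.5,
                                        delta = 0.05, seed = 7))
tr
#> SmoothingTrace: 6 iterations (converged), 128 x 128 grid, r = 2, alpha = 0.5
#>   final v = 0.0394932 (delta = 0.05)
round(convergenceDiffs(tr), 4)
#> [1] 1.7670 1.0623 2.5164 1.7403 0.2406 0.0395
```

The run converged in 6 iterations: the inter-iteration difference `v`
(CIELab units per pixel) rises briefly while the randomly-initialized
centroids find the two regions, then collapses below `δ = 0.05`.
Homogeneity before:

```r
band <- edgeBand(fx$labels, 7)   # 7-pixel band centered on the boundary
H0 <- multichannelHomogeneity(normalizeUnit(fx$image), 2)
regionMeanHomogeneity(H0, fx$labels, band)
#>  region mean_homogeneity n_pixels
#>       1        0.9415977    13042
#>       2        0.9415419     1479
#>    band        0.9035727     1863
```

and after (`homogeneityReport` evaluates trace iterations; iteration 6 is
the converged image):

```r
homogeneityReport(tr, fx$labels, iterations = 6, n = 2, bandWidth = 7)
#>  iteration region mean_homogeneity n_pixels
#>          6      1        0.9916561    13042
#>          6      2        0.9935620     1479
#>          6   band        0.9354284     1863
```

Both region interiors became markedly flatter (0.94 → 0.99) while the
boundary band stayed the *least* homogeneous part of the image — the
deposit edges were preserved, not smoothed away.

Fixture generators for the other study images (`cubeFixture` — five
regions for cluster-count experiments; `coherenceFixture` — pink/green
images with decreasing spatial coherence for choosing `α`) and the
experiment drivers (`sweepClusters`, `sweepAlpha`,
`initSensitivityExperiment`) work the same way; see the vignette.

## Command line

```sh
cassfcm fixtures blob-deposit --size 128 --seed 7 -o fx/
cassfcm smooth fx/image.png -r 2 --alpha 0.5 --delta 0.05 -o out/
cassfcm evaluate out/iter_*.png --mask fx/labels.png --band-width 7 -o report.csv
```

`smooth` writes the numbered image sequence (`iter_0000.png`, …), a
per-iteration `v` log and a YAML manifest from which `rerunManifest()`
reproduces the run bit-identically. Exit codes: 0 converged, 3 iteration
cap reached, 2 usage error.

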
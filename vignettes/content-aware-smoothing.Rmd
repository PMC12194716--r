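---
title: "Content-aware smoothing with spatial fuzzy c-means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-aware smoothing with spatial fuzzy c-means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassfcm)
```

## The model

`cassfcm` smooths an image by clustering its pixels, not by filtering
them. An image $I:\Omega\mapsto T$ on an $M\times N$ grid is mapped to a
dataset with one instance $(x, y, t_1,\dots,t_k)$ per pixel: the
*spatio-tonal universe* $\Omega\times T$. Fuzzy c-means with $r$ clusters
is run on this dataset under the convex metric

$$d_\psi(a,b) \;=\; \alpha\, d_\tau(\hat a,\hat b) \;+\;
  (1-\alpha)\, d_\omega(\tilde a,\tilde b),$$

with $d_\tau$, $d_\omega$ Euclidean on the CIELab tones and the
normalized positions respectively. At iteration $t$ the algorithm holds
$r$ centroids $C_{t,i}\in\Omega\times T$ and membership functions
$\mu_{t,i}:\Omega\mapsto[0,1]$ forming a Ruspini partition
($\sum_i \mu_{t,i}(p)=1$ at every pixel). The iteration image is the
membership-weighted convex combination of the centroid *tonal* parts,

$$I_t(x,y)=\sum_{i=1}^{r}\mu_{t,i}(q)\cdot \hat C_{t,i},$$

and the loop stops when the mean per-pixel tonal difference
$\Phi(I_t,I_{t-1})=\frac{1}{|\Omega|}\sum_{(x,y)}
d_\tau\!\big(I_t(x,y),I_{t-1}(x,y)\big)$ drops below the tolerance
$\delta$. Because each pixel's tone is pulled toward the tones of the
clusters it belongs to — and the clusters are global objects, not local
windows — regions homogenize internally while boundaries between
tonally distinct regions survive, and the sequence converges to a
piecewise-homogeneous image rather than to the flat mean tone that
diffusion-style smoothers approach.

The update formulas are the standard fuzzy c-means ones with $d_\psi$
substituted for the distance:
$\mu_i(p) = \big[\sum_j (d_\psi(p,C_i)/d_\psi(p,C_j))^{2/(m-1)}\big]^{-1}$
and $C_i = \sum_p \mu_i(p)^m\, p \,/\, \sum_p \mu_i(p)^m$, the centroid
update running over the full $2+k$ coordinates. The framework
generalizes the *metric*, not the membership functional: no
neighborhood-window spatial weighting is applied inside the membership
update, so `alpha` is the single, interpretable control over how much
position matters. Within one iteration the centroid update precedes the
membership update, and the initial memberships are computed from the
Forgy draw before the loop.

## Parameters

* **`r`** (clusters) — the number of distinct regions the user sees in
  the image. Deliberately manual: automating it would couple the
  smoother to a model-selection heuristic. Under-estimating `r` merges
  tonally close regions; over-estimating splits regions into tonal
  sub-bands (`sweepClusters()` makes both visible).
* **`alpha`** $\in[0,1]$ — tonal-vs-spatial weight, dimensionless.
  Default 1 (tonal only). Use lower values when regions are defined by
  position as much as by color (`sweepAlpha()` on the coherence
  fixtures illustrates the regimes; `alpha = 0` is content-unaware and
  clusters by position alone).
* **`delta`** — convergence tolerance on $\Phi$, in CIELab units per
  pixel. Default 0.05: differences this size are far below a just
  noticeable color difference. `delta = 0` disables the test and runs to
  the cap, which is how the experiment drivers obtain an exact number of
  iterations.
* **`m`** — fuzzifier, dimensionless, default 2 (the customary fuzzy
  c-means choice). Crisper values ($m\to1$) harden memberships toward
  k-means behavior; see Limitations.
* **`maxIter`** — iteration cap, default 200.
* **`seed`** — one seeded generator drives the whole run (Forgy draw and
  empty-cluster re-seeding), so a `(config, seed)` pair reproduces a
  trace bit-identically.
* **`divisor`** — spatial scaling. How positions and CIELab values
  should be co-scaled before combination has no canonical answer, so
  the convention is explicit: default `"max-dim"` divides both axes by
  $\max(M,N)$ (aspect preserved, coordinates in $[0,1]$); `"per-axis"`
  and `"none"` are available.
* **Homogeneity window `n`** — radius of the $(2n+1)^2$ window, default
  2 (a 5×5 window: one scale above trivial, still local at the 128-pixel
  fixture scale). **Band width `w`** — default 7 pixels, centered on the
  boundary (Chebyshev geometry, matching the square window of the
  operator; Euclidean optional).

## Color handling

sRGB input is converted to CIELab under the D65/2° observer (the de
facto standard; `grDevices::convertColor` supplies the conversion).
Grayscale images are lifted to luminance-only Lab, $(100\cdot g, 0, 0)$,
so a single metric and reconstruction path serves $k=1$ and $k=3$. All
smoothing runs in CIELab; conversion back to sRGB happens only at file
write time. The homogeneity operator instead requires channels in
$[0,1]$: `normalizeUnit()` maps CIELab by the *fixed* nominal ranges
($L/100$, $(a+128)/255$, $(b+128)/255$) rather than per-image extrema,
so maps from different iterations of one run remain comparable.

## Numerical choices

* **Zero distances.** A pixel coinciding with one or more centroids
  takes membership split equally over the zero-distance centroids and 0
  elsewhere — the symmetric choice that preserves the Ruspini partition.
* **Empty clusters.** A cluster whose membership mass underflows is
  re-seeded from a uniformly random instance, keeping `r` at the user's
  declared region count instead of silently dropping a cluster.
* **Homogeneity borders.** Window extrema are taken over the in-grid
  subset only; no padding. Consequently a ramp edge pixel sees a
  truncated window, which the tests pin down exactly.
* **Band geometry.** A label change is marked on the first pixel of each
  differing 4-adjacent pair, then dilated by $\lfloor w/2\rfloor$; a
  straight boundary yields exactly $w$ full rows/columns.
* **Exact-iteration runs.** The initialization-sensitivity and sweep
  drivers run with `delta = 0` for exactly `nIters` iterations; if a
  run's image sequence stops changing earlier, the final image is
  carried forward so every iteration index is populated.

## The synthetic fixtures

The experiments run entirely on generated imagery with exact ground
truth; palettes are stated directly in CIELab so metric-space contrasts
are controlled:

* **`cubeFixture()`** — an isometric cube (three orange-family faces)
  on a two-part blueish background: five regions, pairwise tone
  separation > 20 CIELab units. Default noise 0: a clean rendered test
  figure whose regions are internally constant, the setting for
  cluster-count experiments.
* **`coherenceFixture()`** — two-region pink/green images with identical
  tonal content and decreasing spatial coherence: A (compact disc,
  blended rim), B (compact disc over speckled background), C (pink
  pixels scattered iid — an exact count, so the pink fraction is exact).
  These separate what `alpha` does.
* **`blobFixture()`** — the immunostain-style case: textured light-blue
  background, 1–3 darker brownish deposits at a prescribed CIELab
  contrast (default 30), Gaussian-blurred boundaries, speckle texture
  everywhere. Ground-truth labels are the crisp pre-blur geometry.

Default size is 128×128: large enough that band statistics and
autocorrelation checks are stable, small enough that a full 100-iteration
trace takes about a second. What the fixtures deliberately do *not*
reproduce: real histology optics (uneven illumination, chromatic stain
variation), anti-aliasing of rendered figures, and 1D curvilinear
structures. Tests passing on these fixtures therefore demonstrate the
clustering and reconstruction mechanics and the boundary-preservation
behavior on blob-like geometry — not performance on arbitrary natural
images.

## Design decisions that were genuinely open

* **Fuzzifier default.** The method description leaves $m$ unstated;
  $m=2$ is adopted as the field's default. The oracle cross-checks also
  use $m=2$.
* **Spatial scaling.** Positions divided by $\max(M,N)$ so one divisor
  preserves aspect ratio (configurable). Tonal values stay in native
  CIELab units for the metric — only the homogeneity operator uses the
  $[0,1]$ embedding.
* **Initialization.** Forgy (random instances) only; fancier schemes are
  out of scope, and the initialization-sensitivity experiment exists
  precisely to show that after tens of iterations the Forgy draw barely
  matters.
* **Cube noise default 0.** The cluster-count experiments reason about
  exact tone counts; a clean piecewise-constant figure is the setting in
  which those counts are well defined. Noise is a parameter for the
  experiments that need texture (e.g. demonstrating sub-region splitting
  at large `r`).

## Limitations

* **Residual tonal mixing under coarse `r`.** With $m=2$, a region at
  tonal distance $d$ from its cluster centroid is reconstructed offset by
  roughly $d^2/D$ toward the other centroid ($D$ the inter-centroid
  distance). When `r` under-counts the regions (two tonal families merged
  into one cluster each), the members of a family therefore keep small
  but nonzero tone differences — visually one tone, but countable as
  distinct values at sub-unit rounding. Only near-crisp fuzzifiers
  remove this, at the cost of k-means-like initialization brittleness.
* **Initialization can trap centroids.** If the Forgy draw puts two
  centroids in one region and none in another, the fuzzy updates do not
  always redistribute them (especially on noisy data); the run converges
  to a merged/split labeling. On the clean cube this resolves well at
  $m=2$, but it is the main failure mode to watch with more clusters.
* **Exactly duplicated instances.** On noise-free imagery two Forgy
  draws can be *identical* instances; such centroid pairs evolve
  identically forever and the run degenerates (for `r = 2`, to a flat
  image). Any nonzero noise removes the exact symmetry.
* **1D structures.** Thin lines and curvilinear detail occupy little
  spatio-tonal mass and can be absorbed into surrounding clusters;
  reduce the spatial weight or use a local-information smoother for
  such imagery.
* **Homogeneity is descriptive.** The homogeneity summaries characterize
  *how* a run develops (interiors flatten, bands keep contrast); they are
  not a standalone quality score for ranking different algorithms.

## Problem sizes used by the test suite

Unit tests run on grids from 1×2 to 20×20 with brute-force oracles
(double-loop fuzzy c-means iteration, explicit window scans, reference
colorimetric formulas); the end-to-end property checks and
`scripts/acceptance.R` use the 128×128 fixtures with 100-iteration or
converged runs, and a 10-seed initialization-sensitivity experiment at
50 iterations — the package's standard study configuration.
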
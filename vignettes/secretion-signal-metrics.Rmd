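---
title: "Position-aware inequality metrics for secretion-signal maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-aware inequality metrics for secretion-signal maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s2map)
```

## The measurement problem

A single secreting cell sits at the center of an imaging field; each frame is
a non-negative intensity matrix, and the biology of interest is *where* the
secreted signal goes, not only how much of it there is. Classic inequality
statistics (Gini, entropy, Herfindahl) are permutation-invariant: they see
the histogram of intensities and discard position, so a signal plume to the
left scores the same as one to the right or one at the center. The package's
core statistics keep position.

## Degree of inequality and its derivative

For a profile $x_1,\dots,x_n$ (an axis projection of a map) the degree of
inequality is the average doubled gap between the *unsorted* Lorenz curve
and the equality diagonal:

$$DI = \frac{1}{n}\sum_{k=1}^{n} 2\left(\frac{\sum_{i\le k} x_i}{\sum_i x_i}
 - \frac{k}{n}\right) \in [-1, 1].$$

Because the profile is not sorted, $DI$ is linear in the mass distribution:
it equals $(n + 1 - 2\bar{k})/n$, where $\bar{k}$ is the intensity-weighted
mean pixel index. Three consequences drive the package design:

* **scale invariance** — intensities enter only as shares, so detector gain
  cancels;
* **resolution invariance** — duplicating every pixel leaves $DI$ exactly
  unchanged;
* **centroid dependence** — any resampling of a map that conserves mass and
  centroid leaves $DI$ of the projections unchanged.

The pixelwise derivative of the prefix-DI curve collapses to
$\partial DI(k) = x_k/\sum x - 1/n$ (with $DI(0)=0$), the excess share over
uniform. Pixels with $\partial DI > 0$ are *signal units*, the rest *noise
units*; their ratio is the SNR, and the center-weighted SNR is

$$CWSNR = SNR \cdot \sum_i V(i)\,W(i),$$

with $V = \max(\partial DI, 0)$ and $W$ a semicircular weight profile. The
2D composites are the Euclidean norms over the two axis projections:
$SII = \sqrt{DI_x^2 + DI_y^2}$ (dissymmetry) and
$SCI = \sqrt{CWSNR_x^2 + CWSNR_y^2}$ (central coverage of asymmetric
signal).

Although each $|DI| \le 1$ implies $SII \le \sqrt 2$, values above 1 require
extreme corner concentration on *both* axes at once; the package does not
clamp $SII$ and documents $\sqrt 2$ as the attainable bound.

## Numerical conventions

Degenerate inputs follow one rule: an all-zero profile is the limit of a
uniform profile, so $DI = 0$, $\partial DI = 0$, $SNR = 0$, $CWSNR = 0$.
A profile with no noise units cannot arise from a real projection (some
pixel is always at or below the uniform share), but `signal_noise_ratio()`
is callable on arbitrary vectors and then caps the ratio at the signal
count, with a warning, rather than returning infinity.

The center weights use offsets from the geometric axis center,
$o_i = |i - (n+1)/2|$, and half-span $h = (n-1)/2$, giving exactly 1 at the
center pixel of an odd axis and exactly 0 at both endpoints. For an even
axis the two central pixels sit at offset $1/2$ and share the maximum
weight $\sqrt{1 - 1/(n-1)^2}$. This keeps the three anchor properties
(center 1, endpoints 0, semicircular in between) exact at every $n$; the
alternative of pinning the even-axis center value to $\sqrt{1 - 1/n^2}$
differs by $O(1/n^2)$ and cannot coexist with zero endpoints on a true
semicircle.

The Theil index needs a guard against $\log 0$; the implementation shifts
all values by $\varepsilon = 0.01$ *and* takes the mean over the shifted
values, so perfect equality scores exactly 0 and the index stays in
$[0,\infty)$. Shannon entropy uses base 2 (bits); Theil uses the natural
log. Formulas are stated 1-based; storage is 0-based R vectors, and the
conversion lives entirely inside the inequality module.

## The simulators

`simulate_1d()` provides the twelve stages of four 5-pixel models (shifting,
shaping, spreading, propagating); three stages share the same centered
start, leaving the ten distinct scenarios of `scenario_profiles_1d()`. The
shaping stages are the permutations of densities (3, 2, 1) over the right
three pixels; the stage order (b1 = 2,3,1; b2 = 3,2,1; b3 = 1,2,3) is the
unique assignment consistent with the intended CWSNR ranking
b2 > b1 > b3, b2 being the maximal permutation.

`metric_separation()` reports the number of distinct (DI, CWSNR) pairs over
the number of scenarios. Ties always involve at least two scenarios, so an
"accuracy of 0.9 with one indistinguishable scenario" means nine distinct
values among ten scenarios: the uniform spread (c3) and the endpoint
propagation (d3) both score (0, 0) — the endpoints carry zero center weight,
so their positive derivatives contribute nothing.

`simulate_2d()` builds the four diffusion models on a square grid, default
$51\times 51$ with the center pixel at 0-based (25, 25): an odd grid admits
the exact center the formulas assume. At time $t$ the pattern occupies
Euclidean distances $[4(t-1), 5(t-1)]$ from the center with amplitude
$5000/(5(t-1))$ — signal decays with the outer distance. The translation
model uses the *same* inner-to-outer span collapsed onto the center row
(cells at distance 4(t−1) through 5(t−1) to the right). A point footprint
was considered and rejected: the spanned segment is what makes the
translation model's x-axis CWSNR at 0° (≈ 0.04) and its SII sequence
(0.176, 0.353, 0.529 at t = 2, 3, 4) internally consistent with the annulus
models' construction, whereas a single translated pixel yields systematically
smaller values (0.157, 0.314, 0.471).

`rotate_map()` resamples by forward bilinear mass splatting: each source
cell's intensity is distributed over the four cells around its rotated
position (quarter turns reduce to exact index permutations). Splatting
conserves total mass exactly and preserves the intensity centroid, so SII
is rotation invariant to machine precision — the observed sweep variance is
~1e−33. Nearest-neighbor resampling was rejected because on sparse patterns
it can drop entire source pixels (up to half the mass of a two-pixel
footprint at some angles) and injects rasterization noise of order $1/n$
into SII.

What the simulators do *not* emulate: detector noise, photobleaching and
drift, sub-pixel cell displacement, non-radial diffusion anisotropy, and
overlapping signals from neighboring cells. Tests passing on simulator
output therefore validate the metric algebra and its invariances, not
robustness to those acquisition artifacts; the pipeline's averaging,
baselining and cutoff stages exist precisely because real data contain
them.

## The time-series pipeline

Stages run in a fixed order — crop/aggregate, window-average, baseline,
cutoff, metrics — and each stage is individually skippable, so the assembled
pipeline with everything disabled reproduces `metric_series()` exactly.
Defaults mirror a 30-minute cytokine-secretion recording:

* `crop_size = 250`, `block = 5` — a centered 250×250 crop pooled into a
  50×50 grid by block *sums*; sums conserve photon-count-like mass, and the
  metrics' scale invariance makes sums and means equivalent;
* `window_minutes = 1` — each requested time point averages the frames in
  the half-open window $(t-1, t]$ minutes, taming frame-to-frame flicker;
* baselining is per pixel against the 0-minute frame, with the *smaller* of
  the two values as baseline, so outputs are non-negative and pixels that
  dipped below their starting level are neutralised rather than going
  negative into the Lorenz machinery;
* `cutoff_mode = "fraction_of_peak"` with value 0.10 zeroes delta signal
  below 10% of the series' peak delta; in delta mode negative increments are
  clipped to 0 before the cutoff.

Pearson comparison of two metric series uses the exact $t$ transform
($t = r\sqrt{(n-2)/(1-r^2)}$, two-sided, $n-2$ degrees of freedom) via
`stats::cor.test`; series shorter than 3 points or with zero variance are
refused rather than silently returning `NA`. Clustering uses Euclidean
distances between temporal metric vectors; only the distance is fixed by
the method, so the linkage is configurable with average (UPGMA) as the
default — a neutral middle ground between single linkage's chaining and
complete linkage's outlier sensitivity.

## Rendering

The map figure stacks three layers: an RBF-interpolated heatmap of the
delta signal, contour lines for delta and/or cumulative signal (cumulative
levels below a configurable cutoff are suppressed), and a velocity layer
with arrows that start at the strongest surface peaks and follow the
negative gradient toward the valleys. Hotspots are the largest surface
values after 3×3 non-maximum suppression — a deliberate, simple definition,
since any peak notion on a smoothed surface is somewhat arbitrary. The RBF
system is solved densely with a constant-term augmentation (weights sum to
zero), so a flat map interpolates to an exactly flat surface under every
kernel; without the augmentation a narrow Gaussian kernel visibly rings
between nodes. The dense solve costs $O(N^3)$ in the number of cells, hence
the guard at 4096 nodes: aggregate first, then interpolate.

## Problem sizes and determinism

The test suite exercises profiles up to length 60, maps up to $51\times51$,
and scaling runs on random matrices of side 400–3200 with five repetitions
per size (seeds are fixed; timings are recorded but never asserted as
wall-clock values — only the growth trend is checked, and it is close to
linear in pixel count). The acceptance script is fully deterministic given
its seed. All randomized property tests draw from fixed seeds.

## Known limitations

* SII is blind to centrally symmetric structure by construction: every
  circular-propagation frame scores exactly 0 regardless of ring radius;
  SCI is the complementary lens.
* CWSNR changes discontinuously when a pixel's share crosses the uniform
  share $1/n$ (a unit flips between signal and noise), so tiny intensity
  perturbations near that threshold can move SCI visibly.
* The rotation model treats the map as a continuous mass field; patterns
  rotated close to the grid boundary lose the mass that leaves the grid.
* Correlations between two cells' metric series assume aligned, equally
  long recordings; there is no time-warping or resampling.
* The fraction-of-peak cutoff ties the threshold to the series' own peak,
  which is robust to gain but not to a single hot outlier pixel.
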
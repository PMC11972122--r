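# s2map — secretion-signal map analytics for single-cell imaging

Single-cell secretion imaging (for example label-free LSPR imaging of
cytokines released by an immune cell) produces time series of 2D intensity
maps: one secreting cell in the middle of a sensor field, with signal
accumulating around it. Two cells can secrete the same *amount* of protein
with very different spatial behaviour — isotropically, in a directed plume,
in a sector, or as a travelling spot. `s2map` quantifies those behaviours so
that cells can be compared and clustered into *secretio-types*: phenotype
classes defined by the spatiotemporal pattern of their secretion signal.

The package is aimed at imaging groups who already have per-frame intensity
matrices and want position-aware summary statistics, robustness-tested
simulators, and a reproducible pipeline from raw stacked matrices to metric
tables, correlations, dendrograms and rendered maps.

## The statistics

For a 1D profile `x(1..n)` (an axis projection of a map), the **degree of
inequality** is an *unsorted* Lorenz-curve statistic,

    DI = (1/n) * sum_k 2 * ( sum_{i<=k} x_i / sum_i x_i  -  k/n ),

in [−1, 1]: 0 for uniform or symmetric profiles, positive when mass sits at
low pixel indices, negative at high indices. Unlike the Gini coefficient the
profile is not sorted, so DI keeps *where* the signal is. Its pixelwise
derivative `dDI(k) = x_k / sum(x) − 1/n` splits pixels into signal units
(`dDI > 0`) and noise units, giving `SNR = C_signal / C_noise`, and the
**center-weighted SNR**

    CWSNR = SNR * sum_i V(i) * W(i),

where `V` is the positive part of `dDI` and `W` is a semicircular weight
profile (1 at the axis center, 0 at both endpoints). For a 2D map the two
axis projections combine into the **signal inequality index** and the
**signal coverage index**:

    SII = sqrt(DIx^2 + DIy^2)        # dissymmetry
    SCI = sqrt(CWSNRx^2 + CWSNRy^2)  # central coverage of asymmetric signal

SII depends only on the intensity centroid of each projection, which makes it
invariant under rotations of the pattern about the grid center — the property
that separates a genuinely translated signal from a merely rotated one.

## Worked example

```r
library(s2map)

# a point signal translated 8 grid units right of center on a 51 x 51 grid
m <- simulate_2d("translation", t = 3)
map_metrics(m)
#> SII = 0.3529 (DIx = -0.3529, DIy = 0.0000); SCI = 0.0582 (CWSNRx = 0.0548, CWSNRy = 0.0196)

# the 1D metric swings with rotation; the 2D composite does not
sw <- rotation_sweep("translation", t = 3)
sw$summary
#>    metric         mean     variance
#> 1    di_x 2.145817e-17 6.794589e-02
#> 2 cwsnr_x 5.008137e-02 4.371617e-04
#> 3     sii 3.529412e-01 2.801353e-33
#> 4     sci 7.531283e-02 1.589752e-04
```

`DIx` alone averages to zero over rotations (it cannot tell a translated
signal from a centered one once the direction is unknown), while `SII`
stays at 0.3529 with variance ~1e−33. The ten reference 1D scenarios are
separated by the (DI, CWSNR) pair with accuracy 0.9 — nine distinct metric
pairs for ten scenarios; only the uniform spread and the endpoint
propagation coincide at (0, 0):

```r
metric_separation()$accuracy
#> [1] 0.9
```

A full time-series analysis, from a stacked plain-text matrix to a metric
table, is one call:

```r
s <- read_series("cell1.txt")          # x*n rows, n columns -> x frames
cfg <- pipeline_config(cutoff_mode = "fraction_of_peak", cutoff_value = 0.10)
analyze_series(s, cfg)                 # sample_id, time_min, sii, sci
```

and `compare_series()` / `cluster_series()` correlate and cluster samples by
their temporal metric vectors.

## Command line

The same operations are available from a shell via the installed `exec/s2map`
script:

```sh
s2map simulate --model translation --t 2 --out d2.txt
s2map metrics d2.txt
s2map analyze --input cell1.txt --mode delta --cutoff-fraction 0.1 --block 5 --window 1 --out cell1.csv
s2map compare cell1.csv cell2.csv --metric sii
s2map cluster *.csv --metric sci
s2map render --input d2.txt --out figs/d2
s2map benchmark --dims 400,800 --reps 3 --seed 0
```

Every command logs its effective parameters; `--config FILE` supplies
`key = value` defaults that flags override.

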
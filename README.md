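# mcpalm — motion-corrected PALM analysis of moving chromatin loci

Live-cell PALM of a chromatin locus (e.g. a dCas9-GFP-labelled telomere with
MCP-tethered photoactivatable dyes) faces two coupled problems: the locus
moves during the minutes-long acquisition, smearing its single-molecule
localizations along its trajectory, and the diffusion coefficients of bound
and slowly moving unbound molecules overlap so heavily that no mobility
threshold can tell them apart.

`mcpalm` implements the correlative conventional-fluorescence + PALM
analysis that solves both. The locus is tracked as a diffraction-limited
cluster in an interleaved conventional channel (one GFP frame, one
activation frame, eight PALM frames per 10-frame cycle at 20 Hz) and its
trajectory is linearly interpolated across the PALM frames. Single-molecule
traces are classified **bound** / **partially bound** / **unbound** by
instantaneous proximity: a localization co-localizes with a cluster when its
distance to the interpolated center is below *radius + σ_cluster +
σ_molecule*, and a trace is bound only if every localization stays inside
one cluster. The interpolated trajectory is then subtracted from the bound
localizations ("motion correction"), recovering the time-averaged
super-resolved locus, which is quantified by convex-hull area, maximal
extension, radius of gyration, covariance-ellipse axes and
duration-normalized localization density.

Mobility is quantified per trace by the time-averaged mean squared
displacement fitted to the 2D diffusion model

    <r²>(Δt) = 4 D Δt + 2 σ²

with Gaussian mixture models on log₁₀D (BIC-selected), kernel-density
overlap coefficients between distributions, and the mobility of bound
molecules relative to their host cluster (pooled bound-trace MSD fit divided
by the cluster's D). Localization precision uses the three-term Thompson
formula; channels are registered with a bead-calibrated third-order
bivariate polynomial.

A synthetic-experiment generator (`simulate_experiment()`) produces complete
correlative experiments with ground truth — moving clusters, binding sites,
confined bound-molecule motion, a fast/slow unbound mixture, constant-rate
photoactivation, geometric bleaching, Thompson-consistent photometry, a
seeded cubic channel distortion and bead calibration fields — so every stage
of the pipeline is validated against known truth.

## Worked example

```r
library(mcpalm)

ex  <- simulate_experiment(simulation_config(seed = 42))
res <- analyze_tables(ex$sm_locs, ex$cluster_locs, ex$bead_pairs,
                      experiment_config(seed = 42))
print(res)
#> correlative PALM analysis results
#>   sm_localizations       22079
#>   cluster_localizations  2000
#>   traces                 2087
#>   cluster_tracks         10
#>   bound                  596
#>   partially_bound        61
#>   unbound                1430
#>   clusters_with_metrics  10

head(res$metrics[, c("cluster_id", "n_localizations", "area_um2",
                     "rg_nm", "extension_nm", "density_per_um2_s")], 4)
#>   cluster_id n_localizations  area_um2    rg_nm extension_nm density_per_um2_s
#> 1          1             331 0.2149236 143.3947     586.6175          15.47822
#> 2          2             598 0.3022909 163.8496     727.5009          19.88167
#> 3          3             697 0.2582675 169.9752     656.9754          27.12314
#> 4          4             681 0.3975695 186.0168     782.2399          17.21516
```

Each row is one motion-corrected locus: its hull area (µm²), radius of
gyration and maximal extension (nm), and localizations per µm² per second of
observation. The unbound traces show the expected two mobility states:

```r
fit_logd_mixture(res$trace_d$D[res$trace_d$class == "unbound"])
#> Gaussian mixture on log10 D: 2 component(s)
#>   pi=0.441  mean=-1.744 (D=0.01802 um^2/s)  sd=0.629
#>   pi=0.559  mean=-0.642 (D=0.2283 um^2/s)  sd=0.263
#>   ( 140 non-positive D excluded )
```

Because the generator provides ground truth, the classification can be
scored, including against the best possible single mobility threshold:

```r
ground_truth_compare(res$traces, res$classes, res$corrected, res$trace_d, ex)
#> correlative classification accuracy: 98.4%
#> best single-D-threshold accuracy:   71.4% (threshold 0.02113 um^2/s)
#>          predicted
#> truth     bound partially_bound unbound
#>   bound     589              25       2
#>   unbound     7              36    1428
```

The correlative classification recovers bound molecules with ~98% accuracy
where the best mobility threshold tops out near 71% — the overlap between
bound and slow-unbound mobilities makes thresholding hopeless, which is the
point of the correlative approach.

File-based runs (`run_pipeline()`, or `inst/scripts/mcpalm.R` from a shell)
write per-stage CSVs, a serialized transform, displacement tables for
external mobility tools, and a manifest with config hash, seed, input digests
and per-stage counts.

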
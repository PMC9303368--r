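---
title: "Motion-corrected PALM of moving chromatin loci: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected PALM of moving chromatin loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpalm)
```

## The problem

PALM accumulates single-molecule localizations over thousands of frames. In a
living cell a chromatin locus — for example a telomere labelled with
dCas9-GFP and MCP-tethered photoactivatable dyes — moves during that time, so
the localizations of molecules bound to it smear out along its trajectory.
Neither the time-averaged nanoscale structure of the locus nor the identity
of the bound molecules can be recovered from the PALM channel alone: the
diffusion-coefficient distributions of bound molecules and of slowly moving
unbound molecules overlap heavily, so no mobility threshold separates them.

`mcpalm` implements the correlative analysis that solves both problems at
once. The locus is tracked as a diffraction-limited cluster in an interleaved
conventional-fluorescence channel while single molecules are localized in the
PALM channel. Single-molecule traces are classified bound / partially bound /
unbound by their instantaneous proximity to the moving cluster, and the
interpolated cluster trajectory is subtracted from the bound localizations,
yielding a motion-corrected, time-averaged super-resolved image of the locus.

## Acquisition model

A repeating shutter cycle (default 10 frames at 20 Hz) interleaves the
channels: slot 1 is the conventional (GFP) frame, slot 2 the
photoactivation/brightfield frame, slots 3–10 are PALM excitation frames.
`frame_role()` maps absolute frame indices onto this cycle; linking operates
on per-channel frame grids, so two PALM frames separated by the
conventional/activation slots still count as consecutive (they are not dark
frames — the molecule was simply not imaged).

Localization tables carry `x`, `y` (canonically µm), `frame` (1-based),
`photons`, `width` (nm) and `background` (photons/pixel). Localization
precision is computed from the photometry with the full three-term Thompson
expression

$$\sigma^2 = \frac{s^2}{N} + \frac{a^2}{12N} + \frac{8\pi s^4 b^2}{a^2 N^2},$$

with $s$ the fitted PSF width, $N$ the photon count, $a$ the pixel size and
$b$ the background noise. The camera pixel size is not a property of the
tables, so it is a configuration parameter (default 160 nm/pixel, a common
EMCCD geometry at 100×).

## Pipeline stages and their parameters

1. **Registration.** The PALM channel is mapped onto the conventional channel
   with a full bivariate polynomial of total degree 3 (10 monomials per
   output axis), fitted by linear least squares to bead pairs from several
   calibration fields. The registration precision is estimated on held-out
   beads by leave-one-field-out; both the RMS and the mean mapping error are
   reported since either convention is in use.
2. **Single-molecule linking** (`link_single_molecules`). Localizations
   within 0.48 µm in consecutive PALM frames are chained; no dark frame is
   allowed; traces need at least 4 localizations. When several candidates
   fall inside the link radius, matching is nearest-neighbour, resolved
   globally per frame pair in ascending distance with ties broken by row
   order — activation densities are kept low precisely so that such
   conflicts are rare.
3. **Cluster linking** (`link_clusters`). Conventional-frame localizations
   within 0.68 µm in consecutive conventional frames are chained, with the
   additional width-continuity rule |Δwidth| ≤ 200 nm (a large width jump
   signals axial movement out of focus); tracks need at least 5
   localizations. The fitted Gaussian width of the conventional localization
   doubles as the cluster radius.
4. **Interpolation** (`interpolate_tracks`). Cluster centers are linearly
   interpolated between conventional frames so a center exists at every PALM
   frame the track spans; the radius and precision are carried
   piecewise-constant from the last conventional localization.
   `interpolation_error_experiment()` quantifies the cost of this
   approximation from continuously imaged tracks: positions are subsampled
   every cycle, re-interpolated and compared with the observed intermediate
   positions. For a stationary cluster with per-axis noise $\sigma$ the
   median deviation follows the Rayleigh median
   $\sqrt{2\ln 2}\,\sigma\sqrt{1 + w^2 + (1-w)^2}$ at relative gap position
   $w$; for Brownian motion the bridge variance $2D\,T\,w(1-w)$ per axis adds
   in quadrature. Both closed forms are verified in the test suite.
5. **Co-localization** (`colocalize`). A localization at frame $f$
   co-localizes with a cluster when its distance to the interpolated center
   is below radius + σ(cluster) + σ(molecule); it is assigned to the nearest
   such cluster, distance ties to the lower cluster id.
6. **Classification** (`classify_traces`). A trace is *bound* when every
   localization lies inside one cluster, *unbound* when none does, and
   *partially bound* otherwise — a molecule that enters and exits a locus
   within a trace is interpreted as searching or freely diffusing, because
   documented dCas9/MCP residence times (minutes to hours) make true
   binding/unbinding within a few-hundred-millisecond trace implausible. The
   4-localization cutoff balances mobility accuracy against falsely calling
   scanning molecules bound. Two edge rules are needed where the source
   procedure is silent: a trace overlapping the start/end of its host
   cluster's observation window is judged only on frames where the center is
   defined and is excluded from the bound class (flagged `window_limited`)
   when fewer than 4 such frames exist; a trace touching two different
   clusters is classified partially bound and flagged `multi_cluster` rather
   than silently assigned.
7. **Motion correction** (`motion_correct`). The interpolated host center is
   subtracted per frame from every bound localization. The corrected
   coordinates are expressed relative to the cluster center (the subtraction
   leaves the origin arbitrary; the center is the natural choice).
   Within-frame relative geometry is untouched by construction.
8. **Structure** (`cluster_metrics`). Convex-hull area, maximal extension
   (exact, computed over hull vertices), radius of gyration and
   covariance-ellipse axes use standard second-moment definitions — the
   quantities are conventional even where the source names them without
   formulas. Because photoactivation is held constant, localization counts
   scale with observation time, so counts are normalized by the cluster's
   observed duration; both the duration-normalized count and the count per
   area per time are exported, since "localization density" is used with
   either meaning.
9. **Mobility** (`tamsd`, `fit_diffusion`, `fit_logd_mixture`,
   `distribution_overlap`, `relative_mobility`). Per-trace TAMSD curves are
   fitted to $\langle r^2\rangle = 4D\,\Delta t + 2\sigma^2$ by ordinary
   least squares. Cluster fits use the conventional-frame spacing
   (cycle/frame-rate) as $\Delta t$. Relative bound-molecule mobility pools
   the TAMSD curves of all bound traces of a cluster (count-weighted, i.e.
   averaging displacements, not fitted coefficients), fits once, and divides
   by the cluster's own D.

## Numerical choices

* **Lag cap.** By default only the first 3 TAMSD lags enter the linear fit
  (`max_fit_lags` in `experiment_config()`). With photobleaching-limited
  traces (minimum 4, mean ~7 localizations) the highest lags average one or
  two strongly correlated displacements; including them drags the median
  fitted D far below truth, while the initial linear portion recovers the
  median within the accuracy the validation suite requires. Fitting only the
  first few MSD points is the standard remedy in the single-particle-tracking
  literature.
* **Negative fits.** A negative fitted slope yields D ≤ 0, which is kept and
  flagged so that distribution tails are not censored, but such values are
  excluded (with a count) from the log-D mixture, which requires positive D.
  A negative intercept likewise gives `sigma_um = NA` with the raw intercept
  reported.
* **Noise intercept convention.** The model is fitted exactly as written,
  $4D\Delta t + 2\sigma^2$. With independent per-axis localization noise $s$
  the true intercept is $4s^2$, so the fitted σ estimates $s\sqrt 2$; the
  slope, and hence D, is unaffected.
* **Mixture fitting.** Gaussian mixtures on log₁₀D use `mclust`
  (unequal-variance univariate models) with BIC selection over K ∈ {1,2,3};
  mclust's model-based hierarchical initialization makes the fit
  deterministic.
* **Overlap coefficient.** Distribution overlap is
  $\int \min(\hat p_a, \hat p_b)$ of Gaussian kernel density estimates on a
  shared grid with Silverman bandwidths, on the log₁₀D scale for diffusion
  coefficients. The estimator is stated because overlap percentages are
  meaningless without one.
* **Degenerate inputs.** Collinear point sets have no hull area or covariance
  ellipse (errors, not NaNs); traces of one localization cannot be fitted;
  underdetermined or rank-deficient bead layouts are rejected at fit time.

## The synthetic-experiment generator

`simulate_experiment()` produces complete experiments with ground truth:
clusters move as 2D Brownian motion with per-cluster D drawn log-normally
(median 0.002 µm²/s, ~1 dex spread — telomere-like), with an optional
directed-transport mode mirroring the actively transported loci seen in live
cells; cluster widths follow the observed 376 ± 221 nm law (truncated at
250 nm, the fitting software's lower width bound). Bound molecules sit at
Gaussian-distributed binding sites (σ = 100 nm) and wiggle with confined
(Ornstein–Uhlenbeck) local motion (stationary sd 55 nm, relaxation 0.5 s,
apparent local D ≈ 0.006 µm²/s, so the bound peak lands near 0.008 µm²/s once
cluster motion is included). Unbound molecules diffuse freely as a fast/slow
mixture (0.21 and 0.008 µm²/s, slow weight 0.3 — the slow fraction is a free
mixture weight, its physical origin being unresolved). Photoactivation is a
constant-rate Poisson process (2 molecules per PALM frame over a 20 × 20 µm
field); bleaching is geometric with per-PALM-frame survival 0.85 (mean trace
~6.7 frames). Photometry is drawn so that Thompson precisions are ~20 nm for
single molecules and ~30 nm for a nominal 376 nm cluster; the emitted
single-molecule table is warped by a seeded cubic polynomial distortion
(~1 pixel RMS) that the bead fields (5 fields × 12 beads, 5 nm noise) let the
analysis undo. Default acquisitions are 2000 frames; all statistical
structure is per-frame, so longer runs only add statistics.

What the generator does **not** emulate: camera physics (EMCCD gain, read
noise, pixelation), fluorophore dark states and blinking beyond
activation/bleach, anomalous (non-Brownian) diffusion, axial (z) structure
and defocus, and spatially varying background. Passing tests therefore
demonstrate the correctness and internal consistency of the analysis under
its own model assumptions — not that real chromatin obeys those assumptions.

`ground_truth_compare()` scores any analysis run: classification confusion
matrix and accuracy, the best accuracy achievable by any single
diffusion-coefficient threshold (full sweep — the baseline the correlative
classification must beat), D recovery per class, and radius-of-gyration
recovery before and after motion correction.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` rerun the validation experiments at
desk scale: 100 continuously imaged tracks of 200 s at 20 Hz for the
interpolation-error estimate; 5 bead fields × 12 beads for registration;
700-trace ensembles per diffusion coefficient for recovery; a 2000-frame,
10-cluster default experiment for classification; and an 8-cluster
directed-transport experiment (uniform 376 nm width, 150 nm site spread, ~3
µm displacement per cluster) for motion-correction recovery. The
motion-correction experiment pins the cluster width at its nominal value so
the anchor precision stays at ~30 nm: wider clusters have intrinsically worse
Thompson precision, which inflates the corrected radius of gyration — a real
property of the method discussed below, not something subtraction can remove.

## Known limitations

* The corrected image is convolved with localization noise *and* the
  interpolation error of the cluster trajectory; the latter (tens of nm per
  cycle for telomere-like mobility) dominates the structural resolution.
  Metrics of small loci are correspondingly biased upward.
* Clusters fitted with large widths have worse anchor precision (Thompson
  scales with $s^2$ and $s^4b^2$), so their corrected radii of gyration are
  inflated more.
* Slowly diffusing unbound molecules that happen to reside inside a cluster
  footprint for a whole trace are classified bound; with default conditions
  this residual contamination is at the percent level overall but
  concentrates in the largest clusters.
* Brownian motion is assumed throughout trajectory analysis; fitted D values
  for sub-diffusive chromatin are apparent coefficients, useful for relative
  comparison, not absolute transport parameters.
* Traces at most belong to one molecule by construction of the linker; merge
  and split events, gap closing and axial tracking are out of scope.
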
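---
title: "Methods: the flytube synthetic assay and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the flytube synthetic assay and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(flytube)
```

flytube quantifies two-choice olfactory avoidance in tube assays: flies are
placed in a horizontal tube with an odorant source at one end and a solvent
control at the other, the tube is imaged at a fixed frame rate, and the
population's preference is summarized per frame by a normalized
center-of-mass (CoM) statistic. This vignette documents the statistical
model behind the synthetic assay generator, the definitions used by the
tracking statistics, and the numerical choices made throughout — including
the places where a published convention is ambiguous and a decision had to
be made.

## The center-of-mass and avoidance-index statistics

A tracked frame reduces to a pixel mask: for each of the `W` columns of the
tube span, the number of above-threshold pixels. With 0-based column
offsets `x` measured **from the odorant end**, and `M` flagged pixels in
total,

$$\mathrm{CoM} = \frac{\sum_n x_n}{M \,(W - 1)} \in [0, 1].$$

The normalization by `W - 1` (not `W`) is deliberate: it is the only choice
under which the three documented anchors are attained exactly — all pixels
in the farthest column give 1.0, all in the odorant-end column give 0.0,
and a homogeneous occupancy gives 0.5. A denominator of `W` misses all
three by O(1/W).

```{r anchors}
compute_com(mask_from_counts(c(0, 0, 0, 9)))  # far column
compute_com(mask_from_counts(rep(3, 101)))    # homogeneous
```

The avoidance index is the half-count difference
$(\text{odorant-half} - \text{solvent-half}) / M$. Implemented literally,
avoidance (flies away from the odorant) is **negative**; `compute_ai()`
keeps the literal formula and offers `flip_sign = TRUE` for reporting
avoidance as positive. For odd `W` the midline column belongs to neither
half but stays in the denominator, so a fly sitting exactly on the midline
dilutes the index rather than being assigned a side.

## The synthetic assay generator

Real recordings of this assay cannot ship with a package, so flytube
includes a generative model with the statistical structure the analysis
assumes. Each fly follows a biased random walk along the tube axis
(position in mm, tube length `L`):

$$x_{t+\Delta} = x_t + \kappa\,(1 - e^{-t/\tau})\,\Delta
  + \sigma \sqrt{\Delta}\,\xi_t, \qquad \xi_t \sim \mathcal{N}(0,1),$$

with reflecting boundaries at 0 and `L`, plus a pairwise soft-core
repulsion: flies closer than `d_ex` push each other apart by
$0.5\,\eta\,(d_{ex} - d)$ each. Euler stepping at the frame cadence is
adequate because the per-step displacement (≈ 4 mm) is small relative to
both the tube and `d_ex`-scale structure.

Default parameters and their rationale:

| parameter | default | units | rationale |
|---|---|---|---|
| `drift_mm_s` (κ) | 0.25 | mm/s | with σ below, stationary density ∝ exp(2κx/σ²) has mean CoM ≈ 0.75, a strong but not saturating avoidance |
| `onset_tau_s` (τ) | 420 | s | single-exponential onset puts the trace within 6% of steady state by 20 min, matching the convention of averaging from 20 min onward |
| `diffusion_mm_sqrt_s` (σ) | 4 | mm/√s | sets the mixing time L²/σ² ≈ 23 min so the 60-min assay actually reaches steady state |
| `crowding_radius_mm` (d_ex) | 5 | mm | about two body lengths; produces the overcrowding depression of the mean response at 32–64 flies |
| `crowding_strength` | 0.5 | – | soft core: overlaps relax over a few frames rather than instantaneously |
| `drift_cv` | 0.2 | – | per-tube drift heterogeneity (unit-mean lognormal factor on κ); puts a floor under replicate variance so effect size plateaus with group size instead of growing without bound |
| `fps` | 1 | frames/s | capture cadence of the assay |

`drift_cv` deserves emphasis. With identical parameters in every replicate,
the variance of replicate means falls like 1/n and Cohen's d grows like √n
forever, which no real assay does. Real tubes differ (odor loading, animals,
temperature), and a 20% coefficient of variation on the drift reproduces the
observed behavior: variance decays with group size down to a
between-tube floor, and the effect size rises and then plateaus. That
plateau is what makes 8–16 flies per tube the practical optimum, and
`calibrate_group_size()` reproduces it:

```{r calibration, eval = FALSE}
cal <- calibrate_group_size(assay_sim_config(seed = 11), n_reps = 50)
autoplot(cal)
```

One global `seed` governs everything through documented substreams: the
per-tube drift factor is drawn first, then initial positions, then the walk
noise; rendering uses `seed + 1`. Two runs with the same config are
bit-identical.

### What the generator emulates — and what it does not

It emulates the lengthwise statistics of the population: onset kinetics,
steady-state spatial tilt, group-size dependence of replicate variance and
effect size, and overcrowding. It does **not** model odor plume physics,
olfactory transduction, light stimulation, fly orientation, grooming, or
wall-following; dynamics are strictly one-dimensional, and only the
lengthwise coordinate enters any statistic.

## Rendering, and why it is invertible

`render_frames()` rasterizes trajectories into 8-bit grayscale frames: each
fly is a filled disc of radius `fly_radius_px` at the pixel column its
position maps to, on a random transverse row, over additive Gaussian noise
clipped below the segmentation threshold margin. The camera resolution and
fly size in pixels are free parameters of the rendering, not of the assay.

Column-count tracking of a binary mask is only faithful if every fly
contributes the same pixel weight in every frame. Two design rules enforce
that:

* the mapped column is clamped so the whole disc stays inside the tube
  span — a truncated disc would lose pixels and drag the frame CoM toward
  its neighbors; the clamp costs at most `fly_radius_px` of positional
  error at the extreme ends;
* flies whose columns come within one disc diameter are drawn on transverse
  rows separated by more than a diameter, so discs never occlude. If more
  flies crowd one lengthwise neighborhood than `height_px` can separate,
  rendering fails loudly instead of silently under-counting.

Together these bound the render-then-track error of the frame CoM by
`fly_radius_px / (W - 1)` against the point-mass CoM of the true positions,
which is the package's verified roundtrip guarantee.

## Steady-state windows and downsampling

Frames are captured at 1/s but analyzed at one frame per 10 s
(`downsample_series()`, which keeps every k-th sample rather than
averaging). Steady-state averages use per-odor windows shipped in
`inst/extdata/odor_windows.yaml` (e.g., benzaldehyde 20–60 min, propionic
acid 5–25 min); endpoints are **inclusive** on both sides, missing samples
are dropped rather than imputed, and `window_average()` reports how many
samples it used.

## Group-size calibration

`calibrate_group_size()` sweeps flies-per-tube over paired arms — an
odorant arm with the configured drift and a control arm with κ = 0 — and
reports, per group size: the variance of replicate-mean CoM (unbiased,
n−1), Cohen's d against control (pooled (n−1)-weighted SD), and both arm
means. It computes CoM directly from trajectories (point-mass per frame)
rather than rendering hundreds of thousands of frames; the render→track
path is validated separately by the roundtrip bound above. Replicate seeds
are derived deterministically from the base seed, group size, replicate,
and arm, so sweeps are reproducible and arms are independent.

## Statistics

Two-group comparisons use the Mann–Whitney test and paired recordings the
Wilcoxon signed-rank test, both delegated to `stats::wilcox.test`: exact
small-sample branches when there are no ties (and n permits), tie-corrected
normal approximation with continuity correction otherwise. Multi-group
workflows use `stats::kruskal.test` followed by Dunn's z-tests with midrank
tie correction and Bonferroni adjustment (`kruskal_dunn()`); Dunn's test is
implemented here because no installed package provides it. The test suite
validates all branches against independent full-enumeration oracles and
Monte-Carlo type-I calibration. One caveat found while testing: at the
exact/approximate branch boundary (8 vs 8) the two branches can disagree by
up to 0.0109 in the mid-tail — a property of the discrete null
distribution, not of the implementation; in the decision-relevant tail
(p ≤ 0.10) they agree to better than 0.005.

## Evoked responses

`quantify_peak()` implements the peak-minus-baseline rule shared by the
electrophysiology and imaging modalities: baseline is the mean over the
`baseline_s` seconds **before** stimulus onset; the response is the largest
deflection from baseline within the modality's response window (EAG 10 s,
DCFDA 120 s, patch 30 s by default). EAG and patch deflect downward and are
reported as positive magnitudes; EAG amplitudes below 0.05 mV are excluded
with a machine-readable reason rather than dropped silently.
`percent_of_control()` is 100·test/control and refuses excluded controls.
`dcfda_response()` adds the fluorescence conventions: 30 s baseline, peak
of a 3-sample moving average over the 120 s post-stimulus record (a
steady-state peak robust to single-sample spikes), reported as ΔF and
ΔF/F₀. ΔF is offset-invariant; ΔF/F₀ deliberately is not.

## Limitations

* The generator's parameters were chosen to reproduce qualitative assay
  phenomenology; its numerical outputs are not calibrated to any specific
  odorant or genotype.
* Tracking assumes a clean two-level segmentation; it has no blob
  detection, so it counts pixels, not flies — occlusion in real video
  would bias weights in a way the synthetic renderer deliberately avoids.
* One-dimensional dynamics cannot express transverse behavior (e.g.,
  wall-following), and the rendering's row placement is cosmetic.
* The exact statistical branches require untied data; heavily tied data
  silently uses the normal approximation, as in `stats::wilcox.test`.
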
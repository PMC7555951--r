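---
title: "Quantifying DNA damage focus dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA damage focus dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociTrack)
```

## The problem

After ionizing radiation, DNA double-strand breaks recruit repair proteins
such as 53BP1 into micrometre-scale nuclear foci. Live-cell imaging of
GFP-tagged 53BP1 turns DSB repair into a quantitative, time-resolved
measurement: how many foci a nucleus carries over time, how long each focus
persists, how bright and large it is, and how it moves. fociTrack implements
that measurement chain — adaptive focus segmentation, center-of-mass
tracking, mean-squared-displacement (MSD) analysis, distribution summaries,
and a fixed-cell two-channel colocalization counter for resection markers
(RPA) nested inside repair foci — together with a synthetic image generator
that provides ground truth for every stage.

## Adaptive focus segmentation

Focus segmentation must survive photobleaching and slow global intensity
changes over a many-hour acquisition, so a single fixed threshold fails.
fociTrack instead calibrates a threshold *factor* once per cell and lets the
absolute threshold float with the frame statistics:

* On the first frame, the analyst (or a configuration value standing in for
  the visual choice) supplies a manual lower threshold $L$. With the
  nucleus-masked mean $\mu_0$ and standard deviation $\sigma_0$ of that
  frame, the factor is
  $$f = \frac{L - \mu_0}{\sigma_0}.$$
* Every frame $t$ is then thresholded at
  $$T_t = \mu_t + f\,\sigma_t,$$
  with a fixed upper bound of 255 (8-bit convention; deeper inputs are
  rescaled on read). Applying the model to the calibration frame reproduces
  $L$ exactly, and the whole construction is invariant under affine
  intensity rescaling $x \mapsto \alpha x + \beta$ of frame plus manual
  threshold — both properties are enforced by tests.

Statistics use the sample ($n-1$) standard deviation; a population option
exists. The Gaussian blur ($\sigma = 1$ px) belongs to threshold *selection*
on the first frame; later frames are segmented unblurred — the calibration
convention takes the manual threshold as chosen on the smoothed first
frame, and nothing in the procedure requires blurring the frames being
measured. Touching foci are split by a distance-transform watershed, and
blobs under 4 px (configurable, 0 in exact-oracle tests) are discarded as
single-pixel noise. Focus measurements are pixel count $\times$ pixel
area, mean member-pixel intensity, their product (total signal per focus),
and the intensity-weighted center of mass (geometric centroid available);
coordinates are 0-based at the top-left pixel center and reported in µm.
Mean intensities are not background-subtracted.

Nucleus segmentation is a global Otsu threshold with hole filling, a
200-px area floor and border exclusion (both configurable) — standard
practice rather than anything specific to this pipeline. Rigid-body
stabilization (translation via FFT cross-correlation, rotation by a 1°
grid search refined by golden-section optimization about the nucleus
centroid) removes whole-nucleus motion before focus motion is measured;
known transforms are recovered to sub-pixel/0.5° accuracy in tests.

## Tracking

Foci are linked between consecutive frames when the Euclidean distance
between their centers of mass is **below 0.7 µm** (strict inequality;
an inclusive option exists). When several candidates compete, assignment is
greedy by ascending distance with ties broken by ascending label, so the
linker is deterministic; a focus with two or more candidates in the next
frame records a *split* event, two or more foci sharing one candidate
record a *merge*. Tracks are maximal chains of such links: gap-free by
construction, free to start or end at any frame. The continuing track
follows the nearest partner; other branches open (splits) or close
(merges) separate tracks annotated with their parent — the events are
well-defined, the bookkeeping convention is ours. Track duration is
$$\text{duration} = (n_\text{foci} - 1)\times \Delta t,$$
so a focus present in all 51 frames of a 20-min-interval acquisition has
lived 1000 min, and a single-frame focus has duration 0. Durations are
binned into 20–80, 100–160, 180–240, 260–320 and 340–400 min groups plus
an overflow group, with single-frame tracks counted separately. Per-frame
focus counts are reported independently of tracking (the raw segmentation
count is the default, as the more robust of the two), and a least-squares
$R^2$ utility supports manual-versus-script count validation.

## Mobility analysis

Each track's MSD is the time-averaged estimator over all ordered in-track
pairs (overlapping windows; a non-overlapping option exists). Ensemble
curves average per-track MSDs per lag without weighting by track length,
report the SEM across tracks, and are truncated at the lag still supported
by ≥ 3 tracks. For free 2-D diffusion $\mathrm{MSD}(t) = 4Dt$; the
apparent diffusion coefficient comes from an unweighted least-squares line
through the origin on the **first four nonzero lags** (lag 0 is trivially
zero), with $D = a/4$. Confined motion bends the MSD toward a plateau, so
curves are classified by comparing the through-origin line against a
single-exponential plateau $c\,(1-e^{-t/\tau})$, with residuals weighted
by the inverse squared per-lag SEM so that the poorly estimated long-lag
tail of a time-averaged MSD (few independent pairs, high variance, a
known downward bias) cannot impersonate a plateau; the saturating model
must reduce the weighted residual norm below 0.6 of the linear fit's to
win, which keeps the extra parameter from beating a straight line on
noise. The plateau time constant $\tau$ is additionally capped at the
largest observed lag: as $\tau \to \infty$ the plateau model degenerates
into a straight line, so a "plateau" that would only appear beyond the
data window is not evidence of confinement. The exponential
plateau is our choice of saturating family; only the qualitative curvature
distinction is inherent to the analysis.

## Distribution summaries

Population distributions of per-focus intensity, area and total signal use
a Gaussian-kernel density estimate whose bandwidth is the kernel SD in
data units — conventionally 6, 0.3 and 220 for the three quantities on the
8-bit/µm² scales. Each curve is rescaled so its area equals the area of the
source histogram (enforced to 1% by tests); a normalization factor fixed at
the first time point scales the highest histogram peak to 1 and is reused
at later time points, and two conditions are compared after scaling their
histogram areas equal. The evaluation grid adapts to the bandwidth
(at least 8 points per kernel SD) so small bandwidths on wide ranges are
not undersampled.

## Colocalization

Fixed-cell two-channel analysis selects S-phase nuclei by an Otsu threshold
over per-nucleus mean EdU intensities (an absolute fallback cutoff handles
a single nucleus or degenerate means), segments channel-A (53BP1-like) and
channel-B (RPA-like) foci per nucleus with per-nucleus Otsu thresholds and
watershed, measures B intensity inside each A mask without background
subtraction, and assigns each B focus to the A focus containing its center
of mass (COM containment; an area-overlap ≥ 50% rule is available).
Per-A-focus counts are reduced to the categories 0 / 1 / >1 and reported as
fractions of all A foci, which sum to 1 by construction.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
the physics of irradiation. A time-lapse run renders point-spread-blurred
foci (isotropic 2-D Gaussians, σ = 1.5 px by default) inside an elliptical
nucleus of strictly positive background, with:

* Brownian motion with per-axis step variance $2D\,\Delta t$, optionally
  reflected at a confinement disc anchored at each focus' birth position;
* Poisson births and Bernoulli deaths per frame — the simplest process
  giving a mixture of short- and long-lived tracks;
* per-focus amplitude growth and a global exponential bleaching factor;
* rigid whole-nucleus drift and rotation that carries the foci along;
* Poisson shot noise plus additive Gaussian read noise, each configurable
  to zero for exact tests.

Defaults mirror a 20-min-interval confocal acquisition of 51 frames at
0.1 µm/px, background 40 and focus amplitude 120 on the 8-bit scale, and
Gaussian read noise of SD 2 (the acquisition hardware's noise and PSF are
not characterized anywhere we could draw on, so these are chosen for
realism and testability, not fidelity to a specific instrument).
Rendering happens directly in the projected 2-D plane because the analysis
operates on maximum-intensity projections. Identical configuration and
seed give bit-identical stacks and ground truth.

A `min_initial_spacing` option enforces a minimum pairwise focus distance
at placement. Linker-fidelity experiments use it to realize the low-density
regime in which frame-to-frame linking is well-posed: 6 confined foci
(D = 0.001 µm²/min, confinement radius 0.5 µm) spaced ≥ 1.8 µm, i.e. more
than 3 × the expected rms step $\sqrt{4D\Delta t} \approx 0.28$ µm, and
comfortably more than the 0.7 µm linking distance. Under these conditions
the probability that a true step exceeds the linking cutoff is
$e^{-0.7^2/(4D\Delta t)} \approx 0.2\%$, so near-complete link recovery is
the correct expectation; at diffusion coefficients whose rms step
approaches 0.7 µm, track fragmentation is a property of the
distance-threshold linker itself, not an implementation artifact.

The fixed-cell generator lays nuclei on a grid, draws the number of
B foci nested in each A focus from a user distribution, and renders
siblings on a ring inside the parent footprint (evenly spaced angles) so
that they remain resolvable at the rendering resolution — real resection
clusters are not so polite, which is exactly why the paper-scale analysis
of such structures needs super-resolution; the generator tests the
counting machinery, not the optics.

What passing on synthetic data does **not** show: robustness to real
heterogeneous chromatin background, to nucleoli and other dark
structures, to focus shapes far from Gaussian, to z-drift surviving the
projection, or to segmentation at signal-to-noise ratios below the
defaults. Those require real acquisitions.

## Numerical choices and degenerate inputs

* Thresholding uses `>=` on the lower bound, `<=` on the upper.
* Calibration with zero frame SD is rejected with the frame named.
* Empty frames, blank stacks, and empty masks return empty tables or zero
  labels rather than erroring, except where a statistic is undefined
  (fewer than 2 masked pixels).
* Frames with zero foci yield missing values (not zeros) in the intensity
  time series.
* Registration of constant frames warns and passes them through.
* Tie-breaks everywhere (greedy linking, watershed labels) are
  deterministic, and all randomness flows from a single seed, so every
  pipeline output is byte-reproducible.

## Problem sizes

The validation suite runs at deliberately modest scale: Monte-Carlo oracles
with 400–10 000 tracks of 2–30 steps, single-nucleus stacks of 128 × 128 px
over 8–25 frames, and a 100-nucleus fixed-cell field with 1000 A foci.
These sizes give Monte-Carlo errors comfortably inside the asserted
tolerances (e.g. <3% on a 10 000-sample mean step, ±5 points on multinomial
fractions at n = 1000) while keeping the whole suite fast.

## Known limitations

* No gap closing, motion-model prediction, or globally optimal assignment:
  the linker is deliberately the distance-threshold, gap-free design whose
  behavior the duration statistics assume.
* No 3-D segmentation, deconvolution, or anomalous-diffusion exponents.
* Merged foci at high density segment as one object until watershed can
  separate them; the per-frame count is then an undercount relative to
  truth, which is why low-density conditions are used for fidelity
  statements.
* The saturating-model threshold (0.6 residual ratio) is a pragmatic
  classification boundary, not an inference procedure.
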
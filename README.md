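# fociTrack

Quantification of DNA double-strand-break (DSB) repair foci in live-cell
time-lapse and fixed-cell fluorescence microscopy.

After ionizing radiation, repair proteins such as 53BP1 accumulate at
DSB-flanking chromatin into micrometre-scale nuclear foci. Imaging
GFP-tagged 53BP1 every 20 minutes over many hours turns DSB processing into
a quantitative measurement: how many foci a nucleus carries over time, how
long each focus lives, how bright and large it gets, and how it moves.
fociTrack implements that measurement chain for researchers analyzing such
acquisitions, and ships a seeded synthetic image generator with full ground
truth so every stage can be validated without real data.

## What it computes

**Adaptive segmentation.** A manual lower threshold `L` chosen on the first
frame is converted into a per-cell factor using the nucleus-masked mean and
SD of that frame,

    factor = (L − mean₀) / sd₀,

and every frame `t` is then thresholded at `mean_t + factor × sd_t` (upper
bound 255), so the threshold tracks bleaching. Touching foci are split by
distance-transform watershed; per focus the area (µm²), mean intensity,
total intensity and intensity-weighted center of mass (COM) are measured.

**Tracking.** Foci in consecutive frames are linked when their COM distance
is below 0.7 µm (greedy nearest-first, deterministic tie-breaks, split and
merge events recorded). Tracks are gap-free chains with

    duration = (number of linked foci − 1) × frame interval,

so a focus present in all 51 frames of a 20-min acquisition lived
1000 min. Tracks are binned into 20–80, 100–160, 180–240, 260–320,
340–400 min duration groups plus overflow.

**Mobility.** Per-track time-averaged mean squared displacement, ensemble
MSD per duration group, and the apparent diffusion coefficient from a
through-origin fit `MSD = a·t` on the first four lags with `D = a/4`
(free 2-D diffusion: `MSD = 4Dt`). Curves are classified as linear (free
diffusion) or saturating (confined motion).

**Distributions.** Gaussian-kernel density estimates of per-focus
intensity, area and total signal (bandwidths 6 / 0.3 / 220), each anchored
to its source histogram's area, with a peak normalization fixed at the
first time point.

**Colocalization.** For fixed two-channel images (e.g. 53BP1 + RPA + EdU):
EdU-positive nuclei are auto-selected, foci are segmented per nucleus in
both channels, B-channel intensity is measured inside A-focus masks, and
each A focus is scored by the number of B foci whose COM it contains,
reported as 0 / 1 / >1 category fractions.

## Worked example

Simulate a low-density nucleus with six confined foci and analyze it:

```r
library(fociTrack)

cfg <- sim_config(n_frames = 25, n_initial_foci = 6,
                  diffusion_coefficient = 0.001,   # µm²/min
                  confinement_radius = 0.5,        # µm
                  min_initial_spacing = 1.8, noise_gaussian_sd = 1,
                  seed = 1)
sim <- simulate_timelapse(cfg)

res <- run_pipeline(run_config(output_dir = "out", threshold_factor = 3),
                    stack = sim$stack)

head(res$foci, 3)
#>   frame label com_x_um com_y_um area_um2 mean_intensity total_intensity
#> 1     0     1 2.805044 6.400217     0.21       103.1674        21.66516
#> 2     0     2 8.902352 4.695534     0.21       103.1135        21.65384
#> 3     0     3 4.917066 7.839916     0.19       105.4137        20.02860

head(as.data.frame(res$msd), 4)
#>   lag_min    msd_um2        sem n_tracks
#> 1      20 0.06920168 0.00599904        7
#> 2      40 0.12333554 0.01582468        7
#> 3      60 0.16524093 0.02140918        7
#> 4      80 0.18229746 0.02557015        7

res$diffusion[c("slope", "D")]
#> $slope
#> [1] 0.002567976
#> $D
#> [1] 0.0006419939
```

Six foci become seven tracks (one brief split). The MSD flattens toward a
plateau instead of growing as `4Dt` — these foci are confined in 0.5 µm
discs, so the apparent `D` from the early lags (0.00064 µm²/min) is far
below the free-motion input value, exactly the signature the MSD shape
classifier reads (`classify_msd_shape(res$msd)$shape` returns
`"saturating"`). The CSV tables and a JSON manifest land in `out/`.

A thin command-line front end over the same functions is available at
`inst/scripts/focitrack.R` (subcommands `simulate`, `run`, `coloc`).

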
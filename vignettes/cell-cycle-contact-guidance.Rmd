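---
title: "Quantifying cell-cycle-dependent contact guidance from FUCCI time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cycle-dependent contact guidance from FUCCI time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Migrating carcinoma cells respond to directional cues — confinement in
microchannels (contact guidance) and soluble growth-factor gradients
(chemotaxis) — and the question this package addresses computationally is
whether that directed migration depends on cell-cycle phase. The measurement
couples the FUCCI reporter system (a red nuclear signal, mKO2-hCdt1, marking
G1; a green signal, mAG-hGem, marking S/G2; transient co-expression — "yellow"
— marking the early-S handoff) with automated segmentation, tracking, and
per-track migration statistics on multi-channel time-lapse movies (three
channels, 10 min frame interval, up to 30 h).

`fuccitrack` reimplements that measurement chain end to end and, because no
raw movies are available, pairs it with a ground-truthed synthetic scene
generator so every stage can be validated quantitatively. The workflow under
`analysis/` strings the stages together; every computation lives in the
package and is unit-tested.

## The synthetic scene generator

The generator is first-class code, not a test fixture. It emulates:

* **Motility.** A discrete-time persistent random walk: per step the heading
  gains Gaussian noise with phase-dependent sd (`heading_noise_G1/SG2`,
  radians), and the step length is `speed_phase x frame_interval` with 10%
  multiplicative jitter. Channel modes confine cells to 10 um-wide horizontal
  channels (reflecting walls); `channel_chemotaxis` adds a restoring torque of
  strength `chemotaxis_bias` toward +x, the gradient direction. The persistent
  random walk is the minimal model producing the persistence/velocity
  phenomenology of interest; heading-noise sd is the single knob mapping to
  persistence.
* **The FUCCI clock.** Deterministic phases G1 (10 h) -> early-S overlap
  (2 h) -> S/G2 (10 h), restarted without division (mitosis is out of scope);
  asynchrony comes from uniform per-cell phase offsets. The empirically
  grounded constant is the ~2 h overlap; the 10 + 10 h flanks are a plausible
  choice for this cell line, not a measured value. Red decays and green rises
  linearly across the overlap, so both channels exceed half their maxima only
  inside it. One consequence worth knowing: with a linear crossfade the sum of
  the channels is constant, so "both above 50% of max" is a boundary case —
  population-level yellow calls therefore use detectability thresholds well
  below half-max.
* **Imaging.** Fluorescence channels are sums of isotropic Gaussian blobs
  (sd = `blob_radius`, default 4 um) scaled by the clock intensities, plus a
  slow-varying background (Gaussian-filtered white noise, filter sd = 25% of
  the image side, synthesized on a 64-pixel grid and bilinearly upsampled —
  the retained frequencies are far below the interpolation scale) plus
  white shot noise. The transmitted channel renders a darker body, a thin
  bright rim and, in channel modes, dark channel walls. Defaults: 0.65 um/px,
  512x512 (a 20x objective scale).

What the generator does **not** emulate: cell-cell exclusion (two cells can
occupy the same spot; in a real 10 um channel they cannot pass each other),
photobleaching, focus drift, mitotic rounding, shape dynamics. Passing tests
therefore demonstrate correctness of the measurement chain under the stated
noise model, not robustness to every artifact of real microscopy. Because
pass-through encounters corrupt any tracker's identities, the bundled
channel-scene conditions spread cells across many channels (32 um pitch,
<= 2 cells per channel, starts staggered over the left 40% of the field) —
the regime the physical device actually produces.

## Segmentation

Per frame and channel: a 3x3 median filter removes shot noise, and a Gaussian
low-pass estimate of the background (kernel 10% of the smaller image
dimension; sd = kernel/6 so the kernel spans +-3 sd) is subtracted and the
result clipped at zero. Otsu's threshold is then recomputed each frame
("adaptive" in the temporal sense) on the pixelwise max of the two
fluorescence channels, so cells remain detectable through the red-to-green
handoff; 8-connected components below 30 px (about half a nucleus at default
scale) are dropped. The transmitted channel contributes a second mask — pixels
more than one sd from the frame median (cells are darker bodies with bright
rims), unioned with an Otsu-thresholded Sobel gradient magnitude, holes
filled — and the final segmentation is the pixelwise intersection of the
fluorescence components with that mask, dropping components that lose more
than half their area. Mean red/green intensities are measured on the raw
channels so that background subtraction cannot distort classification
thresholds.

## Tracking

Detections are associated over a sliding three-frame window. The pair cost
adds three dimensionless terms (weights 1:1:1, configurable): centroid
distance over the radius sum, relative area difference, and intensity change
over the pair's larger total intensity. Pairs are gated to infinite cost when
separated by more than twice the larger equivalent radius (times an adaptive
scale) or differing in area by more than 90%. The spatial gate expands by
1.5x until at least five candidates are in reach or the pool is exhausted.
Links may skip one frame (occlusion), at a 1.25x cost penalty per skipped
frame; tracks unmatched for a full window close.

Within each window step the head-to-detection assignment is solved exactly as
a minimum-cost maximum-cardinality bipartite matching (Kuhn-Munkres via
igraph, with cardinality prioritized by a large-constant weight transform).
We initially committed edges greedily, but on small instances where exhaustive
enumeration of all feasible link sets is tractable the greedy rule missed the
enumerated optimum on about 2% of cases; the exact per-step matching agrees
with the enumeration on 1000 of 1000 random instances (up to 4 cells x 5
frames) and is the shipped rule. The enumeration oracle lives in the test
suite and stays independent of the tracker.

## Cell-cycle classification

Two modes, for two uses:

* **Longitudinal** (tracks followed through the transition): a frame is G1
  when its mean red exceeds 50% of the track's maximum red, else S/G2; frames
  where green additionally exceeds 50% of its track maximum are marked as the
  early-S overlap and excluded from phase statistics. The track maximum is
  retrospective (whole observed track). The switch frame is the first S/G2
  frame after a G1 run — under the linear crossfade this is the overlap ramp
  midpoint, and on high-SNR synthetic traces it lands within +-1 frame of the
  true midpoint in >= 95% of tracks. Note the mean-intensity readout averages
  ~130 segmented pixels, so trace noise is about sqrt(130)-fold smaller than
  per-pixel image noise.
* **Snapshot** (population statistics): red-only above threshold is G1,
  green-only S/G2, both "yellow" (excluded, with the count reported), neither
  unknown. Default thresholds are 50% of the per-movie 99th-percentile
  intensity; yellow detectability uses lower thresholds as discussed above.

## Migration statistics

Instantaneous velocity is displacement between consecutive observed frames
over elapsed time (gaps use true elapsed time). Persistence is net
displacement over total path length — the only reading that gives values in
(0, 1); a motionless track is undefined (NA with warning). Phase-segment
metrics use contiguous same-phase runs of at least 6 frames, bridging
single-frame gaps; per-cell G1:S/G2 ratios require both segments. Group
comparisons use the equal-variance two-tailed Student t-test (Welch behind a
flag), reported as mean +- SEM with the usual star thresholds, and no
multiple-testing correction — matching the source analysis conventions.
Population summaries default to per-track means; per-step pooling is a flag.
In channel experiments tracks are clipped to start at the taper entry
(x >= `taper_entry_x`), dropping tracks that never enter.

## Gradient model

Gradient formation along the microchannel is the 2D unsteady diffusion
equation dC/dt = D (Cxx + Cyy) on the 850 x 10 um rectangle: source edge fixed
at the reservoir concentration (justified by the ~10^6-fold reservoir-to-
channel volume ratio), sink edge leaking flux k*C (Robin condition; k is a
mass-transfer coefficient in um/s, default D/1000 um — a well-mixed large
reservoir), walls no-flux. D = 0.5e-4 cm2/s (5e3 um2/s). One source prints
this diffusivity with um2/s units in a second place; the cm2/s value is the
dimensionally sensible one and is used, with this note as the record.
Similarly, the printed equation carries a negative sign on the Laplacian,
which is anti-diffusive; the standard positive-sign heat equation is solved,
the only form consistent with a monotone equilibrating gradient.

The solver is explicit finite differences (dx = 5 um, dt = 50% of the
stability bound dx^2/(4D), enforced with an informative error), with the
stepping loop in compiled code. The solution obeys the maximum principle;
with all edges closed, trapezoid-weighted mass is conserved to float
rounding. Since L^2/D ~ 2.4 min, the system is effectively at steady state
long before 6 h, which is exactly why the 6-to-24 h steepness difference is
tiny. Steepness is the mean absolute central-difference slope of the
width-averaged profile (whether the original averaged |slope| or fitted one
line is unstated; both the mean-|slope| value and the profile itself are
available). Steady profiles are verified against the 1D closed form
C(x) = C0 (1 - x/(L + D/k)) and its k -> infinity linear limit. Profiles are
normalized as (I - I_min)/(I_max - I_min), which is affine-invariant; a
constant profile raises an error rather than dividing by zero.

## Fiber orientation

Collagen organization is summarized by per-pixel orientations from the
smoothed structure tensor (tensor smoothing sd 2 px; fiber direction is the
minor eigenvector), weighted by the eigenvalue difference and thresholded at
coherence 0.2. The image is pre-smoothed (sd 2 px) before differentiation:
finite-difference gradients on sub-pixel-wide lines are biased toward the
diagonals by several degrees otherwise, and with pre-smoothing the circular
mean is recovered within ~1 degree across orientations. Angles are axial
(mod 180), so all statistics double the angles first. The uniform-vs-aligned
verdict is the Rayleigh test (p >= 0.05 means uniform), with the circular
mean and sd of the axial distribution reported as a wrapped-normal fit. For
estimated angle sets the per-pixel samples are correlated along fibers, so
the test accepts an effective sample size (e.g. the fiber count); the raw
pixel count would overstate power enormously. This structure-tensor estimator
replaces a curvelet-based fiber extraction tool by design: the claims under
test concern angle distributions, not individual fiber geometry.

## Numerical and design notes

* Coordinates: x right, y down, origin at the top-left pixel center, 0-based
  pixel indices; lengths in um, times in minutes, angles in degrees at all
  interfaces (pixels only inside segmentation).
* Determinism: the generator consumes only `config$seed` (rendering uses
  seed + 1); the analysis pipeline itself is RNG-free, so identical inputs
  give byte-identical CSV outputs.
* Otsu on an empty (all-zero) frame returns an empty mask, not an error;
  a constant transmitted frame yields an empty phase mask.
* 16-bit TIFF I/O: intensities are written as rounded integers in [0, 65535]
  and round-trip losslessly, as do label masks with up to 65535 labels.
* Problem sizes in the bundled tests and acceptance runs — e.g. two
  25-cell x 120-frame chemotaxis scenes for the effect-size recovery and a
  100-fiber image for orientation checks — are chosen so the whole suite runs
  in minutes while keeping every statistical check well-powered.

## Known limitations

Touching cells are not split (no watershed); mitosis is neither simulated nor
tracked (no lineage trees); the per-frame Otsu is global, not tiled; the
tracker's window-sequential matching is exact per step but not across steps
(a globally optimal multi-frame solution could differ in rare gap
configurations); and the synthetic transmitted-light model is far simpler
than real phase-contrast optics.
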
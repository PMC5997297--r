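# fuccitrack

Cell-cycle-resolved migration analysis for FUCCI time-lapse microscopy, built
for the question: *is directed (contact-guided, chemotactic) cancer-cell
migration cell-cycle-dependent?* The package reimplements the full measurement
chain used to answer it — fluorescence/transmitted-light segmentation,
cost-gated multi-frame tracking, FUCCI phase classification, migration
statistics, a microchannel chemoattractant-gradient diffusion model, and
collagen fiber orientation analysis — together with a ground-truthed synthetic
scene generator, so the whole chain is testable without any raw movies.

It is aimed at quantitative cell biologists and image-analysis developers who
want a reproducible, scriptable version of this measurement, or a validated
baseline to compare their own pipelines against.

## The measurement in brief

* **FUCCI classification.** Red (mKO2-hCdt1) marks G1, green (mAG-hGem) marks
  S/G2, and a transient ~2 h red+green overlap marks early S. Longitudinally
  tracked cells are classified per frame by the 50%-of-maximum-red rule
  (mean red > 0.5 x track max -> G1, else S/G2); overlap frames are excluded.
* **Migration metrics.** Instantaneous velocity `v_i = |x(t_{i+1}) - x(t_i)| / dt`
  (um/min) and persistence = net displacement / total path length, in [0, 1];
  per-cell G1:S/G2 ratios of both; equal-variance two-tailed Student t-tests
  with `*`/`**`/`***` at p < 0.05/0.01/0.001.
* **Tracking.** Detections are linked over a 3-frame window with a cost built
  from position, size and intensity differences, gated at twice the larger
  cell radius (adaptively expanded until >= 5 candidates) and at 90% area
  difference; each window step is solved as an exact min-cost max-cardinality
  assignment. Verified against exhaustive enumeration on small instances.
* **Gradient model.** dC/dt = D (Cxx + Cyy) on the 850 x 10 um channel with a
  constant-concentration source edge, concentration-proportional sink outflux
  and no-flux walls, D = 0.5e-4 cm2/s, solved by explicit finite differences
  and checked against the 1D Robin closed form C(x) = C0 (1 - x/(L + D/k)).
* **Fiber orientation.** Structure-tensor orientation fields summarize
  collagen images; the Rayleigh test on doubled (axial) angles separates
  uniform (random gel) from unimodal (aligned gel) distributions.

## Worked example

Simulate a microchannel + chemoattractant experiment whose G1 cells are 1.2x
faster than S/G2 cells, run the full pipeline, and test the difference:

```r
library(fuccitrack)

cfg <- scene_config(n_cells = 15, n_frames = 60, mode = "channel_chemotaxis",
                    chemotaxis_bias = 0.5, image_shape = c(384L, 1024L),
                    pixel_size = 1.3, channel_pitch = 32, start_span = 0.4,
                    speed_G1 = 0.6, speed_SG2 = 0.5, seed = 102L)
truth <- simulate_trajectories(cfg)
movie <- render_movie(truth)
res   <- run_pipeline(movie, out_dir = "results/pipeline/channel")

m    <- res$metrics
cmp  <- compare_groups(m$mean_instantaneous_velocity[m$phase_segment == "G1"],
                       m$mean_instantaneous_velocity[m$phase_segment == "SG2"])
vp   <- velocity_by_phase(res)
```

On this scene the pipeline prints (via `analysis/04_migration_statistics.R`):

```
channel: G1 0.583 +/- 0.007 um/min (n=12) vs S/G2 0.489 +/- 0.003 (n=13): t=13.35, p=2.55e-12 ***; excess 19.3%
  per-cell ratios (n=9): median velocity 1.212, median persistence 1.037
```

Read: G1-classified track segments move at 0.583 um/min (mean +/- SEM) versus
0.489 um/min for S/G2 — a 19.3% excess recovering the generator's 1.2x speed
ratio — and the per-cell velocity ratio (same cell followed through both
phases) has median 1.212. Tracking against ground truth on this scene: 16
tracks, 0 identity switches, purity 1.000.

The gradient model (`analysis/02_gradient_model.R`) prints:

```
steepness at 6 h: 5.405e-04 per um; at 24 h: 5.405e-04 per um
relative change 6 -> 24 h: 0% (stable gradient window)
channel volume 1.7e-04 mm3 vs reservoir 200 mm3 (10^6.1-fold)
```

i.e. the gradient is effectively at steady state well before 6 h (L^2/D is
about 2.4 min), which is what makes the 6-24 h imaging window usable. And the
fiber analysis (`analysis/05_fiber_orientation.R`):

```
random gel: verdict uniform (Rayleigh p = 0.878); mu = 30.4 deg, sigma = 81.2 deg
aligned gel: verdict unimodal (Rayleigh p = 2.17e-257); mu = 89.5 deg, sigma = 7.5 deg
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the whole study flow on synthetic
data; each writes its tables under `results/`:

1. `01_simulate_scenes.R` — generate free-2D and channel scenes (TIFF + ground truth)
2. `02_gradient_model.R` — gradient formation, steepness stability, geometry
3. `03_segment_track_classify.R` — segmentation, tracking, phase labels, quality vs truth
4. `04_migration_statistics.R` — per-phase velocities, ratios, t-tests
5. `05_fiber_orientation.R` — fiber angle estimation and uniform/aligned verdicts

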
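#!/usr/bin/env Rscript
# Run the full image-analysis pipeline (denoise -> adaptive Otsu -> phase-mask
# intersection -> cost-gated tracking -> longitudinal FUCCI classification) on
# the movies written by 01_simulate_scenes.R, and score tracking quality
# against the generator's ground truth.

library(fuccitrack)

for (nm in c("free2d", "channel")) {
  dir <- file.path("results/scenes", nm)
  if (!dir.exists(dir)) stop("run analysis/01_simulate_scenes.R first")
  cfg <- read_flat_config(file.path(dir, "scene_config.txt"))
  movie <- read_movie_tiff(file.path(dir, paste0(nm, "_red.tif")),
                           file.path(dir, paste0(nm, "_green.tif")),
                           file.path(dir, paste0(nm, "_trans.tif")),
                           pixel_size = cfg$pixel_size,
                           frame_interval = cfg$frame_interval)
  res <- run_pipeline(movie, out_dir = file.path("results/pipeline", nm))
  truth <- read_ground_truth(file.path(dir, "ground_truth.csv"))
  lq <- link_quality(res$tracks, truth, max_dist_um = 10 * cfg$pixel_size)
  message(sprintf(
    "%s: %d detections, %d tracks, %d identity switches, mean purity %.3f, %d overlap frames excluded",
    nm, nrow(res$detections), res$n_tracks, lq$switches, lq$mean_purity,
    res$excluded))
}
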
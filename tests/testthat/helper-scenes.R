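# Shared fixture builders (everything is generated in code).

# Small noise-free scene with well-separated stationary-ish cells placed on a
# grid: the cleanest oracle for segmentation accuracy checks.
grid_scene <- function(n_cells = 5, n_frames = 3, image_px = 256L,
                       noise = FALSE, mode = "free2d", seed = 42L) {
  cfg <- fuccitrack::scene_config(
    n_cells = n_cells, n_frames = n_frames,
    image_shape = c(image_px, image_px), mode = mode,
    speed_G1 = 0.3, speed_SG2 = 0.25,
    background_amplitude = if (noise) 50 else 0,
    shot_noise_scale = if (noise) 20 else 0,
    seed = seed)
  fld <- image_px * cfg$pixel_size
  k <- ceiling(sqrt(n_cells))
  xs <- fld * (rep(seq_len(k), k)[seq_len(n_cells)] - 0.5) / k
  ys <- fld * (rep(seq_len(k), each = k)[seq_len(n_cells)] - 0.5) / k
  truth <- do.call(rbind, lapply(seq_len(n_cells), function(ci)
    data.frame(cell_id = ci, frame = seq_len(n_frames),
               t_min = (seq_len(n_frames) - 1) * cfg$frame_interval,
               x_um = xs[ci], y_um = ys[ci],
               phase = "G1", red = cfg$intensity_peak, green = 0)))
  structure(list(config = cfg, truth = truth), class = "ground_truth")
}

# A track data.frame from raw coordinates (um), 10 min frame interval
toy_track <- function(x, y, frame = seq_along(x), dt_min = 10) {
  data.frame(frame = frame, t_min = (frame - 1) * dt_min, x_um = x, y_um = y)
}

# Minimal detection row for tracking unit tests
det_row <- function(frame, x, y, area = 100, red = 500, green = 0,
                    label_id = 1L) {
  data.frame(frame = frame, label_id = label_id, x_px = x, y_px = y,
             area_px = area, radius_px = sqrt(area / pi),
             mean_red = red, mean_green = green)
}
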
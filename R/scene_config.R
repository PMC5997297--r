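#' Parameterize a synthetic FUCCI time-lapse experiment
#'
#' Bundles every knob of the synthetic scene generator: population size and
#' movie length, physical calibration, motility regime, the FUCCI cell-cycle
#' clock, and the rendering/noise model. The defaults emulate a 20x widefield
#' acquisition of FUCCI-labelled breast carcinoma cells imaged every 10 minutes,
#' with microchannel geometry matching a 10 um-wide channel array.
#'
#' @param n_cells number of simulated cells.
#' @param n_frames number of movie frames.
#' @param frame_interval minutes between frames (default 10).
#' @param pixel_size microns per pixel (default 0.65, 20x objective scale).
#' @param image_shape integer c(height, width) in pixels.
#' @param mode one of "free2d" (unconstrained 2D walk), "channel" (confined to
#'   horizontal microchannels), "channel_chemotaxis" (confined plus a +x
#'   heading bias emulating a chemoattractant gradient).
#' @param channel_width microchannel width in microns (default 10).
#' @param channel_pitch center-to-center spacing of parallel channels, microns.
#' @param taper_entry_x x position (um) of the taper entry where track
#'   recording starts; 0 disables entry clipping.
#' @param start_span fraction (0, 1] of the usable channel length over which
#'   initial x positions are staggered; keep below 1 for chemotaxis scenes so
#'   the directed run fits inside the field.
#' @param speed_G1,speed_SG2 mean cell speed in each phase, um/min.
#' @param heading_noise_G1,heading_noise_SG2 sd of the per-step heading
#'   perturbation, radians.
#' @param chemotaxis_bias dimensionless in [0, 1]; strength of the restoring
#'   torque toward the +x gradient direction (channel_chemotaxis mode only).
#' @param t_G1,t_overlap,t_SG2 cell-cycle clock durations in hours: G1 (red),
#'   the red/green early-S overlap, and S/G2 (green). Defaults 10 + 2 + 10 h.
#' @param cycle_phase_offsets per-cell starting position in the cycle as a
#'   fraction in [0, 1); NULL draws them uniformly (asynchronous population).
#' @param blob_radius rendered cell radius (Gaussian sd), microns.
#' @param intensity_peak peak fluorescence of a fully-on channel, a.u.
#' @param background_amplitude sd of the slow-varying background field, a.u.
#' @param shot_noise_scale sd of the per-pixel shot noise, a.u.
#' @param seed integer RNG seed; identical config (incl. seed) gives
#'   bit-identical ground truth and rendered movies.
#' @return object of class `scene_config` (a validated list).
#' @export
scene_config <- function(n_cells = 20, n_frames = 120, frame_interval = 10,
                         pixel_size = 0.65, image_shape = c(512L, 512L),
                         mode = c("free2d", "channel", "channel_chemotaxis"),
                         channel_width = 10, channel_pitch = 48,
                         taper_entry_x = 0, start_span = 1,
                         speed_G1 = 0.6, speed_SG2 = 0.5,
                         heading_noise_G1 = 0.5, heading_noise_SG2 = 0.5,
                         chemotaxis_bias = 0,
                         t_G1 = 10, t_overlap = 2, t_SG2 = 10,
                         cycle_phase_offsets = NULL,
                         blob_radius = 4, intensity_peak = 1000,
                         background_amplitude = 50, shot_noise_scale = 20,
                         seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, pixel_size = pixel_size,
    image_shape = as.integer(image_shape), mode = mode,
    channel_width = channel_width, channel_pitch = channel_pitch,
    taper_entry_x = taper_entry_x, start_span = start_span,
    speed_G1 = speed_G1, speed_SG2 = speed_SG2,
    heading_noise_G1 = heading_noise_G1, heading_noise_SG2 = heading_noise_SG2,
    chemotaxis_bias = chemotaxis_bias,
    t_G1 = t_G1, t_overlap = t_overlap, t_SG2 = t_SG2,
    cycle_phase_offsets = cycle_phase_offsets,
    blob_radius = blob_radius, intensity_peak = intensity_peak,
    background_amplitude = background_amplitude,
    shot_noise_scale = shot_noise_scale, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  pos <- c("frame_interval", "pixel_size", "channel_width", "channel_pitch",
           "t_G1", "t_overlap", "t_SG2", "blob_radius", "intensity_peak")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("scene_config: '", f, "' must be finite and strictly positive",
           call. = FALSE)
  }
  for (f in c("speed_G1", "speed_SG2", "heading_noise_G1", "heading_noise_SG2",
              "background_amplitude", "shot_noise_scale", "taper_entry_x")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop("scene_config: '", f, "' must be finite and non-negative",
           call. = FALSE)
  }
  if (cfg$n_cells < 0 || cfg$n_frames < 1)
    stop("scene_config: need n_cells >= 0 and n_frames >= 1", call. = FALSE)
  if (cfg$chemotaxis_bias < 0 || cfg$chemotaxis_bias > 1)
    stop("scene_config: chemotaxis_bias must lie in [0, 1]", call. = FALSE)
  if (cfg$channel_width / cfg$pixel_size < 4)
    stop("scene_config: channel_width/pixel_size must be >= 4 pixels ",
         "(cells must be resolvable)", call. = FALSE)
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 10))
    stop("scene_config: image_shape must be two dimensions >= 10 px",
         call. = FALSE)
  if (!is.null(cfg$cycle_phase_offsets)) {
    o <- cfg$cycle_phase_offsets
    if (length(o) != cfg$n_cells || any(o < 0) || any(o >= 1))
      stop("scene_config: cycle_phase_offsets must be n_cells values in [0,1)",
           call. = FALSE)
  }
  if (cfg$start_span <= 0 || cfg$start_span > 1)
    stop("scene_config: start_span must lie in (0, 1]", call. = FALSE)
  if (abs(cfg$seed) >= 2^30)
    stop("scene_config: |seed| must be < 2^30", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic scene config:", x$n_cells, "cells,", x$n_frames, "frames @",
      x$frame_interval, "min;", x$mode, "mode;",
      paste(x$image_shape, collapse = "x"), "px @", x$pixel_size, "um/px;",
      "seed", x$seed, "\n")
  invisible(x)
}

# Field dimensions in microns: c(height_um, width_um)
field_um <- function(cfg) cfg$image_shape * cfg$pixel_size

# y centerlines (um) of the channels that fit in the field
channel_centerlines <- function(cfg) {
  h <- field_um(cfg)[1]
  n <- max(1L, floor(h / cfg$channel_pitch))
  offset <- (h - (n - 1) * cfg$channel_pitch) / 2
  offset + (seq_len(n) - 1) * cfg$channel_pitch
}
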
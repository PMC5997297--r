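#' Simulate ground-truth cell trajectories with a phase-dependent persistent
#' random walk
#'
#' Cells perform a discrete-time persistent random walk: each step the heading
#' receives a Gaussian perturbation whose sd depends on the current cell-cycle
#' phase, and the step length is the phase speed times the frame interval with
#' 10% multiplicative jitter. In the channel modes, y positions reflect off the
#' channel walls; in `channel_chemotaxis` a restoring torque of strength
#' `chemotaxis_bias` pulls headings toward +x. Cell-cycle phase follows a
#' deterministic clock (G1 -> early-S overlap -> S/G2, then restart) started at
#' each cell's `cycle_phase_offsets`; true FUCCI intensities follow the clock.
#'
#' @param config a [scene_config()].
#' @return object of class `ground_truth`: list with `config` and `truth`, a
#'   data.frame with columns cell_id, frame (1-based), t_min, x_um, y_um,
#'   phase ("G1"/"earlyS"/"SG2"), red, green.
#' @export
simulate_trajectories <- function(config) {
  validate_scene_config(config)
  cfg <- config
  set.seed(cfg$seed)
  fld <- field_um(cfg)
  dt_min <- cfg$frame_interval
  t_min <- (seq_len(cfg$n_frames) - 1) * dt_min
  cycle_h <- cfg$t_G1 + cfg$t_overlap + cfg$t_SG2

  offsets <- cfg$cycle_phase_offsets
  if (is.null(offsets)) offsets <- runif(cfg$n_cells)

  in_channel <- cfg$mode %in% c("channel", "channel_chemotaxis")
  centers <- if (in_channel) channel_centerlines(cfg) else NULL
  half_w <- cfg$channel_width / 2

  out <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    # clock state over the movie (hours within the cycle)
    cyc_t <- ((t_min / 60) + offsets[ci] * cycle_h) %% cycle_h
    ph <- cycle_phase(cyc_t, cfg)
    inten <- fucci_intensity(cyc_t, cfg)

    margin <- pmin(4 * cfg$blob_radius, fld / 4)
    if (in_channel) {
      chan <- centers[((ci - 1) %% length(centers)) + 1]
      n_in_chan <- ceiling(cfg$n_cells / length(centers))
      slot <- (ci - 1) %/% length(centers)
      x_lo <- max(cfg$taper_entry_x, margin[2])
      span <- (fld[2] - margin[2] - x_lo) * cfg$start_span
      x0 <- x_lo + span * (slot + 0.5) / n_in_chan +
        runif(1, -0.15, 0.15) * span / n_in_chan
      y0 <- chan + runif(1, -half_w / 2, half_w / 2)
    } else {
      x0 <- runif(1, margin[2], fld[2] - margin[2])
      y0 <- runif(1, margin[1], fld[1] - margin[1])
    }

    x <- numeric(cfg$n_frames); y <- numeric(cfg$n_frames)
    x[1] <- x0; y[1] <- y0
    heading <- runif(1, -pi, pi)
    for (fr in seq_len(cfg$n_frames - 1)) {
      f <- overlap_fraction(cyc_t[fr], cfg)
      speed <- blend_phase(cfg$speed_G1, cfg$speed_SG2, ph[fr], f)
      hnoise <- blend_phase(cfg$heading_noise_G1, cfg$heading_noise_SG2,
                            ph[fr], f)
      heading <- heading + rnorm(1, 0, hnoise)
      if (cfg$mode == "channel_chemotaxis")
        heading <- heading - cfg$chemotaxis_bias * sin(heading)
      step <- speed * dt_min * max(0, 1 + 0.1 * rnorm(1))
      nx <- x[fr] + step * cos(heading)
      ny <- y[fr] + step * sin(heading)
      if (in_channel) {
        refl <- reflect_interval(ny, chan - half_w, chan + half_w)
        ny <- refl$value
        if (refl$flipped) heading <- -heading
        nx <- reflect_interval(nx, 0, fld[2])$value
      } else {
        rx <- reflect_interval(nx, 0, fld[2])
        ry <- reflect_interval(ny, 0, fld[1])
        nx <- rx$value; ny <- ry$value
        if (rx$flipped) heading <- pi - heading
        if (ry$flipped) heading <- -heading
      }
      x[fr + 1] <- nx; y[fr + 1] <- ny
    }
    out[[ci]] <- data.frame(cell_id = ci, frame = seq_len(cfg$n_frames),
                            t_min = t_min, x_um = x, y_um = y, phase = ph,
                            red = inten$red, green = inten$green,
                            stringsAsFactors = FALSE)
  }
  truth <- if (cfg$n_cells > 0) do.call(rbind, out) else
    data.frame(cell_id = integer(), frame = integer(), t_min = numeric(),
               x_um = numeric(), y_um = numeric(), phase = character(),
               red = numeric(), green = numeric())
  structure(list(config = cfg, truth = truth), class = "ground_truth")
}

# Map time-within-cycle (hours) to phase label
cycle_phase <- function(cyc_t, cfg) {
  ifelse(cyc_t < cfg$t_G1, "G1",
         ifelse(cyc_t < cfg$t_G1 + cfg$t_overlap, "earlyS", "SG2"))
}

# Fraction through the early-S overlap window (0 outside-G1-side, 1 at S/G2)
overlap_fraction <- function(cyc_t, cfg) {
  pmin(1, pmax(0, (cyc_t - cfg$t_G1) / cfg$t_overlap))
}

blend_phase <- function(v_g1, v_sg2, phase, f) {
  if (phase == "G1") v_g1
  else if (phase == "SG2") v_sg2
  else (1 - f) * v_g1 + f * v_sg2
}

# Fold a coordinate back into [lo, hi] by reflection; flags odd reflections
reflect_interval <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  flipped <- u > w
  list(value = lo + ifelse(flipped, 2 * w - u, u), flipped = isTRUE(flipped))
}

# True FUCCI intensities from the clock: red full in G1 and decaying linearly
# across the overlap; green rising linearly across the overlap, full in S/G2.
fucci_intensity <- function(cyc_t, cfg) {
  f <- overlap_fraction(cyc_t, cfg)
  in_g1 <- cyc_t < cfg$t_G1
  in_sg2 <- cyc_t >= cfg$t_G1 + cfg$t_overlap
  red <- cfg$intensity_peak * ifelse(in_g1, 1, ifelse(in_sg2, 0, 1 - f))
  green <- cfg$intensity_peak * ifelse(in_sg2, 1, ifelse(in_g1, 0, f))
  list(red = red, green = green)
}

#' Per-frame FUCCI intensities for a phase label sequence
#'
#' Red is at `intensity_peak` through G1 and decays linearly to zero across the
#' early-S overlap; green is zero through G1, rises linearly across the
#' overlap, and sits at `intensity_peak` through S/G2. Both channels exceed
#' half their per-cell maximum only inside the overlap window.
#'
#' When `cycle_time` (hours within the cycle, per frame) is supplied the ramp
#' position is taken from the clock; otherwise it is inferred from the position
#' inside each contiguous run of "earlyS" labels (run midpoint convention, so a
#' run of k frames samples the ramp at (i - 1/2)/k).
#'
#' @param phase_labels character vector of "G1"/"earlyS"/"SG2".
#' @param config a [scene_config()] (supplies `intensity_peak` and the clock).
#' @param cycle_time optional numeric vector, hours within the cycle.
#' @return data.frame with columns red, green.
#' @export
fucci_trace <- function(phase_labels, config, cycle_time = NULL) {
  stopifnot(all(phase_labels %in% c("G1", "earlyS", "SG2")))
  if (!is.null(cycle_time)) {
    i <- fucci_intensity(cycle_time, config)
    return(data.frame(red = i$red, green = i$green))
  }
  n <- length(phase_labels)
  f <- numeric(n)
  f[phase_labels == "SG2"] <- 1
  r <- rle(phase_labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values == "earlyS")) {
    k <- r$lengths[j]
    f[starts[j]:ends[j]] <- (seq_len(k) - 0.5) / k
  }
  peak <- config$intensity_peak
  red <- peak * ifelse(phase_labels == "G1", 1,
                       ifelse(phase_labels == "SG2", 0, 1 - f))
  green <- peak * ifelse(phase_labels == "SG2", 1,
                         ifelse(phase_labels == "G1", 0, f))
  data.frame(red = red, green = green)
}
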
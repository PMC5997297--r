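#' Instantaneous velocities along a track
#'
#' The instantaneous velocity is the displacement between two consecutive
#' observed frames divided by the elapsed time; steps spanning an occlusion
#' gap use the actual elapsed time.
#'
#' @param track data.frame with t_min, x_um, y_um (one track).
#' @return numeric vector of per-step velocities, um/min (length n-1; empty
#'   for single-detection tracks).
#' @export
instantaneous_velocity <- function(track) {
  track <- track[order(track$t_min), , drop = FALSE]
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  dx <- diff(track$x_um); dy <- diff(track$y_um); dt <- diff(track$t_min)
  sqrt(dx^2 + dy^2) / dt
}

#' Migration persistence of a track
#'
#' Net (start-to-end) displacement divided by the total path length; 1 for a
#' straight path, 0 for a path returning to its start. A zero-length path has
#' undefined persistence and returns NA with a warning.
#'
#' @param track data.frame with t_min, x_um, y_um (>= 2 rows).
#' @return persistence in [0, 1], or NA for a motionless track.
#' @export
persistence <- function(track) {
  track <- track[order(track$t_min), , drop = FALSE]
  if (nrow(track) < 2)
    stop("persistence: need at least 2 positions", call. = FALSE)
  path <- sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
  if (path == 0) {
    warning("persistence: zero path length; undefined")
    return(NA_real_)
  }
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  net / path
}

# Contiguous runs of TRUE (bridging gaps of <= bridge frames), as index lists
phase_runs <- function(frames, flag, bridge = 1) {
  idx <- which(flag)
  if (!length(idx)) return(list())
  f <- frames[idx]
  brk <- c(0, which(diff(f) > bridge + 1), length(f))
  lapply(seq_len(length(brk) - 1),
         function(i) idx[(brk[i] + 1):brk[i + 1]])
}

# Segment metrics for one phase within a track: pooled mean step velocity and
# step-weighted mean persistence over contiguous runs of >= min_steps frames
segment_metrics <- function(track, flag, min_steps = 6, bridge = 1) {
  runs <- phase_runs(track$frame, flag, bridge)
  runs <- runs[lengths(runs) >= min_steps]
  if (!length(runs)) return(NULL)
  v <- c(); pers <- c(); wts <- c(); n_steps <- 0
  for (r in runs) {
    seg <- track[r, , drop = FALSE]
    v <- c(v, instantaneous_velocity(seg))
    p <- suppressWarnings(persistence(seg))
    if (!is.na(p)) { pers <- c(pers, p); wts <- c(wts, nrow(seg) - 1) }
    n_steps <- n_steps + nrow(seg) - 1
  }
  list(mean_velocity = mean(v),
       persistence = if (length(pers)) sum(pers * wts) / sum(wts) else NA_real_,
       n_steps = n_steps)
}

#' Per-cell G1 to S/G2 migration ratios
#'
#' For tracks observed through both phases, computes the ratio of the
#' phase-segment metrics (mean instantaneous velocity and persistence) between
#' the G1 and S/G2 segments of the same cell. Early-S overlap frames are
#' excluded; only contiguous phase runs of at least `min_steps` frames count,
#' with occlusion gaps of at most one frame bridged.
#'
#' @param track data.frame for one track (frame, t_min, x_um, y_um).
#' @param phase per-frame phase labels aligned with `track` rows
#'   (G1/earlyS_overlap/SG2/unknown), e.g. from [classify_longitudinal()].
#' @param min_steps minimum frames per phase segment (default 6).
#' @return one-row data.frame with velocity_ratio_G1_over_SG2,
#'   persistence_ratio_G1_over_SG2 and the per-phase metrics, or NULL when a
#'   phase segment is missing.
#' @export
per_cell_ratios <- function(track, phase, min_steps = 6) {
  stopifnot(length(phase) == nrow(track))
  track <- track[order(track$frame), , drop = FALSE]
  g1 <- segment_metrics(track, phase == "G1", min_steps)
  sg2 <- segment_metrics(track, phase == "SG2", min_steps)
  if (is.null(g1) || is.null(sg2)) return(NULL)
  data.frame(velocity_G1 = g1$mean_velocity, velocity_SG2 = sg2$mean_velocity,
             persistence_G1 = g1$persistence, persistence_SG2 = sg2$persistence,
             n_steps_G1 = g1$n_steps, n_steps_SG2 = sg2$n_steps,
             velocity_ratio_G1_over_SG2 = g1$mean_velocity / sg2$mean_velocity,
             persistence_ratio_G1_over_SG2 = g1$persistence / sg2$persistence)
}

#' Clip a track to start at microchannel taper entry
#'
#' Track recording starts when the cell enters the tapered channel mouth:
#' the track is truncated to begin at its first frame with x >= taper_entry_x;
#' tracks that never enter are dropped (NULL).
#'
#' @param track data.frame with x_um, frame.
#' @param taper_entry_x entry x position, um.
#' @return the clipped track, or NULL.
#' @export
channel_entry_filter <- function(track, taper_entry_x) {
  track <- track[order(track$frame), , drop = FALSE]
  k <- which(track$x_um >= taper_entry_x)[1]
  if (is.na(k)) return(NULL)
  track[k:nrow(track), , drop = FALSE]
}

#' Two-sample comparison with the two-tailed Student t-test
#'
#' Equal-variance two-tailed t-test (Welch available via `var_equal = FALSE`),
#' with group summaries as mean +/- SEM and significance stars (* p < 0.05,
#' ** p < 0.01, *** p < 0.001).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param var_equal pool variances (classic Student test; default TRUE).
#' @return list with n/mean/sem per group, t, df, p and `stars`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("compare_groups: each sample needs n >= 2", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0)
    stop("compare_groups: zero variance in both groups", call. = FALSE)
  ht <- t.test(a, b, var.equal = var_equal)
  list(n_a = length(a), mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
       n_b = length(b), mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = significance_stars(ht$p.value))
}

#' @rdname compare_groups
#' @param p a p-value.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}
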
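#' Run the full segmentation -> tracking -> phase -> statistics pipeline
#'
#' Executes the stages in order on a multi-channel movie: per-frame cell
#' detection (denoise, adaptive Otsu, transmitted-light intersection),
#' cost-gated multi-frame association, longitudinal FUCCI phase
#' classification, and migration statistics (per-track per-phase velocity and
#' persistence, per-cell G1:S/G2 ratios, G1 vs S/G2 group comparison). The
#' pipeline contains no randomness: identical inputs give identical outputs.
#'
#' @param movie a `movie_stack` (from [render_movie()] or [read_movie_tiff()]).
#' @param min_size minimum segmented object area, pixels.
#' @param window tracking association window, frames.
#' @param min_track_len tracks shorter than this many frames are dropped from
#'   statistics (default 5).
#' @param min_steps minimum frames per phase segment for per-cell ratios.
#' @param taper_entry_x when positive, tracks are clipped to start at their
#'   first frame with x >= this position (um) and non-entering tracks dropped.
#' @param out_dir optional output directory; when given, detections, tracks,
#'   phase-labeled tracks, metrics, ratios, the group comparison and a
#'   manifest are written as CSV/text under it.
#' @return list with detections, tracks (phase-labeled data.frame), metrics
#'   (per track and phase segment), ratios (per-cell), comparison (G1 vs S/G2
#'   velocity test or NULL), excluded (early-S overlap frame count), and
#'   n_tracks.
#' @export
run_pipeline <- function(movie, min_size = 30, window = 3, min_track_len = 5,
                         min_steps = 6, taper_entry_x = 0, out_dir = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  det <- detect_cells(movie, min_size = min_size)
  tracks <- associate(det$detections, window = window)
  if (nrow(tracks)) {
    tracks$t_min <- (tracks$frame - 1) * movie$frame_interval
    keep <- names(which(table(tracks$track_id) >= min_track_len))
    tracks <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  }

  # entry clipping (channel experiments)
  if (taper_entry_x > 0 && nrow(tracks)) {
    parts <- split(tracks, tracks$track_id)
    parts <- lapply(parts, channel_entry_filter, taper_entry_x = taper_entry_x)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    parts <- parts[vapply(parts, nrow, 1L) >= min_track_len]
    tracks <- if (length(parts)) do.call(rbind, parts) else tracks[0, ]
  }

  # longitudinal phase classification
  tracks$phase <- rep(NA_character_, nrow(tracks))
  metrics <- list(); ratios <- list(); excluded <- 0L
  for (tid in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == tid)
    tr <- tracks[sel, , drop = FALSE]
    pt <- tryCatch(suppressWarnings(classify_longitudinal(tr)),
                   error = function(e) NULL)
    if (is.null(pt)) next
    ord <- order(tr$frame)
    tracks$phase[sel[ord]] <- pt$phase
    tr <- tr[ord, , drop = FALSE]
    excluded <- excluded + sum(pt$phase == "earlyS_overlap")
    for (ph in c("G1", "SG2")) {
      m <- segment_metrics(tr, pt$phase == ph, min_steps)
      if (!is.null(m))
        metrics[[length(metrics) + 1]] <-
          data.frame(track_id = tid, phase_segment = ph,
                     mean_instantaneous_velocity = m$mean_velocity,
                     persistence = m$persistence, n_steps = m$n_steps)
    }
    wt <- if (nrow(tr) >= 2) suppressWarnings(persistence(tr)) else NA_real_
    if (nrow(tr) >= 2)
      metrics[[length(metrics) + 1]] <-
        data.frame(track_id = tid, phase_segment = "whole_track",
                   mean_instantaneous_velocity =
                     mean(instantaneous_velocity(tr)),
                   persistence = wt, n_steps = nrow(tr) - 1)
    rr <- per_cell_ratios(tr, pt$phase, min_steps)
    if (!is.null(rr)) {
      rr$track_id <- tid
      ratios[[length(ratios) + 1]] <- rr
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  ratios <- if (length(ratios)) do.call(rbind, ratios) else NULL

  comparison <- NULL
  if (!is.null(metrics)) {
    vg1 <- metrics$mean_instantaneous_velocity[metrics$phase_segment == "G1"]
    vsg2 <- metrics$mean_instantaneous_velocity[metrics$phase_segment == "SG2"]
    if (length(vg1) >= 2 && length(vsg2) >= 2)
      comparison <- tryCatch(compare_groups(vg1, vsg2), error = function(e) NULL)
  }

  result <- list(detections = det$detections, tracks = tracks,
                 metrics = metrics, ratios = ratios, comparison = comparison,
                 excluded = excluded,
                 n_tracks = length(unique(tracks$track_id)))
  if (!is.null(out_dir)) write_pipeline_outputs(result, movie, out_dir)
  result
}

write_pipeline_outputs <- function(result, movie, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$detections, file.path(out_dir, "detections.csv"),
            row.names = FALSE)
  write.csv(result$tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  if (!is.null(result$metrics))
    write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  if (!is.null(result$ratios))
    write.csv(result$ratios, file.path(out_dir, "ratios.csv"),
              row.names = FALSE)
  if (!is.null(result$comparison)) {
    cmp <- result$comparison
    write.csv(data.frame(group = c("G1", "SG2"),
                         n = c(cmp$n_a, cmp$n_b),
                         mean = c(cmp$mean_a, cmp$mean_b),
                         sem = c(cmp$sem_a, cmp$sem_b),
                         t = cmp$t, p = cmp$p, stars = cmp$stars),
              file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  cfg <- movie$config
  manifest <- c(paste0("fuccitrack_version=", as.character(packageVersion("fuccitrack"))),
                paste0("pixel_size=", sprintf("%.17g", movie$pixel_size)),
                paste0("frame_interval=", sprintf("%.17g", movie$frame_interval)))
  if (!is.null(cfg)) {
    cfg_path <- file.path(out_dir, "scene_config.txt")
    write_flat_config(cfg, cfg_path)
    manifest <- c(manifest,
                  paste0("scene_config_md5=", unname(tools::md5sum(cfg_path))))
  }
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Population mean velocity per cell-cycle phase
#'
#' Summarizes a pipeline result as the mean of per-track phase-segment mean
#' instantaneous velocities for G1 and S/G2 (the default), or the mean over
#' pooled per-step velocities when `pooled = TRUE`.
#'
#' @param result a [run_pipeline()] result (or a metrics data.frame).
#' @param pooled pool steps across tracks weighted by step count.
#' @return named list with mean_G1, mean_SG2, n_G1, n_SG2 and
#'   percent_excess_G1 = 100 * (mean_G1/mean_SG2 - 1).
#' @export
velocity_by_phase <- function(result, pooled = FALSE) {
  metrics <- if (is.data.frame(result)) result else result$metrics
  sel <- metrics$phase_segment %in% c("G1", "SG2")
  m <- metrics[sel, , drop = FALSE]
  agg <- function(ph) {
    mm <- m[m$phase_segment == ph, , drop = FALSE]
    if (!nrow(mm)) return(c(mean = NA_real_, n = 0))
    v <- if (pooled)
      sum(mm$mean_instantaneous_velocity * mm$n_steps) / sum(mm$n_steps)
    else mean(mm$mean_instantaneous_velocity)
    c(mean = v, n = nrow(mm))
  }
  g1 <- agg("G1"); sg2 <- agg("SG2")
  list(mean_G1 = unname(g1["mean"]), mean_SG2 = unname(sg2["mean"]),
       n_G1 = unname(g1["n"]), n_SG2 = unname(sg2["n"]),
       percent_excess_G1 = 100 * (unname(g1["mean"]) / unname(sg2["mean"]) - 1))
}
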
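#' Longitudinal FUCCI phase classification of a track
#'
#' Frames with mean red fluorescence above 50% of the track's maximum red are
#' classified G1, the rest S/G2. Frames where additionally the green channel
#' exceeds 50% of the track's maximum green are marked as the early-S
#' red/green overlap ("earlyS_overlap"). The switch frame is the first frame
#' classified S/G2 after a G1 run. Classification depends only on per-track
#' normalized intensities, so it is invariant to common intensity scaling.
#'
#' @param track data.frame for one track with columns frame, mean_red,
#'   mean_green (ordered or unordered).
#' @param min_frames minimum track length to classify (default 5).
#' @return object of class `phase_trace`: list with `frames`, `phase`
#'   (G1/earlyS_overlap/SG2/unknown per frame), `max_red`, `max_green`,
#'   `switch_frame` (NA when no G1 -> S/G2 switch is observed).
#' @export
classify_longitudinal <- function(track, min_frames = 5) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < min_frames)
    stop("classify_longitudinal: track shorter than ", min_frames, " frames",
         call. = FALSE)
  max_red <- max(track$mean_red)
  max_green <- max(track$mean_green)
  n <- nrow(track)
  if (max_red <= 0) {
    warning("classify_longitudinal: all-zero red trace; phases unknown")
    return(structure(list(frames = track$frame,
                          phase = rep("unknown", n),
                          max_red = max_red, max_green = max_green,
                          switch_frame = NA_integer_),
                     class = "phase_trace"))
  }
  red_hi <- track$mean_red > 0.5 * max_red
  green_hi <- max_green > 0 & track$mean_green > 0.5 * max_green
  phase <- ifelse(red_hi, ifelse(green_hi, "earlyS_overlap", "G1"), "SG2")
  sw <- NA_integer_
  pure_sg2 <- which(!red_hi)
  if (length(pure_sg2)) {
    first_g1 <- which(red_hi)[1]
    cand <- pure_sg2[pure_sg2 > first_g1]
    if (!is.na(first_g1) && length(cand)) sw <- track$frame[cand[1]]
  }
  structure(list(frames = track$frame, phase = phase, max_red = max_red,
                 max_green = max_green, switch_frame = sw),
            class = "phase_trace")
}

#' Snapshot (population-level) FUCCI classification
#'
#' Classifies detections independently of track context: red-only above
#' threshold is G1, green-only is S/G2, both is "yellow" (the early-S overlap,
#' excluded from phase-stratified quantification), neither is "unknown".
#'
#' @param detections data.frame with mean_red, mean_green.
#' @param red_threshold,green_threshold positive intensity thresholds.
#' @return character vector of phases.
#' @export
classify_snapshot <- function(detections, red_threshold, green_threshold) {
  stopifnot(red_threshold > 0, green_threshold > 0)
  r <- detections$mean_red > red_threshold
  g <- detections$mean_green > green_threshold
  ifelse(r & g, "yellow", ifelse(r, "G1", ifelse(g, "SG2", "unknown")))
}

#' Default snapshot thresholds: 50% of the per-movie 99th-percentile intensity
#'
#' @param detections data.frame with mean_red, mean_green over a whole movie.
#' @return list with red and green thresholds.
#' @export
snapshot_thresholds <- function(detections) {
  list(red = 0.5 * quantile(detections$mean_red, 0.99, names = FALSE),
       green = 0.5 * quantile(detections$mean_green, 0.99, names = FALSE))
}

#' Exclude yellow (early-S overlap) entries from phase-stratified statistics
#'
#' @param x data.frame with a `phase` column.
#' @param yellow_labels labels to exclude.
#' @return list with `kept` (filtered data.frame) and `excluded` (count).
#' @export
exclude_yellow <- function(x, yellow_labels = c("yellow", "earlyS_overlap",
                                                "earlyS")) {
  drop <- x$phase %in% yellow_labels
  list(kept = x[!drop, , drop = FALSE], excluded = sum(drop))
}
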
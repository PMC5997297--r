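#' Association cost between two detections
#'
#' The cost combines differences in spatial location, size, and fluorescence
#' intensity, each normalized to be dimensionless, with configurable weights
#' (defaults 1:1:1). Pairs are gated (infinite cost) when the centroid
#' separation exceeds `gate_scale` times twice the maximum equivalent radius of
#' either cell, or when the area difference exceeds 90% of the larger area.
#'
#' @param a,b detection rows (lists/data.frame rows with frame, x_px, y_px,
#'   area_px, radius_px, mean_red, mean_green); `b` must be from a later frame.
#' @param gate_scale multiplier on the spatial gate (adaptive gating raises it).
#' @param weights numeric length-3: spatial, size, intensity weights.
#' @param size_gate maximum tolerated relative area difference (default 0.9).
#' @return list with spatial_term, size_term, intensity_term and total
#'   (Inf when gated).
#' @export
pair_cost <- function(a, b, gate_scale = 1, weights = c(1, 1, 1),
                      size_gate = 0.9) {
  if (a$frame == b$frame)
    stop("pair_cost: detections must come from different frames", call. = FALSE)
  d <- sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2)
  max_r <- max(a$radius_px, b$radius_px)
  max_area <- max(a$area_px, b$area_px)
  size_diff <- abs(a$area_px - b$area_px) / max_area
  spatial <- d / (a$radius_px + b$radius_px)
  inorm <- max(a$mean_red + a$mean_green, b$mean_red + b$mean_green,
               .Machine$double.eps)
  intensity <- (abs(a$mean_red - b$mean_red) +
                abs(a$mean_green - b$mean_green)) / inorm
  gated <- d > gate_scale * 2 * max_r || size_diff > size_gate
  total <- if (gated) Inf else
    weights[1] * spatial + weights[2] * size_diff + weights[3] * intensity
  list(spatial_term = spatial, size_term = size_diff,
       intensity_term = intensity, total = total)
}

# Vectorized costs from one head detection to a candidate frame of detections
head_costs <- function(head, cand, gate_scale = 1, weights = c(1, 1, 1),
                       size_gate = 0.9) {
  d <- sqrt((head$x_px - cand$x_px)^2 + (head$y_px - cand$y_px)^2)
  max_r <- pmax(head$radius_px, cand$radius_px)
  max_area <- pmax(head$area_px, cand$area_px)
  size_diff <- abs(head$area_px - cand$area_px) / max_area
  inorm <- pmax(head$mean_red + head$mean_green,
                cand$mean_red + cand$mean_green, .Machine$double.eps)
  total <- weights[1] * d / (head$radius_px + cand$radius_px) +
    weights[2] * size_diff +
    weights[3] * (abs(head$mean_red - cand$mean_red) +
                  abs(head$mean_green - cand$mean_green)) / inorm
  total[d > gate_scale * 2 * max_r | size_diff > size_gate] <- Inf
  total
}

#' Adaptive spatial gate expansion
#'
#' Starting from `base_gate`, the spatial gate is multiplied by `expand` until
#' at least `min_matches` candidate pairs have finite cost, or the whole
#' candidate pool is within spatial reach (size-gated pairs remain infinite).
#'
#' @param head a detection row (the open track head).
#' @param candidates data.frame of candidate detections (may be empty).
#' @param base_gate starting gate scale (default 1).
#' @param expand multiplicative growth per iteration (default 1.5).
#' @param min_matches target number of finite-cost candidates (default 5).
#' @param weights passed to the cost function.
#' @return the final gate scale.
#' @export
adaptive_gate <- function(head, candidates, base_gate = 1, expand = 1.5,
                          min_matches = 5, weights = c(1, 1, 1)) {
  if (is.null(candidates) || nrow(candidates) == 0) return(base_gate)
  d <- sqrt((head$x_px - candidates$x_px)^2 + (head$y_px - candidates$y_px)^2)
  max_r <- pmax(head$radius_px, candidates$radius_px)
  scale <- base_gate
  repeat {
    finite <- sum(is.finite(head_costs(head, candidates, scale, weights)))
    all_reached <- all(d <= scale * 2 * max_r)
    if (finite >= min_matches || all_reached) return(scale)
    scale <- scale * expand
  }
}

#' Associate detections across frames into tracks
#'
#' Cost-gated association over a sliding window of `window` frames: open track
#' heads from the previous `window - 1` frames compete for the detections of
#' the current frame, and the minimum-total-cost maximum-cardinality bipartite
#' matching between heads and detections is committed (solved exactly per
#' step), so each head and detection is used at most once. A link spanning a
#' skipped frame (occlusion) has its cost multiplied by `skip_penalty` per
#' skipped frame. Unmatched detections open new tracks; tracks unmatched for
#' `window` or more frames are closed. The spatial gate is adapted per head
#' via [adaptive_gate()].
#'
#' @param detections data.frame of detections over all frames (as produced by
#'   [detect_cells()]), with a `frame` column.
#' @param window association window in frames (default 3).
#' @param weights cost weights (spatial, size, intensity).
#' @param skip_penalty cost multiplier per skipped frame (default 1.25).
#' @return data.frame of tracked detections: track_id plus all detection
#'   columns, ordered by track then frame. Attributes `total_cost` and
#'   `n_links` record the summed cost (including skip penalties) and number of
#'   committed links.
#' @export
associate <- function(detections, window = 3, weights = c(1, 1, 1),
                      skip_penalty = 1.25) {
  if (nrow(detections) == 0)
    return(cbind(track_id = integer(), detections))
  detections <- detections[order(detections$frame, detections$label_id), ,
                           drop = FALSE]
  frames <- sort(unique(detections$frame))
  # track state
  track_rows <- list()   # per track: integer row indices into `detections`
  head_frame <- integer(0)
  open <- logical(0)
  det_frame <- detections$frame

  total_cost <- 0
  n_links <- 0L

  new_track <- function(ri) {
    track_rows[[length(track_rows) + 1]] <<- ri
    head_frame[length(head_frame) + 1] <<- det_frame[ri]
    open[length(open) + 1] <<- TRUE
  }
  first_frame_rows <- which(det_frame == frames[1])
  for (ri in first_frame_rows) new_track(ri)

  for (t in frames[-1]) {
    cand_rows <- which(det_frame == t)
    cand <- detections[cand_rows, , drop = FALSE]
    heads <- which(open & head_frame >= t - (window - 1) & head_frame < t)
    if (length(heads) && nrow(cand)) {
      # cost matrix heads x candidates
      cost <- matrix(Inf, length(heads), nrow(cand))
      for (hi in seq_along(heads)) {
        hrow <- detections[track_rows[[heads[hi]]][
          length(track_rows[[heads[hi]]])], , drop = FALSE]
        gs <- adaptive_gate(hrow, cand, weights = weights)
        cc <- head_costs(hrow, cand, gs, weights)
        gap <- t - head_frame[heads[hi]] - 1
        cost[hi, ] <- cc * skip_penalty^gap
      }
      mt <- min_cost_matching(cost)
      used_c <- rep(FALSE, nrow(cand))
      for (hi in seq_along(mt)) {
        cj <- mt[hi]
        if (is.na(cj)) next
        tr <- heads[hi]
        total_cost <- total_cost + cost[hi, cj]
        n_links <- n_links + 1L
        track_rows[[tr]] <- c(track_rows[[tr]], cand_rows[cj])
        head_frame[tr] <- t
        used_c[cj] <- TRUE
      }
      for (cj in which(!used_c)) new_track(cand_rows[cj])
    } else {
      for (ri in cand_rows) new_track(ri)
    }
    open[open & head_frame <= t - window] <- FALSE
  }

  ids <- rep(seq_along(track_rows), lengths(track_rows))
  rows <- unlist(track_rows)
  out <- cbind(track_id = ids, detections[rows, , drop = FALSE])
  rownames(out) <- NULL
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  attr(out, "total_cost") <- total_cost
  attr(out, "n_links") <- n_links
  out
}

# Exact minimum-cost maximum-cardinality matching on a (possibly Inf-gated)
# cost matrix (rows: heads, cols: candidate detections). Cardinality takes
# priority: matching one more pair always beats any cost saving. Solved as a
# maximum-weight bipartite matching with weights M - cost, M above the total
# finite cost. Returns, per row, the matched column index or NA.
min_cost_matching <- function(cost) {
  nh <- nrow(cost); nc <- ncol(cost)
  fin <- which(is.finite(cost), arr.ind = TRUE)
  if (!nrow(fin)) return(rep(NA_integer_, nh))
  M <- sum(cost[fin]) + 1
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nh), rep(TRUE, nc)),
                                    edges = as.vector(t(cbind(fin[, 1],
                                                              nh + fin[, 2]))))
  w <- M - cost[fin]
  mm <- igraph::max_bipartite_match(g, weights = w)
  match_vec <- mm$matching[seq_len(nh)]
  out <- rep(NA_integer_, nh)
  ok <- !is.na(match_vec) & match_vec > nh
  out[ok] <- as.integer(match_vec[ok]) - nh
  out
}

#' Tracking quality against ground truth
#'
#' Matches each tracked detection to its nearest ground-truth cell within
#' `max_dist_um` and reports identity switches (frame-to-frame links whose
#' ground-truth identity changes) and per-track purity (largest fraction of a
#' track's detections explained by a single ground-truth cell).
#'
#' @param tracks data.frame from [associate()] with x_um, y_um, frame.
#' @param truth ground-truth data.frame (cell_id, frame, x_um, y_um).
#' @param max_dist_um matching distance cutoff in microns.
#' @return list with `switches` (count), `purity` (per-track named vector) and
#'   `mean_purity`.
#' @export
link_quality <- function(tracks, truth, max_dist_um = 10) {
  gt_id <- integer(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    cand <- truth[truth$frame == tracks$frame[i], , drop = FALSE]
    if (!nrow(cand)) { gt_id[i] <- NA_integer_; next }
    d <- sqrt((cand$x_um - tracks$x_um[i])^2 + (cand$y_um - tracks$y_um[i])^2)
    j <- which.min(d)
    gt_id[i] <- if (d[j] <= max_dist_um) cand$cell_id[j] else NA_integer_
  }
  switches <- 0L
  purity <- c()
  for (tid in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == tid)
    ids <- gt_id[sel][order(tracks$frame[sel])]
    ok <- !is.na(ids)
    if (sum(ok) >= 2) {
      runs <- ids[ok]
      switches <- switches + sum(runs[-1] != runs[-length(runs)])
    }
    purity[as.character(tid)] <- if (any(ok))
      max(table(ids[ok])) / sum(ok) else NA_real_
  }
  list(switches = switches, purity = purity,
       mean_purity = mean(purity, na.rm = TRUE))
}
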
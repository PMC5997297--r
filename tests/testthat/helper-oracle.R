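# Independent oracles used across the suite.

# Exhaustive data-association oracle: enumerates every feasible link set over
# the association window (links span <= window-1 frames, each detection has at
# most one incoming and one outgoing link, a skipped frame multiplies the link
# cost by skip_penalty) and returns the lexicographic optimum: maximum number
# of links, then minimum total cost. Spatial gating is fully relaxed (the
# adaptive gate expands until the pool is reachable on such small pools); the
# 90% size gate still applies. Intended for tiny instances only.
oracle_associate <- function(detections, window = 3, skip_penalty = 1.25) {
  det <- detections[order(detections$frame, detections$label_id), ,
                    drop = FALSE]
  n <- nrow(det)
  frames <- sort(unique(det$frame))
  rows_by_frame <- lapply(frames, function(f) which(det$frame == f))
  future_dets <- rev(cumsum(rev(lengths(rows_by_frame))))

  # precompute all pairwise edge costs (rows: earlier, cols: later)
  ec <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    df <- det$frame[j] - det$frame[i]
    if (df < 1 || df > window - 1) next
    pc <- fuccitrack::pair_cost(det[i, ], det[j, ], gate_scale = Inf)
    ec[i, j] <- pc$total * skip_penalty^(df - 1)
  }

  best_links <- -1L
  best_cost <- Inf

  recurse <- function(t_idx, heads, links, cost) {
    ub <- links + (if (t_idx <= length(frames)) future_dets[t_idx] else 0L)
    if (ub < best_links || (ub == best_links && cost >= best_cost)) return()
    if (t_idx > length(frames)) {
      if (links > best_links ||
          (links == best_links && cost < best_cost - 1e-12)) {
        best_links <<- links
        best_cost <<- cost
      }
      return()
    }
    t <- frames[t_idx]
    cand <- rows_by_frame[[t_idx]]
    eligible <- heads[det$frame[heads] >= t - (window - 1)]

    enum <- function(ci, avail, add_links, add_cost, matched) {
      if (ci > length(cand)) {
        new_heads <- c(if (length(matched)) heads[!(heads %in% matched)]
                       else heads, cand)
        recurse(t_idx + 1, new_heads, links + add_links, cost + add_cost)
        return()
      }
      # cheapest matches first so good solutions are found early (pruning)
      es <- ec[avail, cand[ci]]
      for (h in avail[order(es)][is.finite(sort(es))])
        enum(ci + 1, avail[avail != h], add_links + 1L,
             add_cost + ec[h, cand[ci]], c(matched, h))
      enum(ci + 1, avail, add_links, add_cost, matched)  # new track
    }
    enum(1, eligible, 0L, 0, integer(0))
  }
  recurse(1, integer(0), 0L, 0)
  list(links = best_links, cost = best_cost)
}

# Small generator-realistic tracking instance: ground-truth positions from the
# persistent-random-walk generator, detection features with mild measurement
# noise (no rendering).
random_small_instance <- function(seed, n_cells = NULL, n_frames = NULL) {
  set.seed(seed)
  if (is.null(n_cells)) n_cells <- sample(2:4, 1)
  if (is.null(n_frames)) n_frames <- sample(3:5, 1)
  cfg <- fuccitrack::scene_config(n_cells = n_cells, n_frames = n_frames,
                                  image_shape = c(256L, 256L), seed = seed)
  gt <- fuccitrack::simulate_trajectories(cfg)
  tr <- gt$truth
  set.seed(seed + 13)
  n <- nrow(tr)
  area <- 130 * (1 + 0.05 * rnorm(n))
  data.frame(frame = tr$frame,
             label_id = stats::ave(tr$frame, tr$frame, FUN = seq_along),
             x_px = tr$x_um / cfg$pixel_size + 0.3 * rnorm(n),
             y_px = tr$y_um / cfg$pixel_size + 0.3 * rnorm(n),
             area_px = area, radius_px = sqrt(area / pi),
             mean_red = pmax(tr$red + 10 * rnorm(n), 0),
             mean_green = pmax(tr$green + 10 * rnorm(n), 0))
}

# Closed-form steady profile of the 1D source-Dirichlet / sink-Robin problem
oracle_robin_profile <- function(x_um, L, C0, D_um, k) {
  if (!is.finite(k)) return(C0 * (1 - x_um / L))
  C0 * (1 - x_um / (L + D_um / k))
}
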
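# Build a noisy measured trace straight from the generator's FUCCI clock.
# `snr` is the per-pixel image signal-to-noise; the measured mean fluorescence
# averages ~130 segmented pixels, so trace noise is snr * sqrt(130).
noisy_trace <- function(cfg, offset, snr = 10, n_px = 130, seed = 1) {
  set.seed(seed)
  t_min <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  cyc <- ((t_min / 60) + offset * (cfg$t_G1 + cfg$t_overlap + cfg$t_SG2)) %%
    (cfg$t_G1 + cfg$t_overlap + cfg$t_SG2)
  tr <- fucci_trace(rep("G1", cfg$n_frames), cfg, cycle_time = cyc)
  noise_sd <- cfg$intensity_peak / (snr * sqrt(n_px))
  data.frame(frame = seq_len(cfg$n_frames),
             mean_red = pmax(tr$red + rnorm(cfg$n_frames, 0, noise_sd), 0),
             mean_green = pmax(tr$green + rnorm(cfg$n_frames, 0, noise_sd), 0),
             true_red = tr$red, true_green = tr$green,
             true_phase = fuccitrack:::cycle_phase(cyc, cfg))
}

test_that("constant red track is all G1 with no switch", {
  track <- data.frame(frame = 1:10, mean_red = rep(800, 10),
                      mean_green = rep(0, 10))
  pt <- classify_longitudinal(track)
  expect_true(all(pt$phase == "G1"))
  expect_true(is.na(pt$switch_frame))
  # all-zero red: unknown with a warning
  track0 <- data.frame(frame = 1:6, mean_red = 0, mean_green = 0)
  expect_warning(pt0 <- classify_longitudinal(track0), "all-zero")
  expect_true(all(pt0$phase == "unknown"))
  expect_error(classify_longitudinal(track[1:3, ]), "shorter")
})

test_that("switch frame lands within one frame of the ramp midpoint on high-SNR traces", {
  # The 50%-of-max-red rule fires at the overlap ramp midpoint, so the oracle
  # switch frame is the first frame whose true red drops below half peak.
  cfg <- scene_config(n_cells = 1, n_frames = 120, seed = 1)
  hits <- 0; total <- 0
  for (i in 1:40) {
    offset <- (i - 0.5) / 40 * 0.5  # start somewhere in G1/overlap
    tr <- noisy_trace(cfg, offset, snr = 10, seed = i)
    true_sw <- which(tr$true_red < 0.5 * cfg$intensity_peak)[1]
    if (is.na(true_sw) || true_sw < 2) next
    pt <- classify_longitudinal(tr)
    total <- total + 1
    if (!is.na(pt$switch_frame) && abs(pt$switch_frame - true_sw) <= 1)
      hits <- hits + 1
  }
  expect_gte(total, 20)
  expect_gte(hits / total, 0.95)
})

test_that("the early-S overlap marking matches the 2 h window", {
  cfg <- scene_config(n_cells = 1, n_frames = 120, seed = 1)
  tr <- noisy_trace(cfg, offset = 0.42, snr = 50, seed = 3)
  pt <- classify_longitudinal(tr)
  # 2 h overlap at 10 min/frame: at most 12 overlap frames
  expect_lte(sum(pt$phase == "earlyS_overlap"), 12)
  # overlap frames must sit at the G1 -> SG2 boundary
  ov <- which(pt$phase == "earlyS_overlap")
  if (length(ov)) expect_true(all(diff(ov) == 1))
})

test_that("phase labels are invariant to common intensity scaling", {
  cfg <- scene_config(n_cells = 1, n_frames = 80, seed = 2)
  tr <- noisy_trace(cfg, offset = 0.4, snr = 20, seed = 5)
  pt1 <- classify_longitudinal(tr)
  tr2 <- tr
  tr2$mean_red <- tr$mean_red * 7.3
  tr2$mean_green <- tr$mean_green * 7.3
  pt2 <- classify_longitudinal(tr2)
  expect_identical(pt1$phase, pt2$phase)
  expect_identical(pt1$switch_frame, pt2$switch_frame)
})

test_that("snapshot classification separates G1, S/G2 and yellow", {
  det <- data.frame(mean_red = c(900, 10, 900, 10),
                    mean_green = c(10, 900, 900, 10))
  ph <- classify_snapshot(det, red_threshold = 100, green_threshold = 100)
  expect_identical(ph, c("G1", "SG2", "yellow", "unknown"))
  expect_error(classify_snapshot(det, -1, 100))
})

test_that("yellow cells are under 10% of an asynchronous population and are excluded", {
  # Under the linear red/green crossfade both channels exceed a detectability
  # threshold thr only for overlap fractions in (thr/peak, 1 - thr/peak), so
  # with thr = 10% of peak the expected yellow fraction is 80% of the overlap
  # occupancy: 0.8 * 2 h / 22 h.
  cfg <- scene_config(n_cells = 400, n_frames = 1, seed = 31)
  gt <- simulate_trajectories(cfg)
  det <- data.frame(mean_red = gt$truth$red, mean_green = gt$truth$green)
  thr <- 0.1 * cfg$intensity_peak
  ph <- classify_snapshot(det, thr, thr)
  classified <- ph != "unknown"
  yellow_frac <- sum(ph == "yellow") / sum(classified)
  expect_lt(yellow_frac, 0.10)

  # exclusion bookkeeping
  ex <- exclude_yellow(data.frame(phase = ph))
  expect_identical(ex$excluded, sum(ph == "yellow"))
  expect_false(any(ex$kept$phase == "yellow"))
  # no yellow: identity; all yellow: empty
  ex0 <- exclude_yellow(data.frame(phase = c("G1", "SG2")))
  expect_identical(ex0$excluded, 0L)
  expect_identical(nrow(ex0$kept), 2L)
  ex1 <- exclude_yellow(data.frame(phase = rep("yellow", 4)))
  expect_identical(ex1$excluded, 4L)
  expect_identical(nrow(ex1$kept), 0L)

  # excluded fraction matches the generator-derived occupancy (binomial CI)
  occ <- (1 - 2 * thr / cfg$intensity_peak) *
    cfg$t_overlap / (cfg$t_G1 + cfg$t_overlap + cfg$t_SG2)
  n <- sum(classified)
  expect_lt(abs(yellow_frac - occ), 1.96 * sqrt(occ * (1 - occ) / n) + 0.005)
})
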
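test_that("noise-free walkers are perfectly straight and zero-speed walkers are static", {
  cfg <- scene_config(n_cells = 3, n_frames = 20, heading_noise_G1 = 0,
                      heading_noise_SG2 = 0, speed_G1 = 0.3, speed_SG2 = 0.3,
                      image_shape = c(512L, 512L), seed = 3)
  gt <- simulate_trajectories(cfg)
  for (tr in split(gt$truth, gt$truth$cell_id))
    expect_equal(persistence(tr), 1, tolerance = 1e-12)

  cfg0 <- scene_config(n_cells = 3, n_frames = 15, speed_G1 = 0,
                       speed_SG2 = 0, seed = 3)
  gt0 <- simulate_trajectories(cfg0)
  for (tr in split(gt0$truth, gt0$truth$cell_id)) {
    expect_true(all(tr$x_um == tr$x_um[1]))
    expect_equal(instantaneous_velocity(tr), rep(0, nrow(tr) - 1))
  }
})

test_that("configured G1:S/G2 speed ratio shows up in ground-truth step displacements", {
  cfg <- scene_config(n_cells = 50, n_frames = 120, speed_G1 = 0.6,
                      speed_SG2 = 0.5, seed = 101)
  gt <- simulate_trajectories(cfg)
  step_by_phase <- function(truth) {
    g1 <- c(); sg2 <- c()
    for (tr in split(truth, truth$cell_id)) {
      tr <- tr[order(tr$frame), ]
      d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
      ph <- tr$phase[-nrow(tr)]
      g1 <- c(g1, d[ph == "G1"]); sg2 <- c(sg2, d[ph == "SG2"])
    }
    list(g1 = g1, sg2 = sg2)
  }
  s <- step_by_phase(gt$truth)
  ratio <- mean(s$g1) / mean(s$sg2)
  # bootstrap 95% CI over steps must cover the configured 1.2
  set.seed(1)
  boot <- replicate(500, mean(sample(s$g1, replace = TRUE)) /
                         mean(sample(s$sg2, replace = TRUE)))
  ci <- quantile(boot, c(0.025, 0.975))
  expect_gt(1.2, ci[1])
  expect_lt(1.2, ci[2])
  expect_equal(ratio, 1.2, tolerance = 0.05)
})

test_that("mean step length matches speed x interval within 3 standard errors", {
  # slow walkers so no trajectory ever reaches a reflecting field edge
  # (reflection shortens the apparent step and would bias the estimate)
  cfg <- scene_config(n_cells = 10, n_frames = 1001, speed_G1 = 0.05,
                      speed_SG2 = 0.05, heading_noise_G1 = 2,
                      heading_noise_SG2 = 2, seed = 7)
  gt <- simulate_trajectories(cfg)
  steps <- unlist(lapply(split(gt$truth, gt$truth$cell_id), function(tr)
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)))
  expect_gte(length(steps), 1e4)
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - 0.05 * 10), 3 * se)
})

test_that("channel-mode cells respect the wall constraint", {
  cfg <- scene_config(n_cells = 12, n_frames = 200, mode = "channel",
                      seed = 5)
  gt <- simulate_trajectories(cfg)
  centers <- fuccitrack:::channel_centerlines(cfg)
  dist_to_center <- vapply(gt$truth$y_um,
                           function(y) min(abs(y - centers)), 0)
  expect_true(all(dist_to_center <= cfg$channel_width / 2 + 1e-9))
})

test_that("FUCCI traces follow the red-to-green handoff", {
  cfg <- scene_config(seed = 1)
  # all-G1: red constant at peak, green zero
  tr <- fucci_trace(rep("G1", 10), cfg)
  expect_equal(tr$red, rep(cfg$intensity_peak, 10))
  expect_equal(tr$green, rep(0, 10))
  # midpoint of the overlap window: both at half peak (clock-based)
  mid <- fucci_trace("earlyS", cfg, cycle_time = cfg$t_G1 + cfg$t_overlap / 2)
  expect_equal(mid$red, cfg$intensity_peak / 2)
  expect_equal(mid$green, cfg$intensity_peak / 2)
  # 2 h overlap at 10 min/frame: exactly 12 frames with both signals nonzero
  labels <- c(rep("G1", 5), rep("earlyS", 12), rep("SG2", 5))
  tr2 <- fucci_trace(labels, cfg)
  expect_identical(sum(tr2$red > 0 & tr2$green > 0), 12L)
  # both channels above half max only inside the overlap
  both_hi <- tr2$red > 0.5 * max(tr2$red) & tr2$green > 0.5 * max(tr2$green)
  expect_true(all(which(both_hi) %in% 6:17))
})

test_that("simulation and rendering are bit-identical under a fixed seed", {
  cfg <- scene_config(n_cells = 4, n_frames = 5, image_shape = c(128L, 128L),
                      seed = 99)
  gt1 <- simulate_trajectories(cfg); gt2 <- simulate_trajectories(cfg)
  expect_identical(gt1$truth, gt2$truth)
  mv1 <- render_movie(gt1); mv2 <- render_movie(gt2)
  expect_identical(mv1$red, mv2$red)
  expect_identical(mv1$trans, mv2$trans)
})

test_that("rendering degenerate scenes behaves as specified", {
  cfg <- scene_config(n_cells = 0, n_frames = 3, image_shape = c(64L, 64L),
                      background_amplitude = 0, shot_noise_scale = 0, seed = 1)
  mv <- render_movie(simulate_trajectories(cfg))
  expect_true(all(mv$red == 0))
  expect_true(all(mv$green == 0))

  # one stationary cell, zero noise: red argmax at the rounded centroid
  gt <- grid_scene(n_cells = 1, n_frames = 1, image_px = 64L)
  mv1 <- render_movie(gt, gt$config)
  fr <- mv1$red[, , 1]
  am <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(am["row"]) - 1, gt$truth$y_um[1] / gt$config$pixel_size,
               tolerance = 0.51)
  expect_equal(unname(am["col"]) - 1, gt$truth$x_um[1] / gt$config$pixel_size,
               tolerance = 0.51)

  expect_error(render_movie(simulate_trajectories(
    scene_config(n_cells = 1, n_frames = 1, image_shape = c(16L, 16L),
                 blob_radius = 4, seed = 1))), "too small")
})

test_that("scene_config rejects invalid parameterizations", {
  expect_error(scene_config(speed_G1 = -1), "non-negative")
  expect_error(scene_config(frame_interval = 0), "strictly positive")
  expect_error(scene_config(chemotaxis_bias = 1.5), "\\[0, 1\\]")
  expect_error(scene_config(channel_width = 1, pixel_size = 0.65), ">= 4")
  expect_error(scene_config(cycle_phase_offsets = c(0.5), n_cells = 2),
               "cycle_phase_offsets")
})

test_that("fiber image generator honors the angle distribution", {
  # near-degenerate gaussian: all angles at 90
  f <- simulate_fiber_image(50, "gaussian", mu = 90, sigma = 1e-9,
                            image_shape = c(64L, 64L), seed = 2)
  expect_true(all(abs(f$angles - 90) < 1e-6))
  # uniform angles: resultant of doubled angles near zero
  f2 <- simulate_fiber_image(1e4, "uniform", image_shape = c(32L, 32L),
                             seed = 3)
  th <- 2 * f2$angles * pi / 180
  r_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(r_bar, 3 / sqrt(1e4))
  # determinism
  f3 <- simulate_fiber_image(20, "uniform", image_shape = c(64L, 64L), seed = 3)
  f4 <- simulate_fiber_image(20, "uniform", image_shape = c(64L, 64L), seed = 3)
  expect_identical(f3$image, f4$image)
  expect_identical(f3$angles, f4$angles)
})
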
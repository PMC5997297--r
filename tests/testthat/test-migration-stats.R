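test_that("instantaneous velocity is displacement over elapsed time", {
  still <- toy_track(rep(3, 5), rep(4, 5))
  expect_equal(instantaneous_velocity(still), rep(0, 4))
  # 6 um per 10 min frame: 0.6 um/min
  tr <- toy_track(seq(0, 30, 6), rep(0, 6))
  expect_equal(instantaneous_velocity(tr), rep(0.6, 5))
  # occlusion gap: actual elapsed time is used
  gap <- toy_track(c(0, 6, 18), c(0, 0, 0), frame = c(1, 2, 4))
  expect_equal(instantaneous_velocity(gap), c(0.6, 0.6))
  expect_identical(length(instantaneous_velocity(tr[1, ])), 0L)
})

test_that("persistence is net over path, in [0, 1], with exact limits", {
  expect_equal(persistence(toy_track(seq(0, 50, 10), seq(0, 25, 5))), 1)
  loop <- toy_track(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(persistence(loop), 0)
  expect_warning(p <- persistence(toy_track(c(1, 1), c(2, 2))), "zero path")
  expect_true(is.na(p))
  expect_error(persistence(toy_track(1, 1)), "at least 2")
})

test_that("persistence and velocity are invariant to rigid motions", {
  set.seed(5)
  tr <- toy_track(cumsum(rnorm(20)), cumsum(rnorm(20)))
  th <- 0.7
  rot <- toy_track(cos(th) * tr$x_um - sin(th) * tr$y_um + 12,
                   sin(th) * tr$x_um + cos(th) * tr$y_um - 5)
  expect_equal(persistence(rot), persistence(tr))
  expect_equal(instantaneous_velocity(rot), instantaneous_velocity(tr))
})

test_that("persistence stays in [0, 1] and decreases with heading noise", {
  means <- vapply(c(0.1, 0.5, 1.0, 2.0), function(sig) {
    cfg <- scene_config(n_cells = 30, n_frames = 60, heading_noise_G1 = sig,
                        heading_noise_SG2 = sig, image_shape = c(2048L, 2048L),
                        seed = 11)
    gt <- simulate_trajectories(cfg)
    ps <- vapply(split(gt$truth, gt$truth$cell_id), persistence, 0)
    expect_true(all(ps >= 0 & ps <= 1 + 1e-12))
    mean(ps)
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("per-cell ratios recover symmetric and asymmetric motility", {
  # identical G1/SG2 motility: median ratio compatible with 1
  cfg <- scene_config(n_cells = 60, n_frames = 120, speed_G1 = 0.5,
                      speed_SG2 = 0.5, seed = 19)
  gt <- simulate_trajectories(cfg)
  ratios <- c()
  for (tr in split(gt$truth, gt$truth$cell_id)) {
    rr <- per_cell_ratios(tr, tr$phase)
    if (!is.null(rr)) ratios <- c(ratios, rr$velocity_ratio_G1_over_SG2)
  }
  expect_gte(length(ratios), 20)
  set.seed(2)
  boot <- replicate(400, median(sample(ratios, replace = TRUE)))
  ci <- quantile(boot, c(0.025, 0.975))
  expect_true(ci[1] <= 1 && 1 <= ci[2])

  # 1.2x G1 speed: median ratio CI brackets 1.2
  cfg2 <- scene_config(n_cells = 60, n_frames = 120, speed_G1 = 0.6,
                       speed_SG2 = 0.5, seed = 23)
  gt2 <- simulate_trajectories(cfg2)
  ratios2 <- c()
  for (tr in split(gt2$truth, gt2$truth$cell_id)) {
    rr <- per_cell_ratios(tr, tr$phase)
    if (!is.null(rr)) ratios2 <- c(ratios2, rr$velocity_ratio_G1_over_SG2)
  }
  boot2 <- replicate(400, median(sample(ratios2, replace = TRUE)))
  ci2 <- quantile(boot2, c(0.025, 0.975))
  expect_true(ci2[1] <= 1.2 && 1.2 <= ci2[2])

  # a track with no SG2 frames yields no ratio record
  tr_g1 <- toy_track(seq(0, 90, 10), rep(0, 10))
  expect_null(per_cell_ratios(tr_g1, rep("G1", 10)))
})

test_that("channel entry filter clips tracks at the taper", {
  inside <- toy_track(seq(200, 290, 10), rep(0, 10))
  expect_identical(channel_entry_filter(inside, 150), inside)
  outside <- toy_track(seq(0, 90, 10), rep(0, 10))
  expect_null(channel_entry_filter(outside, 150))
  crossing <- toy_track(seq(100, 190, 10), rep(0, 10))
  out <- channel_entry_filter(crossing, 150)
  expect_identical(out$frame[1], 6L)
  expect_true(all(out$x_um >= 150))
})

test_that("group comparison reproduces the pooled-variance t-test", {
  x <- c(1, 2, 3)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_groups(1, x), "n >= 2")
  same <- compare_groups(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # closed form: pooled t with 8 df
  cmp <- compare_groups(1:5, 2:6)
  expect_equal(cmp$t, -1)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(round(cmp$p, 4), 0.3466)
  expect_identical(cmp$stars, "ns")
  expect_equal(cmp$sem_a, sd(1:5) / sqrt(5))
  expect_identical(significance_stars(0.004), "**")
  expect_identical(significance_stars(0.04), "*")
  expect_identical(significance_stars(5e-4), "***")
})
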
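test_that("denoise removes constant background and isolated spikes", {
  expect_lt(max(denoise(matrix(7, 32, 32))), 1e-9)
  spike <- matrix(0, 64, 64); spike[30, 30] <- 1000
  out <- denoise(spike)
  expect_lt(max(out), 10)  # < 1% of the spike survives
  expect_error(denoise(matrix(0, 5, 5)), "10x10")
})

test_that("denoise raises blob signal relative to background on noisy frames", {
  gt <- grid_scene(n_cells = 2, n_frames = 1, noise = TRUE)
  mv <- render_movie(gt, gt$config)
  raw <- mv$red[, , 1]
  dn <- denoise(raw)
  px <- round(gt$truth$x_um / gt$config$pixel_size) + 1
  py <- round(gt$truth$y_um / gt$config$pixel_size) + 1
  blob_idx <- cbind(py, px)
  off <- cbind(py + 60, px)  # background sample away from both blobs
  snr <- function(img) mean(img[blob_idx]) / (sd(img[off]) + mean(img[off]) + 1)
  expect_gt(snr(dn), snr(raw))
})

test_that("fluorescence segmentation finds isolated blobs with 1 px centroids", {
  gt <- grid_scene(n_cells = 1, n_frames = 1)
  mv <- render_movie(gt, gt$config)
  lab <- segment_fluorescence(denoise(mv$red[, , 1]), denoise(mv$green[, , 1]))
  expect_identical(max(lab), 1L)
  d <- fuccitrack:::measure_detections(lab, mv$red[, , 1], mv$green[, , 1],
                                       1L, gt$config$pixel_size)
  expect_lt(abs(d$x_px - gt$truth$x_um[1] / gt$config$pixel_size), 1)
  expect_lt(abs(d$y_px - gt$truth$y_um[1] / gt$config$pixel_size), 1)

  # all-zero frame: empty mask, no error
  z <- matrix(0, 64, 64)
  expect_identical(max(segment_fluorescence(z, z)), 0L)

  # two blobs far apart: exactly two components
  gt2 <- grid_scene(n_cells = 2, n_frames = 1)
  sep <- dist(gt2$truth[, c("x_um", "y_um")])[1]
  expect_gt(sep, 4 * gt2$config$blob_radius)
  mv2 <- render_movie(gt2, gt2$config)
  lab2 <- segment_fluorescence(denoise(mv2$red[, , 1]),
                               denoise(mv2$green[, , 1]))
  expect_identical(max(lab2), 2L)
})

test_that("segmentation is invariant to common intensity scaling", {
  gt <- grid_scene(n_cells = 3, n_frames = 1, noise = TRUE)
  mv <- render_movie(gt, gt$config)
  r <- mv$red[, , 1]; g <- mv$green[, , 1]
  m1 <- segment_fluorescence(denoise(r), denoise(g)) > 0
  m2 <- segment_fluorescence(denoise(5 * r), denoise(5 * g)) > 0
  expect_lt(mean(m1 != m2), 0.01)
})

test_that("transmitted-light segmentation covers cell bodies", {
  expect_false(any(segment_phase(matrix(128, 64, 64))))
  gt <- grid_scene(n_cells = 2, n_frames = 1)
  mv <- render_movie(gt, gt$config)
  pm <- segment_phase(mv$trans[, , 1])
  # ground-truth cell pixels: within the rendered body/rim radius
  sig <- gt$config$blob_radius / gt$config$pixel_size
  h <- nrow(pm); w <- ncol(pm)
  cell_px <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(gt$truth))) {
    cx <- gt$truth$x_um[i] / gt$config$pixel_size
    cy <- gt$truth$y_um[i] / gt$config$pixel_size
    d2 <- outer((seq_len(h) - 1 - cy)^2, (seq_len(w) - 1 - cx)^2, `+`)
    cell_px <- cell_px | (d2 < (1.5 * sig)^2)
  }
  expect_gte(sum(pm & cell_px) / sum(cell_px), 0.9)
})

test_that("intensity-deviation rule flags the expected fraction of pure noise", {
  set.seed(8)
  img <- matrix(rnorm(256 * 256), 256, 256)
  m <- segment_phase(img, gradient_union = FALSE, fill_holes = FALSE)
  expect_equal(mean(m), 2 * pnorm(-1), tolerance = 0.02 / (2 * pnorm(-1)))
})

test_that("phase-mask intersection follows the majority-retention rule", {
  gt <- grid_scene(n_cells = 2, n_frames = 1)
  mv <- render_movie(gt, gt$config)
  r <- mv$red[, , 1]; g <- mv$green[, , 1]
  fl <- segment_fluorescence(denoise(r), denoise(g))
  all_mask <- matrix(TRUE, nrow(fl), ncol(fl))
  res_all <- combine_segmentations(fl, all_mask, r, g, 1L,
                                   gt$config$pixel_size)
  expect_identical(res_all$labels, fl)
  res_none <- combine_segmentations(fl, !all_mask, r, g, 1L,
                                    gt$config$pixel_size)
  expect_identical(nrow(res_none$detections), 0L)
  # removing just under half of a component keeps it
  half_mask <- all_mask
  ids <- which(fl == 1)
  half_mask[ids[seq_len(floor(0.4 * length(ids)))]] <- FALSE
  res_half <- combine_segmentations(fl, half_mask, r, g, 1L,
                                    gt$config$pixel_size)
  expect_identical(nrow(res_half$detections), 2L)
})

test_that("detection recall and precision are perfect on rendered scenes", {
  gt <- grid_scene(n_cells = 10, n_frames = 1, image_px = 384L, noise = TRUE)
  mv <- render_movie(gt, gt$config)
  det <- detect_cells(mv)$detections
  truth <- gt$truth[gt$truth$frame == 1, ]
  # match detections to truth within 3 px
  used <- rep(FALSE, nrow(truth)); tp <- 0L
  for (i in seq_len(nrow(det))) {
    d <- sqrt((truth$x_um / gt$config$pixel_size - det$x_px[i])^2 +
              (truth$y_um / gt$config$pixel_size - det$y_px[i])^2)
    j <- which.min(ifelse(used, Inf, d))
    if (d[j] <= 3) { tp <- tp + 1L; used[j] <- TRUE }
  }
  expect_identical(tp, nrow(truth))   # recall 1
  expect_identical(tp, nrow(det))     # precision 1
})

test_that("detections never overlap and respect the minimum size", {
  gt <- grid_scene(n_cells = 5, n_frames = 2, noise = TRUE)
  mv <- render_movie(gt, gt$config)
  out <- detect_cells(mv)
  for (lab in out$labels) {
    if (max(lab) == 0) next
    sizes <- tabulate(lab)
    expect_true(all(sizes >= 30))
    expect_identical(sort(unique(as.vector(lab[lab > 0]))),
                     seq_len(max(lab)))
  }
  d <- out$detections
  expect_true(all(abs(d$radius_px - sqrt(d$area_px / pi)) < 1e-9))
  expect_true(all(d$mean_red >= 0 & d$mean_green >= 0))
})
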
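#' Denoise a fluorescence frame
#'
#' Imaging noise is modelled as slow-varying low-frequency background plus
#' high-frequency shot noise. The shot noise is removed by a 3x3 median filter
#' and the background by subtracting a Gaussian low-pass estimate of the frame
#' (kernel size 10% of the smaller image dimension; the Gaussian sd is
#' kernel/6 so the kernel covers +/- 3 sd). Output is clipped at zero.
#'
#' @param image single-channel 2D matrix, at least 10 x 10 pixels.
#' @param kernel_frac low-pass kernel size as a fraction of min(dim).
#' @return denoised matrix, same shape.
#' @export
denoise <- function(image, kernel_frac = 0.1) {
  stopifnot(is.matrix(image))
  if (min(dim(image)) < 10)
    stop("denoise: image must be at least 10x10 pixels", call. = FALSE)
  med <- median3x3_cpp(image)
  sigma <- kernel_frac * min(dim(image)) / 6
  lp <- EBImage::gblur(image, sigma = sigma)
  pmax(med - lp, 0)
}

#' Segment cells from the two denoised FUCCI channels
#'
#' Otsu's threshold is recomputed per frame (adaptive) on the pixelwise
#' maximum of the red and green channels, so cells stay detectable through the
#' red-to-green handoff. Foreground pixels are labeled by 8-connected
#' component analysis and components below `min_size` pixels are dropped.
#'
#' @param red_dn,green_dn denoised channels, same shape.
#' @param min_size minimum component area in pixels (default 30).
#' @return integer label matrix (0 = background, labels contiguous from 1).
#' @export
segment_fluorescence <- function(red_dn, green_dn, min_size = 30) {
  stopifnot(all(dim(red_dn) == dim(green_dn)))
  comb <- pmax(red_dn, green_dn)
  mx <- max(comb)
  if (mx <= 0) return(matrix(0L, nrow(comb), ncol(comb)))
  th <- EBImage::otsu(comb / mx, range = c(0, 1)) * mx
  label_mask(comb > th, min_size)
}

# 8-connected labeling + minimum-size filtering, contiguous labels
label_mask <- function(mask, min_size) {
  lab <- label_components_cpp(mask)
  if (min_size > 1 && max(lab) > 0) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

#' Segment the transmitted-light (phase/bright-field) channel
#'
#' Foreground pixels are those deviating from the mid-level background (frame
#' median) by more than one standard deviation, in either direction (cells
#' have dark bodies and bright rims), combined with an Otsu-thresholded
#' Sobel gradient-magnitude image; holes in the union are filled.
#'
#' @param image transmitted-light frame (matrix).
#' @param gradient_union include the Otsu-thresholded gradient foreground
#'   (default TRUE; FALSE keeps only the intensity-deviation rule).
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return logical foreground mask.
#' @export
segment_phase <- function(image, gradient_union = TRUE, fill_holes = TRUE) {
  stopifnot(is.matrix(image))
  med <- median(image)
  s <- sd(image)
  m <- if (s > 0) abs(image - med) > s else
    matrix(FALSE, nrow(image), ncol(image))
  if (gradient_union) {
    g <- sobel_magnitude(image)
    gm <- max(g)
    if (gm > 0) m <- m | (g > EBImage::otsu(g / gm, range = c(0, 1)) * gm)
  }
  if (!any(m) || !fill_holes) return(m)
  EBImage::fillHull(m) > 0
}

sobel_magnitude <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  gx <- EBImage::filter2(image, kx)
  gy <- EBImage::filter2(image, ky)
  sqrt(gx^2 + gy^2)
}

#' Intersect fluorescence and phase segmentations and measure cells
#'
#' The final foreground is the pixelwise intersection of the fluorescence
#' component labels with the phase mask; components losing more than half of
#' their area to the intersection (or falling below `min_size`) are dropped.
#' Mean intensities are measured on the raw (un-denoised) fluorescence
#' channels within the final boundaries.
#'
#' @param fluor_labels integer label matrix from [segment_fluorescence()].
#' @param phase_mask logical mask from [segment_phase()], or NULL to skip the
#'   intersection (fluorescence-only segmentation).
#' @param raw_red,raw_green raw fluorescence channels for intensity readout.
#' @param frame_index frame number recorded in the detections.
#' @param pixel_size microns per pixel (for calibrated centroids).
#' @param min_size minimum retained component area, pixels.
#' @param min_keep_frac a component is dropped when the intersected area falls
#'   below this fraction of its original area (default 0.5).
#' @return list with `labels` (final integer label matrix) and `detections`
#'   (data.frame: frame, label_id, x_px, y_px, x_um, y_um, area_px, radius_px,
#'   mean_red, mean_green). Pixel coordinates are 0-based, origin at the
#'   top-left pixel center, x right, y down.
#' @export
combine_segmentations <- function(fluor_labels, phase_mask, raw_red, raw_green,
                                  frame_index = 1L, pixel_size = 1,
                                  min_size = 30, min_keep_frac = 0.5) {
  stopifnot(is.null(phase_mask) || all(dim(fluor_labels) == dim(phase_mask)))
  lab <- fluor_labels
  if (!is.null(phase_mask) && max(lab) > 0) {
    orig_sizes <- tabulate(lab)
    lab[!phase_mask] <- 0L
    new_sizes <- tabulate(lab, nbins = length(orig_sizes))
    drop <- new_sizes < pmax(min_keep_frac * orig_sizes, min_size)
    if (any(drop)) lab[lab %in% which(drop)] <- 0L
    # relabel contiguously
    ids <- sort(unique(lab[lab > 0]))
    remap <- integer(max(c(ids, 0L)))
    remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  detections <- measure_detections(lab, raw_red, raw_green, frame_index,
                                   pixel_size)
  list(labels = lab, detections = detections)
}

measure_detections <- function(labels, raw_red, raw_green, frame_index,
                               pixel_size) {
  n <- max(labels)
  empty <- data.frame(frame = integer(), label_id = integer(),
                      x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_px = numeric(), radius_px = numeric(),
                      mean_red = numeric(), mean_green = numeric())
  if (n == 0) return(empty)
  idx <- which(labels > 0)
  l <- labels[idx]
  row0 <- (idx - 1) %% nrow(labels)       # 0-based y
  col0 <- (idx - 1) %/% nrow(labels)      # 0-based x
  area <- tabulate(l, nbins = n)
  x_px <- tapply(col0, l, mean)
  y_px <- tapply(row0, l, mean)
  mr <- tapply(raw_red[idx], l, mean)
  mg <- tapply(raw_green[idx], l, mean)
  data.frame(frame = as.integer(frame_index), label_id = seq_len(n),
             x_px = as.numeric(x_px), y_px = as.numeric(y_px),
             x_um = as.numeric(x_px) * pixel_size,
             y_um = as.numeric(y_px) * pixel_size,
             area_px = area, radius_px = sqrt(area / pi),
             mean_red = as.numeric(mr), mean_green = as.numeric(mg))
}

#' Detect cells in every frame of a movie
#'
#' Runs denoise -> adaptive Otsu fluorescence segmentation -> transmitted-light
#' segmentation -> channel intersection for each frame and collects the
#' per-cell measurements.
#'
#' @param movie a `movie_stack` (arrays red/green and optionally trans).
#' @param min_size minimum component area, pixels.
#' @param use_phase intersect with the transmitted-light mask (default TRUE
#'   when the channel is present).
#' @return list with `detections` (one data.frame over all frames) and
#'   `labels` (list of per-frame label matrices).
#' @export
detect_cells <- function(movie, min_size = 30,
                         use_phase = !is.null(movie$trans)) {
  n_frames <- dim(movie$red)[3]
  dets <- vector("list", n_frames)
  labs <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    r_raw <- movie$red[, , fr]
    g_raw <- movie$green[, , fr]
    fl <- segment_fluorescence(denoise(r_raw), denoise(g_raw), min_size)
    pm <- if (use_phase) segment_phase(movie$trans[, , fr]) else NULL
    res <- combine_segmentations(fl, pm, r_raw, g_raw, frame_index = fr,
                                 pixel_size = movie$pixel_size,
                                 min_size = min_size)
    dets[[fr]] <- res$detections
    labs[[fr]] <- res$labels
  }
  list(detections = do.call(rbind, dets), labels = labs)
}
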
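#' Render a ground-truth scene into a multi-channel movie
#'
#' Fluorescence channels are sums of isotropic Gaussian blobs (sd =
#' `blob_radius`) scaled by the true per-frame FUCCI intensities, plus a
#' slow-varying low-frequency background field (Gaussian-filtered white noise,
#' filter sd = 25% of the image side, scaled to `background_amplitude`) plus
#' zero-mean shot noise (sd `shot_noise_scale`). The transmitted-light channel
#' is a uniform mid-gray with a darker cell body and a thin bright rim per
#' cell, the same noise model, and dark channel walls in the channel modes.
#' All pixel values are clipped at zero. Rendering is deterministic given the
#' scene config (RNG seeded from `config$seed`).
#'
#' @param truth a `ground_truth` from [simulate_trajectories()].
#' @param config the matching [scene_config()]; defaults to `truth$config`.
#' @return object of class `movie_stack`: list of per-channel arrays
#'   (height x width x frame) named red, green, trans, plus calibration.
#' @export
render_movie <- function(truth, config = truth$config) {
  validate_scene_config(config)
  cfg <- config
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  sigma_px <- cfg$blob_radius / cfg$pixel_size
  if (6 * sigma_px > min(h, w))
    stop("render_movie: image_shape too small for blob_radius", call. = FALSE)
  set.seed(cfg$seed + 1L)

  red <- array(0, c(h, w, cfg$n_frames))
  green <- array(0, c(h, w, cfg$n_frames))
  trans <- array(0, c(h, w, cfg$n_frames))
  mid <- 0.5 * cfg$intensity_peak
  tr <- truth$truth

  wall_rows <- integer(0)
  if (cfg$mode %in% c("channel", "channel_chemotaxis")) {
    half_w <- cfg$channel_width / 2
    walls <- as.vector(vapply(channel_centerlines(cfg),
                              function(c) c(c - half_w, c + half_w),
                              numeric(2)))
    wall_rows <- unique(pmin(h, pmax(1, round(walls / cfg$pixel_size) + 1L)))
  }

  for (fr in seq_len(cfg$n_frames)) {
    fr_red <- matrix(0, h, w)
    fr_green <- matrix(0, h, w)
    fr_trans <- matrix(mid, h, w)
    rows <- tr[tr$frame == fr, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cx <- rows$x_um[i] / cfg$pixel_size  # 0-based pixel coords
      cy <- rows$y_um[i] / cfg$pixel_size
      blob <- gaussian_blob(h, w, cx, cy, sigma_px)
      if (is.null(blob)) next
      ri <- blob$rows; ci <- blob$cols; g <- blob$values
      fr_red[ri, ci] <- fr_red[ri, ci] + rows$red[i] * g
      fr_green[ri, ci] <- fr_green[ri, ci] + rows$green[i] * g
      # transmitted: darker body, thin bright rim at ~1.5 sd
      rim <- exp(-((blob$dist - 1.5 * sigma_px)^2) / (2 * (sigma_px / 4)^2))
      fr_trans[ri, ci] <- fr_trans[ri, ci] - 0.4 * mid * g + 0.5 * mid * rim
    }
    if (length(wall_rows)) fr_trans[wall_rows, ] <- 0.3 * fr_trans[wall_rows, ]

    if (cfg$background_amplitude > 0) {
      fr_red <- fr_red + cfg$background_amplitude * lowfreq_field(h, w)
      fr_green <- fr_green + cfg$background_amplitude * lowfreq_field(h, w)
      fr_trans <- fr_trans + cfg$background_amplitude * lowfreq_field(h, w)
    }
    if (cfg$shot_noise_scale > 0) {
      fr_red <- fr_red + matrix(rnorm(h * w, 0, cfg$shot_noise_scale), h, w)
      fr_green <- fr_green + matrix(rnorm(h * w, 0, cfg$shot_noise_scale), h, w)
      fr_trans <- fr_trans + matrix(rnorm(h * w, 0, cfg$shot_noise_scale), h, w)
    }
    red[, , fr] <- pmax(fr_red, 0)
    green[, , fr] <- pmax(fr_green, 0)
    trans[, , fr] <- pmax(fr_trans, 0)
  }
  structure(list(red = red, green = green, trans = trans,
                 pixel_size = cfg$pixel_size,
                 frame_interval = cfg$frame_interval,
                 config = cfg),
            class = "movie_stack")
}

# Local Gaussian footprint around (cx, cy) (0-based pixel coords); returns the
# affected row/col index ranges (1-based), the Gaussian values and the radial
# distance map, or NULL if the support misses the image entirely.
gaussian_blob <- function(h, w, cx, cy, sigma_px, extent = 4) {
  r <- ceiling(extent * sigma_px)
  r0 <- max(1, floor(cy + 1 - r)); r1 <- min(h, ceiling(cy + 1 + r))
  c0 <- max(1, floor(cx + 1 - r)); c1 <- min(w, ceiling(cx + 1 + r))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  dy <- rows - 1 - cy
  dx <- cols - 1 - cx
  d2 <- outer(dy^2, dx^2, `+`)
  list(rows = rows, cols = cols,
       values = exp(-d2 / (2 * sigma_px^2)),
       dist = sqrt(d2))
}

# Slow-varying unit-variance background: white noise filtered with a Gaussian
# of sd = 25% of the (coarse) image side, synthesized on a coarse grid for
# speed and bilinearly upsampled (interpolation error is far above the
# retained spatial frequencies).
lowfreq_field <- function(h, w, rel_sd = 0.25, coarse = 64L) {
  ch <- min(h, coarse); cw <- min(w, coarse)
  n <- matrix(rnorm(ch * cw), ch, cw)
  f <- stats::fft(n)
  fy <- c(0:floor(ch / 2), -((ceiling(ch / 2) - 1):1)) / ch
  fx <- c(0:floor(cw / 2), -((ceiling(cw / 2) - 1):1)) / cw
  sig <- rel_sd * min(ch, cw)
  g <- outer(exp(-2 * pi^2 * sig^2 * fy^2), exp(-2 * pi^2 * sig^2 * fx^2))
  sm <- Re(stats::fft(f * g, inverse = TRUE)) / (ch * cw)
  sm <- sm / max(stats::sd(sm), .Machine$double.eps)
  if (ch == h && cw == w) return(sm)
  bilinear_resize(sm, h, w)
}

bilinear_resize <- function(m, h, w) {
  sy <- (seq_len(h) - 0.5) / h * nrow(m) + 0.5
  sx <- (seq_len(w) - 0.5) / w * ncol(m) + 0.5
  y0 <- pmin(pmax(floor(sy), 1), nrow(m)); y1 <- pmin(y0 + 1, nrow(m))
  x0 <- pmin(pmax(floor(sx), 1), ncol(m)); x1 <- pmin(x0 + 1, ncol(m))
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wyM <- matrix(wy, h, w); wxM <- matrix(wx, h, w, byrow = TRUE)
  a * (1 - wyM) * (1 - wxM) + b * (1 - wyM) * wxM +
    c_ * wyM * (1 - wxM) + d * wyM * wxM
}

#' Render a synthetic collagen fiber image with known angles
#'
#' Draws `n_fibers` anti-aliased line segments of random length and position.
#' Angles are drawn from a uniform distribution on [0, 180) degrees or a
#' Gaussian (wrapped into [0, 180)) centered at `mu` with sd `sigma`, emulating
#' confocal reflection images of random vs. flow-aligned collagen gels.
#'
#' @param n_fibers number of segments (>= 1).
#' @param angle_distribution "uniform" or "gaussian".
#' @param mu,sigma Gaussian mean and sd in degrees (gaussian only; sigma > 0).
#' @param image_shape c(height, width) pixels.
#' @param seed RNG seed.
#' @return list with `image` (matrix) and `angles` (degrees in [0, 180)).
#' @export
simulate_fiber_image <- function(n_fibers,
                                 angle_distribution = c("uniform", "gaussian"),
                                 mu = 90, sigma = 10,
                                 image_shape = c(256L, 256L), seed = 1L) {
  angle_distribution <- match.arg(angle_distribution)
  stopifnot(n_fibers >= 1)
  if (angle_distribution == "gaussian" && sigma <= 0)
    stop("simulate_fiber_image: sigma must be > 0 for gaussian", call. = FALSE)
  set.seed(seed)
  h <- image_shape[1]; w <- image_shape[2]
  angles <- if (angle_distribution == "uniform") runif(n_fibers, 0, 180)
            else (rnorm(n_fibers, mu, sigma)) %% 180
  img <- matrix(0, h, w)
  for (i in seq_len(n_fibers)) {
    th <- angles[i] * pi / 180
    len <- runif(1, 0.3, 0.7) * min(h, w)
    cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
    # x right, y down; angle measured from +x toward +y (axial, mod 180)
    dxy <- c(cos(th), sin(th))
    ts <- seq(-len / 2, len / 2, by = 0.35)
    px <- cx + ts * dxy[1]; py <- cy + ts * dxy[2]
    keep <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    px <- px[keep]; py <- py[keep]
    if (!length(px)) next
    # bilinear deposition (anti-aliasing)
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    for (k in seq_along(px)) {
      xs <- c(x0[k], x0[k] + 1, x0[k], x0[k] + 1) + 1
      ys <- c(y0[k], y0[k], y0[k] + 1, y0[k] + 1) + 1
      ws <- c((1 - fx[k]) * (1 - fy[k]), fx[k] * (1 - fy[k]),
              (1 - fx[k]) * fy[k], fx[k] * fy[k])
      ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
      idx <- cbind(ys[ok], xs[ok])
      img[idx] <- img[idx] + ws[ok]
    }
  }
  img <- EBImage::gblur(img, sigma = 1)
  list(image = img, angles = angles)
}
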
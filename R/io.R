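#' Write and read movies as multi-page TIFF (one file per channel)
#'
#' Intensities are stored as 16-bit samples (values rounded to integers in
#' [0, 65535]); reading restores the integer intensities, so write + read of
#' integer-valued images is lossless. Label masks round-trip exactly up to
#' 65535 labels.
#'
#' @param movie a `movie_stack`.
#' @param dir output directory (created if needed).
#' @param basename file name stem; channels are written as
#'   `<basename>_<channel>.tif`.
#' @return (invisibly) the written paths.
#' @export
write_movie_tiff <- function(movie, dir, basename = "movie") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- intersect(c("red", "green", "trans"), names(movie))
  paths <- character(0)
  for (ch in chans) {
    arr <- movie[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(i)
      pmin(pmax(round(arr[, , i]), 0), 65535) / 65535)
    p <- file.path(dir, paste0(basename, "_", ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_movie_tiff
#' @param red_path,green_path,trans_path per-channel TIFF paths (trans_path
#'   may be NULL).
#' @param pixel_size,frame_interval calibration attached to the movie.
#' @export
read_movie_tiff <- function(red_path, green_path, trans_path = NULL,
                            pixel_size = 0.65, frame_interval = 10) {
  read_chan <- function(p) {
    if (!file.exists(p)) stop("missing channel file: ", p, call. = FALSE)
    pages <- tiff::readTIFF(p, all = TRUE)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (i in seq_along(pages)) {
      pg <- pages[[i]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      arr[, , i] <- round(pg * 65535)
    }
    arr
  }
  red <- read_chan(red_path)
  green <- read_chan(green_path)
  trans <- if (!is.null(trans_path)) read_chan(trans_path) else NULL
  if (!all(dim(red) == dim(green)) ||
      (!is.null(trans) && !all(dim(trans) == dim(red))))
    stop("channel frame counts/shapes disagree", call. = FALSE)
  structure(list(red = red, green = green, trans = trans,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "movie_stack")
}

#' Write per-frame label masks as a 16-bit multi-page TIFF
#' @param labels list of integer label matrices.
#' @param path output file.
#' @export
write_label_tiff <- function(labels, path) {
  pages <- lapply(labels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg))
  })
}

#' Ground-truth CSV round trip
#' @param truth a `ground_truth` or its `truth` data.frame.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- if (inherits(truth, "ground_truth")) truth$truth else truth
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Flat key=value config files
#'
#' Scene and pipeline configurations are echoed to flat `key=value` text so a
#' manifest can hash them bit-exactly. Numeric scalars are written with full
#' (17 significant digit) precision; numeric vectors are comma-separated.
#'
#' @param config a named list (e.g. a `scene_config`).
#' @param path output path.
#' @export
write_flat_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return("NULL")
    if (is.numeric(v)) return(paste(sprintf("%.17g", v), collapse = ","))
    paste(as.character(v), collapse = ",")
  }
  keys <- names(config)
  lines <- vapply(keys, function(k) paste0(k, "=", fmt(config[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flat_config
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- p[1]
    val <- paste(p[-1], collapse = "=")
    if (identical(val, "NULL")) { out[key] <- list(NULL); next }
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
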
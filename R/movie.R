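#' Movie container
#'
#' A movie is a set of channels sharing geometry and calibration. Each channel
#' is a numeric array `X x Y x M` (x index, y index, frame); intensities are
#' finite and non-negative.
#'
#' @param channels Named list of X x Y x M arrays.
#' @param pixel_size um per pixel.
#' @param frame_interval Seconds per frame.
#' @param patient_id,movie_id Free-text identifiers.
#' @return An object of class `lm_movie`.
#' @export
movie <- function(channels, pixel_size = DEFAULT_PIXEL_SIZE,
                  frame_interval = DEFAULT_FRAME_INTERVAL,
                  patient_id = "P0", movie_id = "M0") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("each channel must be an X x Y x M array", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all channels must share the same X, Y, M", call. = FALSE)
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(list(channels = channels,
                 channel_names = names(channels),
                 pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 patient_id = patient_id,
                 movie_id = movie_id),
            class = "lm_movie")
}

#' @export
print.lm_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<lm_movie> %s: %d channel(s) [%s], %dx%d px, %d frames, %.3g um/px, %gs/frame\n",
    x$movie_id, length(x$channels),
    paste(x$channel_names, collapse = ", "),
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.lm_movie <- function(x) dim(x$channels[[1]])
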
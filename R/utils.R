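#' @keywords internal
"_PACKAGE"

# Paper-convention velocity conversion factor (um/min per px/frame) used for
# bare pixel-unit tracks without calibration metadata. 0.4 um/px at 20 s/frame
# gives 1.2 exactly; the published convention rounds to 1.23 and we keep both:
# metadata wins when present.
DEFAULT_CONVERSION_FACTOR <- 1.23
DEFAULT_PIXEL_SIZE <- 0.4    # um / pixel
DEFAULT_FRAME_INTERVAL <- 20 # seconds / frame

#' Velocity conversion factor from calibration metadata
#'
#' Converts pixels/frame into um/min: `pixel_size * 60 / frame_interval`.
#'
#' @param pixel_size Spatial calibration, um per pixel.
#' @param frame_interval Temporal calibration, seconds per frame.
#' @return Scalar factor in (um/min) per (pixel/frame).
#' @export
velocity_factor <- function(pixel_size = DEFAULT_PIXEL_SIZE,
                            frame_interval = DEFAULT_FRAME_INTERVAL) {
  stopifnot(pixel_size > 0, frame_interval > 0)
  pixel_size * 60 / frame_interval
}

# internal: positive scalar check with informative error
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a non-negative finite scalar", name),
         call. = FALSE)
  }
  invisible(x)
}

# internal: wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# internal: derive a 32-bit-safe child seed from a base seed and a stream id
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 11 * stream) %% 2147483647)
}
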
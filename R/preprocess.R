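#' Maximum-intensity projection along z
#'
#' Collapses a z-stack to 2D by the per-pixel maximum over z. A 3D input
#' (X x Y x M) is treated as already projected and returned unchanged, which
#' makes the operation idempotent.
#'
#' @param x A 4D array (X x Y x Z x M) or an already-projected 3D array.
#' @return A 3D array X x Y x M.
#' @export
max_intensity_project <- function(x) {
  nd <- length(dim(x))
  if (nd == 3L) return(x)
  if (nd != 4L) stop("input must be X x Y x Z x M (or X x Y x M)",
                     call. = FALSE)
  if (dim(x)[3] == 0L) stop("empty z-axis", call. = FALSE)
  nx <- dim(x)[1]; ny <- dim(x)[2]; nz <- dim(x)[3]; M <- dim(x)[4]
  out <- array(-Inf, c(nx, ny, M))
  for (z in seq_len(nz)) out <- pmax(out, x[, , z, ])
  out
}

#' Normalize and blur a movie
#'
#' The published preprocessing: low-intensity cut-off, Gaussian blurring, then
#' per-channel min-max rescale to [0, 1], in that fixed order. The order and
#' parameters are recorded in the movie's `preprocessing` field because
#' blurring changes downstream velocity measurements.
#'
#' @param mv An [movie()].
#' @param low_cut Absolute intensity cut-off; intensities below it are set to
#'   0. Default (`NULL`) uses 2\% of the channel maximum.
#' @param blur_sigma Gaussian blur sd in pixels (0 = no blur).
#' @return The preprocessed movie; a constant channel becomes all zeros with
#'   a warning.
#' @export
normalize_and_blur <- function(mv, low_cut = NULL, blur_sigma = 1) {
  stopifnot(inherits(mv, "lm_movie"))
  check_nonneg(blur_sigma, "blur_sigma")
  M <- dim(mv)[3]
  for (ch in mv$channel_names) {
    a <- mv$channels[[ch]]
    cut <- if (is.null(low_cut)) 0.02 * max(a) else low_cut
    a[a < cut] <- 0
    if (blur_sigma > 0) {
      for (t in seq_len(M)) a[, , t] <- blur2d(a[, , t], blur_sigma)
    }
    rng <- range(a)
    if (rng[2] - rng[1] <= 0) {
      warning(sprintf("channel '%s' is constant after cut-off; set to zeros",
                      ch))
      a[] <- 0
    } else {
      a <- (a - rng[1]) / (rng[2] - rng[1])
    }
    mv$channels[[ch]] <- a
  }
  mv$preprocessing <- c(mv$preprocessing, list(list(
    step = "normalize_and_blur", order = c("cutoff", "blur", "rescale"),
    low_cut = low_cut %||% "2% of max", blur_sigma = blur_sigma)))
  mv
}

# bilinear resize of one frame to (nx2, ny2)
resize_bilinear <- function(img, nx2, ny2) {
  nx <- nrow(img); ny <- ncol(img)
  # map output pixel centres into input pixel coordinates
  xs <- (seq_len(nx2) - 0.5) * nx / nx2 - 0.5
  ys <- (seq_len(ny2) - 0.5) * ny / ny2 - 0.5
  xs <- pmin(pmax(xs, 0), nx - 1); ys <- pmin(pmax(ys, 0), ny - 1)
  x0 <- pmin(floor(xs), nx - 2); y0 <- pmin(floor(ys), ny - 2)
  fx <- xs - x0; fy <- ys - y0
  i0 <- x0 + 1L; j0 <- y0 + 1L
  a <- img[i0, j0, drop = FALSE]; b <- img[i0 + 1L, j0, drop = FALSE]
  c2 <- img[i0, j0 + 1L, drop = FALSE]; d <- img[i0 + 1L, j0 + 1L, drop = FALSE]
  fxm <- matrix(fx, nx2, ny2); fym <- matrix(fy, nx2, ny2, byrow = TRUE)
  a * (1 - fxm) * (1 - fym) + b * fxm * (1 - fym) +
    c2 * (1 - fxm) * fym + d * fxm * fym
}

#' Resample a movie to a common spatio-temporal grid
#'
#' Spatial bilinear resampling to `target_pixel_size` and temporal
#' nearest-frame selection to `target_interval`; calibration metadata is
#' updated so downstream unit conversion stays consistent.
#'
#' @param mv An [movie()].
#' @param target_pixel_size Target um/pixel.
#' @param target_interval Target seconds/frame.
#' @return The resampled movie. Spatial upsampling beyond 4x warns.
#' @export
resample_to_common_grid <- function(mv,
                                    target_pixel_size = DEFAULT_PIXEL_SIZE,
                                    target_interval = DEFAULT_FRAME_INTERVAL) {
  stopifnot(inherits(mv, "lm_movie"))
  check_positive(target_pixel_size, "target_pixel_size")
  check_positive(target_interval, "target_interval")
  if (mv$pixel_size / target_pixel_size > 4) {
    warning("spatial upsampling beyond 4x fabricates information")
  }
  d <- dim(mv)
  same_space <- abs(target_pixel_size - mv$pixel_size) < 1e-12
  same_time <- abs(target_interval - mv$frame_interval) < 1e-12
  if (same_space && same_time) return(mv)

  nx2 <- max(1L, round(d[1] * mv$pixel_size / target_pixel_size))
  ny2 <- max(1L, round(d[2] * mv$pixel_size / target_pixel_size))
  t_old <- (seq_len(d[3]) - 1) * mv$frame_interval
  t_new <- seq(0, max(t_old), by = target_interval)
  pick <- vapply(t_new, function(tt) which.min(abs(t_old - tt)), 1L)

  for (ch in mv$channel_names) {
    a <- mv$channels[[ch]]
    out <- array(0, c(nx2, ny2, length(pick)))
    for (k in seq_along(pick)) {
      fr <- a[, , pick[k]]
      out[, , k] <- if (same_space) fr else resize_bilinear(fr, nx2, ny2)
    }
    mv$channels[[ch]] <- out
  }
  mv$pixel_size <- target_pixel_size
  mv$frame_interval <- target_interval
  mv$preprocessing <- c(mv$preprocessing, list(list(
    step = "resample", pixel_size = target_pixel_size,
    frame_interval = target_interval)))
  mv
}
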
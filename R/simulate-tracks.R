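#' Simulate phenotype-specific cell tracks
#'
#' Tracks follow a correlated random walk: per-frame speeds are drawn from a
#' heavy-tailed log-normal law whose population mean (or median, depending on
#' the preset's `speed_calibration`) equals `preset$mean_speed`, and headings
#' evolve with wrapped-normal turning angles. Each track belongs to one of two
#' movement regimes that differ only in heading persistence: "directed"
#' (turning sd `preset$directed_turning_std`) or "undirected" (turning sd
#' `preset$turning_angle_std`).
#'
#' @param preset A [phenotype_preset()].
#' @param config A [scene_config()]; supplies `n_frames`, `frame_interval`,
#'   `pixel_size` and the `seed`.
#' @param n_tracks Number of tracks (default `config$n_cells_per_phenotype`).
#' @param origins Optional `n_tracks` x 2 matrix of starting positions (um);
#'   defaults to the origin.
#' @param seed Optional seed override.
#' @return A `data.frame` with columns `track_id`, `frame` (0-based),
#'   `t_seconds`, `x_um`, `y_um`, `x_px`, `y_px`, `phenotype`, `regime`.
#' @export
simulate_tracks <- function(preset, config,
                            n_tracks = config$n_cells_per_phenotype,
                            origins = NULL, seed = config$seed) {
  stopifnot(inherits(preset, "phenotype_preset"),
            inherits(config, "scene_config"))
  if (n_tracks <= 0) stop("'n_tracks' must be positive", call. = FALSE)
  n_frames <- config$n_frames
  dt_min <- config$frame_interval / 60
  if (is.null(origins)) {
    origins <- matrix(0, n_tracks, 2)
  }
  stopifnot(nrow(origins) == n_tracks)

  set.seed(seed)
  n_steps <- n_frames - 1L
  regime <- ifelse(stats::runif(n_tracks) < preset$directed_fraction,
                   "directed", "undirected")

  # log-normal speed law; calibrated so that either the mean or the median of
  # the per-frame speed distribution equals the preset target
  s <- preset$speed_dispersion
  mu <- if (preset$mean_speed == 0) {
    -Inf
  } else if (preset$speed_calibration == "mean") {
    log(preset$mean_speed) - s^2 / 2
  } else {
    log(preset$mean_speed)
  }

  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    v <- if (is.finite(mu)) stats::rlnorm(n_steps, mu, s) else rep(0, n_steps)
    sdr <- if (regime[i] == "directed") preset$directed_turning_std
           else preset$turning_angle_std
    turns <- if (sdr > 0) stats::rnorm(n_steps - 1L, 0, sdr) else
      rep(0, n_steps - 1L)
    heading <- wrap_angle(cumsum(c(stats::runif(1, -pi, pi), turns)))
    step_len <- v * dt_min                       # um per frame
    dx <- step_len * cos(heading)
    dy <- step_len * sin(heading)
    out[[i]] <- data.frame(
      track_id = i,
      frame = 0:(n_frames - 1L),
      t_seconds = (0:(n_frames - 1L)) * config$frame_interval,
      x_um = origins[i, 1] + c(0, cumsum(dx)),
      y_um = origins[i, 2] + c(0, cumsum(dy)),
      phenotype = preset$name,
      regime = regime[i]
    )
  }
  tracks <- do.call(rbind, out)
  tracks$x_px <- tracks$x_um / config$pixel_size
  tracks$y_px <- tracks$y_um / config$pixel_size
  tracks <- tracks[, c("track_id", "frame", "t_seconds", "x_px", "y_px",
                       "x_um", "y_um", "phenotype", "regime")]
  attr(tracks, "pixel_size") <- config$pixel_size
  attr(tracks, "frame_interval") <- config$frame_interval
  class(tracks) <- c("lm_tracks", "data.frame")
  tracks
}

# internal: split a track table into per-track (frame, x, y) matrices keeping
# calibration metadata
split_tracks <- function(tracks, units = c("um", "px")) {
  units <- match.arg(units)
  xs <- if (units == "um") tracks$x_um else tracks$x_px
  ys <- if (units == "um") tracks$y_um else tracks$y_px
  if (is.null(xs)) { xs <- tracks$x; ys <- tracks$y }
  by_id <- split(data.frame(frame = tracks$frame, x = xs, y = ys),
                 tracks$track_id)
  lapply(by_id, function(d) {
    d <- d[order(d$frame), ]
    as.matrix(d)
  })
}

# internal: per-track metadata (phenotype, regime) — first row of each track
track_meta <- function(tracks) {
  idx <- !duplicated(tracks$track_id)
  meta <- tracks[idx, intersect(c("track_id", "phenotype", "regime",
                                  "movie_id", "patient_id"), names(tracks))]
  rownames(meta) <- NULL
  meta
}
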
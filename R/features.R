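# feature name order is part of the contract: 4 summaries x 3 series + 3
# distances = 15 entries
FEATURE_NAMES <- c(
  "velocity_mean", "velocity_std", "velocity_min", "velocity_max",
  "accel_mean", "accel_std", "accel_min", "accel_max",
  "angle_mean", "angle_std", "angle_min", "angle_max",
  "total_distance", "net_distance", "maximum_distance")

# internal: positions matrix (n x 2, px) from a one-track data.frame
track_positions <- function(track) {
  if (is.matrix(track)) {
    return(track[, c(ncol(track) - 1, ncol(track)), drop = FALSE])
  }
  xs <- track$x_px %||% track$x
  ys <- track$y_px %||% track$y
  if (!is.null(track$track_id) && length(unique(track$track_id)) > 1) {
    stop("expected a single track; got several track_ids", call. = FALSE)
  }
  ord <- order(track$frame %||% seq_along(xs))
  cbind(xs[ord], ys[ord])
}

# internal: um/min per px/frame conversion for a track
track_factor <- function(track, conversion_factor = NULL) {
  if (!is.null(conversion_factor)) return(conversion_factor)
  ps <- attr(track, "pixel_size")
  fi <- attr(track, "frame_interval")
  if (!is.null(ps) && !is.null(fi)) velocity_factor(ps, fi)
  else DEFAULT_CONVERSION_FACTOR
}

#' Per-step speeds of a track
#'
#' Forward differences give `||p[i+1] - p[i]|| / dt`; centered differences
#' (the published default, used for numerical stability) give
#' `||p[i+1] - p[i-1]|| / (2 dt)`. Speeds are converted from px/frame to
#' um/min using the track's calibration metadata when present, otherwise the
#' conventional factor 1.23 (`conversion_factor` overrides both).
#'
#' @param track One track: a data.frame with `frame` and `x_px`/`y_px` (or
#'   `x`/`y`) columns.
#' @param scheme `"centered"` or `"forward"`.
#' @param conversion_factor Optional um/min per px/frame factor.
#' @return Numeric vector of speeds, um/min (length l-1 forward, l-2
#'   centered).
#' @export
compute_velocity <- function(track, scheme = c("centered", "forward"),
                             conversion_factor = NULL) {
  scheme <- match.arg(scheme)
  p <- track_positions(track)
  l <- nrow(p)
  need <- if (scheme == "forward") 2L else 3L
  if (l < need) {
    stop(sprintf("track too short for %s differences (need at least %d points)",
                 scheme, need), call. = FALSE)
  }
  f <- track_factor(track, conversion_factor)
  if (scheme == "forward") {
    sqrt(rowSums(diff(p)^2)) * f
  } else {
    n <- l - 2L
    sqrt(rowSums((p[3:l, , drop = FALSE] - p[1:n, , drop = FALSE])^2)) / 2 * f
  }
}

#' Signed turning angles of a track
#'
#' Angle between consecutive displacement segments, radians in [-pi, pi],
#' clockwise positive in image coordinates (y pointing down). Zero-length
#' segments yield angle 0, flagged in the `degenerate` attribute and excluded
#' from min/max summary statistics.
#'
#' @param track One track (see [compute_velocity()]).
#' @return Numeric vector of length l-2 with attribute `degenerate`.
#' @export
compute_turning_angles <- function(track) {
  p <- track_positions(track)
  l <- nrow(p)
  if (l < 3) stop("track too short for turning angles (need at least 3 points)",
                  call. = FALSE)
  seg <- diff(p)
  u <- seg[-nrow(seg), , drop = FALSE]
  v <- seg[-1, , drop = FALSE]
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  dot <- rowSums(u * v)
  ang <- atan2(cross, dot)
  degen <- rowSums(u^2) == 0 | rowSums(v^2) == 0
  ang[degen] <- 0
  attr(ang, "degenerate") <- degen
  ang
}

#' Path distances of a track
#'
#' `total` is the summed step length, `net` the start-to-end distance,
#' `maximum` the largest distance from the start to any point. Always
#' `total >= maximum >= net`. Units follow the positions (pixels) scaled by
#' `scale` (e.g. pixel size to obtain um).
#'
#' @param track One track.
#' @param scale Multiplicative unit scale (default: pixel size from metadata,
#'   else 1).
#' @return Named numeric vector `c(total, net, maximum)`.
#' @export
compute_distances <- function(track, scale = NULL) {
  p <- track_positions(track)
  if (nrow(p) < 2) stop("track too short for distances (need at least 2 points)",
                        call. = FALSE)
  if (is.null(scale)) scale <- attr(track, "pixel_size") %||% 1
  steps <- sqrt(rowSums(diff(p)^2))
  from_start <- sqrt(rowSums((p[-1, , drop = FALSE] -
                                matrix(p[1, ], nrow(p) - 1, 2, byrow = TRUE))^2))
  c(total = sum(steps), net = from_start[length(from_start)],
    maximum = max(from_start)) * scale
}

#' Invariant (v, a, r) representation of a track
#'
#' Speed, acceleration magnitude and turning angle per interior time point —
#' invariant under global translation and rotation of the source track.
#' Acceleration is the Euclidean norm of the second position difference,
#' unit-converted to um/min^2.
#'
#' @param track One track.
#' @param scheme Velocity scheme, `"centered"` (default) or `"forward"`.
#' @param conversion_factor Optional um/min per px/frame factor.
#' @return Matrix L x 3 with columns `v`, `a`, `r` (L = l - 2) and attribute
#'   `degenerate`.
#' @export
relative_track <- function(track, scheme = c("centered", "forward"),
                           conversion_factor = NULL) {
  scheme <- match.arg(scheme)
  p <- track_positions(track)
  l <- nrow(p)
  if (l < 3) stop("track too short for the relative representation (need 3 points)",
                  call. = FALSE)
  f <- track_factor(track, conversion_factor)
  fi <- attr(track, "frame_interval") %||% DEFAULT_FRAME_INTERVAL
  v <- compute_velocity(track, scheme, conversion_factor)
  if (scheme == "forward") v <- v[seq_len(l - 2L)]
  n <- l - 2L
  sec <- p[3:l, , drop = FALSE] - 2 * p[2:(l - 1L), , drop = FALSE] +
    p[1:n, , drop = FALSE]
  a <- sqrt(rowSums(sec^2)) * f * (60 / fi)   # px/frame^2 -> um/min^2
  r <- compute_turning_angles(track)
  out <- cbind(v = v, a = a, r = as.numeric(r))
  attr(out, "degenerate") <- attr(r, "degenerate")
  out
}

#' Summarize a relative track into the 15-entry feature vector
#'
#' Mean, sd, min and max of each of velocity, acceleration and turning angle,
#' plus total, net and maximum distance. Degenerate (zero-length-segment)
#' angles enter mean/sd as 0 but are excluded from min/max.
#'
#' @param rel Output of [relative_track()].
#' @param distances Output of [compute_distances()].
#' @return Named numeric vector of length 15 (see `FEATURE_NAMES` order).
#' @export
summarize_features <- function(rel, distances) {
  degen <- attr(rel, "degenerate") %||% rep(FALSE, nrow(rel))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  summ <- function(x) c(mean(x), sd0(x), min(x), max(x))
  ang <- rel[, "r"]
  ang_ok <- if (all(degen)) 0 else ang[!degen]
  out <- c(summ(rel[, "v"]), summ(rel[, "a"]),
           mean(ang), sd0(ang), min(ang_ok), max(ang_ok),
           distances[["total"]], distances[["net"]], distances[["maximum"]])
  names(out) <- FEATURE_NAMES
  out
}

#' Feature table for a set of tracks
#'
#' @param tracks An `lm_tracks` table (several tracks).
#' @param scheme Velocity scheme.
#' @param min_length Tracks with fewer points are dropped.
#' @return `data.frame`: `track_id`, `phenotype`, `regime`, `movie_id`,
#'   `patient_id` (when available) and the 15 feature columns.
#' @export
track_feature_table <- function(tracks, scheme = c("centered", "forward"),
                                min_length = 3L) {
  scheme <- match.arg(scheme)
  meta <- track_meta(tracks)
  ps <- attr(tracks, "pixel_size")
  fi <- attr(tracks, "frame_interval")
  rows <- lapply(split(tracks, tracks$track_id), function(d) {
    if (nrow(d) < max(3L, min_length)) return(NULL)
    attr(d, "pixel_size") <- ps
    attr(d, "frame_interval") <- fi
    rel <- relative_track(d, scheme)
    dist <- compute_distances(d)
    fv <- summarize_features(rel, dist)
    cbind(data.frame(track_id = d$track_id[1]), as.data.frame(t(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  merge(meta, out, by = "track_id", sort = TRUE)
}

#' Standardize feature columns
#'
#' Centers and scales the 15 feature columns. Statistics are returned so they
#' can be fitted on training folds only and applied to held-out data (no
#' leakage).
#'
#' @param features Feature table from [track_feature_table()].
#' @param stats Optional list with `center` and `scale` (from a previous
#'   call); when `NULL` they are computed from `features`.
#' @return The standardized table with attribute `standardization`.
#' @export
standardize_features <- function(features, stats = NULL) {
  cols <- intersect(FEATURE_NAMES, names(features))
  if (is.null(stats)) {
    ctr <- vapply(features[cols], mean, 0)
    scl <- vapply(features[cols], stats::sd, 0)
    scl[!is.finite(scl) | scl == 0] <- 1
    stats <- list(center = ctr, scale = scl)
  }
  for (cc in cols) {
    features[[cc]] <- (features[[cc]] - stats$center[[cc]]) / stats$scale[[cc]]
  }
  attr(features, "standardization") <- stats
  features
}
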
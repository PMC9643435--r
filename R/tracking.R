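# square max filter via separable shift-accumulate (window 2r+1)
max_filter <- function(img, r) {
  if (r <= 0) return(img)
  nx <- nrow(img); ny <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(nx), rep(nx, r)), , drop = FALSE]
  out <- img
  for (j in seq_len(2 * r + 1)) {
    out <- pmax(out, pad[j:(j + nx - 1L), , drop = FALSE])
  }
  pad <- out[, c(rep(1L, r), seq_len(ny), rep(ny, r)), drop = FALSE]
  for (j in seq_len(2 * r + 1)) {
    out <- pmax(out, pad[, j:(j + ny - 1L), drop = FALSE])
  }
  out
}

#' Detect cells in a single frame
#'
#' Band-pass filtering (small-scale Gaussian minus local background), local
#' maxima with brightness-ranked separation suppression, sub-pixel centroid
#' refinement, and a minimum integrated-mass filter. Masses are computed on
#' the 8-bit-scaled raw frame (sum of byte intensities within the feature
#' radius), matching the published `minmass` convention.
#'
#' @param frame Numeric matrix (preprocessed, intensities in [0, 1] or raw).
#' @param diameter Expected feature diameter, px.
#' @param separation Minimum distance between features, px.
#' @param minmass Minimum integrated mass (byte units) to keep a detection.
#' @param threshold Relative local-maximum threshold (fraction of the
#'   band-passed maximum).
#' @param mass_frame Optional frame used for mass computation; default scales
#'   `frame` to 0..255 when its maximum is <= 1.
#' @return `data.frame` with columns `x`, `y` (0-based px), `mass`,
#'   `diameter_est`.
#' @export
detect_cells <- function(frame, diameter = 25, separation = 15,
                         minmass = 5000, threshold = 0.05,
                         mass_frame = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(mass_frame)) {
    mass_frame <- if (max(frame) <= 1) frame * 255 else frame
  }
  bp <- blur2d(frame, 1) - blur2d(frame, diameter / 4)
  bp[bp < 0] <- 0
  if (max(bp) <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      diameter_est = numeric(0)))
  }
  r_sep <- max(1L, floor(separation / 2))
  mx <- max_filter(bp, r_sep)
  cand <- which(bp == mx & bp >= threshold * max(bp), arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      diameter_est = numeric(0)))
  }
  vals <- bp[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      rest <- (i + 1):nrow(cand)
      dd <- sqrt((cand[rest, 1] - cand[i, 1])^2 +
                   (cand[rest, 2] - cand[i, 2])^2)
      keep[rest][dd < separation] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  rw <- max(1L, floor(diameter / 2))
  nx <- nrow(frame); ny <- ncol(frame)
  off <- expand.grid(dx = -rw:rw, dy = -rw:rw)
  off <- off[off$dx^2 + off$dy^2 <= rw^2, ]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    cx <- cand[i, 1]; cy <- cand[i, 2]
    for (iter in 1:2) {            # centroid refinement on band-passed patch
      xs <- pmin(pmax(round(cx) + off$dx, 1L), nx)
      ys <- pmin(pmax(round(cy) + off$dy, 1L), ny)
      w <- bp[cbind(xs, ys)]
      if (sum(w) <= 0) break
      cx <- sum(xs * w) / sum(w)
      cy <- sum(ys * w) / sum(w)
    }
    xs <- pmin(pmax(round(cx) + off$dx, 1L), nx)
    ys <- pmin(pmax(round(cy) + off$dy, 1L), ny)
    w <- bp[cbind(xs, ys)]
    mass <- sum(mass_frame[cbind(xs, ys)])
    r2 <- sum(w * ((xs - cx)^2 + (ys - cy)^2)) / max(sum(w), 1e-12)
    data.frame(x = cx - 1, y = cy - 1, mass = mass,
               diameter_est = 2 * sqrt(2 * max(r2, 0)))
  })
  out <- do.call(rbind, out)
  out[out$mass >= minmass, , drop = FALSE]
}

# Jonker-Volgenant style optimal assignment (minimise total cost) on a square
# cost matrix; returns for each row its assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free_j <- which(!used[2:(m + 1)])
      cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

# frame-to-frame matching of active tracks to detections with birth/death
# dummies; infeasible links (displacement > max_speed) get a prohibitive cost
match_frame <- function(prev_xy, det_xy, max_speed) {
  nt <- nrow(prev_xy); nd <- nrow(det_xy)
  BIG <- 1e12
  unassign <- max_speed^2
  cost <- matrix(BIG, nt + nd, nd + nt)
  if (nt && nd) {
    d2 <- outer(prev_xy[, 1], det_xy[, 1], "-")^2 +
      outer(prev_xy[, 2], det_xy[, 2], "-")^2
    d2[d2 > max_speed^2] <- BIG
    cost[seq_len(nt), seq_len(nd)] <- d2
  }
  for (i in seq_len(nt)) cost[i, nd + i] <- unassign
  for (j in seq_len(nd)) cost[nt + j, j] <- unassign
  if (nd && nt) cost[(nt + 1):(nt + nd), (nd + 1):(nd + nt)] <- 0
  assign <- solve_assignment(cost)
  # track i -> detection assign[i] if <= nd else unmatched
  link <- assign[seq_len(nt)]
  link[link > nd] <- NA_integer_
  link
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame optimal bipartite matching minimising total squared
#' displacement, with per-link displacement bounded by `max_speed` px/frame.
#' A track missing up to `memory` consecutive frames stays eligible for
#' reconnection; retained tracks have at least `filter_frames` observed
#' points. Ties are deterministic (lowest track id wins through the ordered
#' assignment).
#'
#' @param detections `data.frame` with columns `frame` (integer), `x`, `y`
#'   (px). May cover non-consecutive frames.
#' @param max_speed Maximum displacement per link, px/frame.
#' @param memory Maximum number of consecutively missed frames.
#' @param filter_frames Minimum number of observed points per retained track.
#' @return `data.frame` `track_id`, `frame`, `x`, `y`, `imputed` (all FALSE;
#'   see [impute_gaps()]).
#' @export
link_tracks <- function(detections, max_speed = 20, memory = 10,
                        filter_frames = 20) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (!nrow(detections)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), imputed = logical(0)))
  }
  detections <- detections[order(detections$frame), ]
  frames <- min(detections$frame):max(detections$frame)
  tracks <- list()   # each: list(points = data.frame(frame,x,y), last_frame)
  active <- integer(0)
  next_id <- 1L
  for (t in frames) {
    det <- detections[detections$frame == t, , drop = FALSE]
    # drop expired tracks
    if (length(active)) {
      gap <- t - vapply(tracks[active], function(z) z$last_frame, 0) - 1L
      active <- active[gap <= memory]
    }
    nd <- nrow(det)
    if (nd == 0) next
    link <- rep(NA_integer_, length(active))
    if (length(active)) {
      prev_xy <- t(vapply(tracks[active], function(z) {
        p <- z$points
        c(p$x[nrow(p)], p$y[nrow(p)])
      }, numeric(2)))
      link <- match_frame(prev_xy, cbind(det$x, det$y), max_speed)
    }
    used_det <- stats::na.omit(link)
    for (i in seq_along(active)) {
      if (!is.na(link[i])) {
        id <- active[i]
        tracks[[id]]$points <- rbind(tracks[[id]]$points,
                                     data.frame(frame = t,
                                                x = det$x[link[i]],
                                                y = det$y[link[i]]))
        tracks[[id]]$last_frame <- t
      }
    }
    new_det <- setdiff(seq_len(nd), used_det)
    for (j in new_det) {
      tracks[[next_id]] <- list(points = data.frame(frame = t, x = det$x[j],
                                                    y = det$y[j]),
                                last_frame = t)
      active <- c(active, next_id)
      next_id <- next_id + 1L
    }
  }
  keep <- which(vapply(tracks, function(z) nrow(z$points), 0) >= filter_frames)
  if (!length(keep)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), imputed = logical(0)))
  }
  out <- do.call(rbind, lapply(seq_along(keep), function(k) {
    p <- tracks[[keep[k]]]$points
    data.frame(track_id = k, frame = p$frame, x = p$x, y = p$y,
               imputed = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Linearly impute missing frames inside tracks
#'
#' Missing positions between flanking observed points are filled by linear
#' interpolation; observed points are unchanged and filled points are flagged
#' in `imputed`. Gaps at track boundaries cannot be imputed (tracks already
#' span only their observed range).
#'
#' @param tracks Track table (`track_id`, `frame`, `x`, `y`, optionally
#'   `imputed`).
#' @return Track table where consecutive frames differ by exactly 1.
#' @export
impute_gaps <- function(tracks) {
  pieces <- lapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$frame), ]
    full <- d$frame[1]:d$frame[nrow(d)]
    if (length(full) == nrow(d)) {
      d$imputed <- if (is.null(d$imputed)) FALSE else d$imputed
      return(d)
    }
    x <- stats::approx(d$frame, d$x, xout = full)$y
    y <- stats::approx(d$frame, d$y, xout = full)$y
    out <- d[rep(1, length(full)), , drop = FALSE]
    out$frame <- full
    out$x <- x
    out$y <- y
    out$imputed <- !(full %in% d$frame)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Detect and track cells on one movie channel
#'
#' @param mv An [movie()] (preprocess first; see [normalize_and_blur()]).
#' @param channel Channel name to track.
#' @param diameter,separation,minmass,max_speed,memory,filter_frames Tracking
#'   parameters in pixel units (defaults are the published values
#'   25/15/5000/20/10/20).
#' @param ... Passed to [detect_cells()].
#' @return An `lm_tracks` table in px and um with calibration metadata.
#' @export
track_movie <- function(mv, channel, diameter = 25, separation = 15,
                        minmass = 5000, max_speed = 20, memory = 10,
                        filter_frames = 20, ...) {
  stopifnot(inherits(mv, "lm_movie"), channel %in% mv$channel_names)
  a <- mv$channels[[channel]]
  M <- dim(a)[3]
  dets <- lapply(seq_len(M), function(t) {
    d <- detect_cells(a[, , t], diameter = diameter, separation = separation,
                      minmass = minmass, ...)
    if (nrow(d)) d$frame <- t - 1L
    d
  })
  dets <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  if (is.null(dets) || !nrow(dets)) {
    tr <- data.frame(track_id = integer(0), frame = integer(0),
                     x = numeric(0), y = numeric(0), imputed = logical(0))
  } else {
    tr <- impute_gaps(link_tracks(dets, max_speed = max_speed,
                                  memory = memory,
                                  filter_frames = filter_frames))
  }
  out <- data.frame(track_id = tr$track_id, frame = tr$frame,
                    t_seconds = tr$frame * mv$frame_interval,
                    x_px = tr$x, y_px = tr$y,
                    x_um = tr$x * mv$pixel_size, y_um = tr$y * mv$pixel_size,
                    phenotype = channel,
                    regime = NA_character_)
  out$imputed <- tr$imputed
  attr(out, "pixel_size") <- mv$pixel_size
  attr(out, "frame_interval") <- mv$frame_interval
  class(out) <- c("lm_tracks", "data.frame")
  out
}
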
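# A PredictionMap is a list: scores (X x Y x M array, NA where unscored),
# filled (logical array: TRUE where the score came from watershed filling),
# provenance (label).

new_prediction_map <- function(scores, filled = NULL, provenance = "model") {
  list(scores = scores,
       filled = filled %||% array(FALSE, dim(scores)),
       provenance = provenance)
}

#' Render spatial model predictions to a per-pixel score map
#'
#' Scores overlapping moving windows with a level-3 (single-frame) or level-4
#' (video) model and averages window scores into every covered pixel; window
#' placement always includes the frame borders, so no margin is left
#' unscored.
#'
#' @param model Fitted `lm_model` (level 3 or 4).
#' @param mv An [movie()].
#' @param channel Channel to score.
#' @param window Spatial window edge, px (model input size).
#' @param stride Window stride, px; must be <= `window`.
#' @param window_t,stride_t Temporal window/stride for level 4.
#' @return A PredictionMap.
#' @export
render_spatial_predictions <- function(model, mv, channel, window = 64L,
                                       stride = 32L, window_t = 16L,
                                       stride_t = 8L) {
  stopifnot(inherits(mv, "lm_movie"))
  if (stride > window) stop("stride > window leaves coverage gaps",
                            call. = FALSE)
  a <- mv$channels[[channel]]
  d <- dim(a)
  positions <- function(n, w, s) {
    p <- unique(c(seq(1L, max(1L, n - w + 1L), by = s), max(1L, n - w + 1L)))
    p
  }
  px <- positions(d[1], window, stride)
  py <- positions(d[2], window, stride)
  acc <- array(0, d); cnt <- array(0, d)
  if (model$level == 3L) {
    for (t in seq_len(d[3])) {
      batch <- list(); where <- list()
      for (x0 in px) for (y0 in py) {
        xr <- x0:(x0 + window - 1L); yr <- y0:(y0 + window - 1L)
        batch[[length(batch) + 1]] <- array(a[xr, yr, t],
                                            c(window, window, 1L))
        where[[length(where) + 1]] <- list(xr = xr, yr = yr, tr = t)
      }
      sc <- predict_scores(model, batch)
      for (k in seq_along(sc)) {
        w <- where[[k]]
        acc[w$xr, w$yr, w$tr] <- acc[w$xr, w$yr, w$tr] + sc[k]
        cnt[w$xr, w$yr, w$tr] <- cnt[w$xr, w$yr, w$tr] + 1
      }
    }
  } else if (model$level == 4L) {
    if (stride_t > window_t) stop("stride > window leaves coverage gaps",
                                  call. = FALSE)
    pt <- positions(d[3], window_t, stride_t)
    for (t0 in pt) {
      tr <- t0:(t0 + window_t - 1L)
      batch <- list(); where <- list()
      for (x0 in px) for (y0 in py) {
        xr <- x0:(x0 + window - 1L); yr <- y0:(y0 + window - 1L)
        batch[[length(batch) + 1]] <-
          array(aperm(a[xr, yr, tr], c(3, 1, 2)),
                c(window_t, window, window, 1L))
        where[[length(where) + 1]] <- list(xr = xr, yr = yr, tr = tr)
      }
      sc <- predict_scores(model, batch)
      for (k in seq_along(sc)) {
        w <- where[[k]]
        acc[w$xr, w$yr, w$tr] <- acc[w$xr, w$yr, w$tr] + sc[k]
        cnt[w$xr, w$yr, w$tr] <- cnt[w$xr, w$yr, w$tr] + 1
      }
    }
  } else stop("spatial rendering needs a level 3 or 4 model", call. = FALSE)
  scores <- array(NA_real_, d)
  scores[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  new_prediction_map(scores, provenance = paste0("level", model$level))
}

#' Paint per-track scores into a score map
#'
#' Each track's score is painted onto a disk of radius `paint_width` px
#' around every (t, x, y) point; overlapping paints are averaged. Pixels
#' without any track remain unscored (see [watershed_fill()]).
#'
#' @param track_scores `data.frame` with `track_id`, `score`.
#' @param tracks Track table with pixel coordinates.
#' @param shape Integer c(X, Y, M) of the target movie.
#' @param paint_width Disk radius, px (default 5).
#' @return A PredictionMap.
#' @export
render_track_predictions <- function(track_scores, tracks, shape,
                                     paint_width = 5L) {
  acc <- array(0, shape); cnt <- array(0, shape)
  off <- expand.grid(dx = -paint_width:paint_width,
                     dy = -paint_width:paint_width)
  off <- off[off$dx^2 + off$dy^2 <= paint_width^2, ]
  sc <- setNames(track_scores$score, track_scores$track_id)
  for (i in seq_len(nrow(tracks))) {
    s <- sc[as.character(tracks$track_id[i])]
    if (is.na(s)) next
    t <- tracks$frame[i] + 1L
    if (t < 1 || t > shape[3]) next
    xs <- round(tracks$x_px[i] %||% tracks$x[i]) + 1L + off$dx
    ys <- round(tracks$y_px[i] %||% tracks$y[i]) + 1L + off$dy
    ok <- xs >= 1 & xs <= shape[1] & ys >= 1 & ys <= shape[2]
    lin <- cbind(xs[ok], ys[ok], t)
    acc[lin] <- acc[lin] + s
    cnt[lin] <- cnt[lin] + 1
  }
  scores <- array(NA_real_, shape)
  scores[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  new_prediction_map(scores, provenance = "track")
}

#' Fill unscored pixels from their nearest scored pixel
#'
#' Every blank pixel receives the score of its nearest scored pixel in
#' (t, x, y) space (Euclidean, with a configurable weight on the temporal
#' axis; 1 frame = 1 px by default). Ties break deterministically towards the
#' lowest (t, y, x). Already-scored pixels are never changed, so the
#' operation is idempotent.
#'
#' @param map A PredictionMap.
#' @param time_weight Pixels per frame in the distance metric.
#' @return The filled PredictionMap (no NA left; `filled` flags the new
#'   pixels).
#' @export
watershed_fill <- function(map, time_weight = 1) {
  scores <- map$scores
  d <- dim(scores)
  seed_lin <- which(!is.na(scores))
  if (!length(seed_lin)) stop("fully blank map: nothing to fill from",
                              call. = FALSE)
  blank_lin <- which(is.na(scores))
  if (!length(blank_lin)) return(map)
  coord <- function(lin) {
    lin0 <- lin - 1L
    x <- lin0 %% d[1]
    y <- (lin0 %/% d[1]) %% d[2]
    t <- lin0 %/% (d[1] * d[2])
    cbind(x, y, t)
  }
  sc_seed <- scores[seed_lin]
  cs <- coord(seed_lin)
  # deterministic ties: order seeds by (t, y, x) and keep the first minimum
  ord <- order(cs[, 3], cs[, 2], cs[, 1])
  cs <- cs[ord, , drop = FALSE]
  sc_seed <- sc_seed[ord]
  cb <- coord(blank_lin)
  chunk <- 4000L
  for (start in seq(1L, length(blank_lin), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(blank_lin))
    d2 <- outer(cb[ix, 1], cs[, 1], "-")^2 +
      outer(cb[ix, 2], cs[, 2], "-")^2 +
      (time_weight * outer(cb[ix, 3], cs[, 3], "-"))^2
    nearest <- max.col(-d2, ties.method = "first")
    scores[blank_lin[ix]] <- sc_seed[nearest]
  }
  filled <- map$filled
  filled[blank_lin] <- TRUE
  new_prediction_map(scores, filled, map$provenance)
}

#' Pixel-level AUC of a prediction map
#'
#' AUC over labelled pixels, optionally excluding "empty" pixels without cell
#' context (context intensity below a floor in all supplied channels) and
#' optionally subsampling pixels for tractability (seed-deterministic).
#'
#' @param map A (filled) PredictionMap.
#' @param truth Logical/0-1 array of the same shape (positive class).
#' @param context Optional list of intensity arrays used for the empty-area
#'   exclusion.
#' @param context_floor Fraction of each context channel's maximum below
#'   which a pixel counts as empty (default 0.05).
#' @param max_pixels Subsample cap (default 2e5).
#' @param seed Subsampling seed.
#' @return AUC scalar.
#' @export
pixel_auc <- function(map, truth, context = NULL, context_floor = 0.05,
                      max_pixels = 2e5, seed = 1L) {
  scores <- map$scores
  stopifnot(identical(dim(scores), dim(truth)))
  keep <- !is.na(scores)
  if (!is.null(context)) {
    ctx <- Reduce(`|`, lapply(context, function(a) a > context_floor * max(a)))
    keep <- keep & ctx
  }
  idx <- which(keep)
  if (length(idx) > max_pixels) {
    set.seed(seed)
    idx <- sample(idx, max_pixels)
  }
  lab <- as.integer(as.logical(truth[idx]))
  if (length(unique(lab)) < 2) {
    stop("AUC undefined: single-class truth after exclusion", call. = FALSE)
  }
  auc_score(scores[idx], lab)
}
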
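# flood fill (4-connectivity) of TRUE pixels starting from (sx, sy); returns
# logical matrix of the reached component
flood_component <- function(mask, sx, sy) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(FALSE, nx, ny)
  if (!mask[sx, sy]) return(comp)
  queue <- matrix(c(sx, sy), 1, 2)
  comp[sx, sy] <- TRUE
  while (nrow(queue)) {
    cur <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      px <- cur[1] + d[1]; py <- cur[2] + d[2]
      if (px >= 1 && px <= nx && py >= 1 && py <= ny &&
          mask[px, py] && !comp[px, py]) {
        comp[px, py] <- TRUE
        queue <- rbind(queue, c(px, py))
      }
    }
  }
  comp
}

#' Ellipse fit of a detected cell
#'
#' Thresholds the background-subtracted patch at a fraction of its peak,
#' takes the connected component containing the detection, and derives the
#' ellipse from its second central moments (axis lengths `4 sqrt(eigenvalue)`,
#' i.e. exact for a solid ellipse). The major axis is the "cell size";
#' eccentricity is `sqrt(1 - (minor/major)^2)`.
#'
#' @param frame Numeric matrix.
#' @param detection One-row data.frame with `x`, `y` (0-based px) — e.g. from
#'   [detect_cells()].
#' @param pixel_size um per pixel for axis conversion.
#' @param patch_radius Half-width of the analysis patch, px.
#' @param threshold_frac Segmentation threshold as fraction of peak (0.5).
#' @return One-row data.frame `major_axis`, `minor_axis` (um), `eccentricity`,
#'   `orientation` (radians), `border` (blob touches the patch border; such
#'   shapes should be omitted from statistics).
#' @export
fit_ellipse <- function(frame, detection, pixel_size = DEFAULT_PIXEL_SIZE,
                        patch_radius = 15, threshold_frac = 0.5) {
  cx <- round(detection$x[1]) + 1L
  cy <- round(detection$y[1]) + 1L
  nx <- nrow(frame); ny <- ncol(frame)
  x0 <- max(1L, cx - patch_radius); x1 <- min(nx, cx + patch_radius)
  y0 <- max(1L, cy - patch_radius); y1 <- min(ny, cy + patch_radius)
  patch <- frame[x0:x1, y0:y1]
  # background from the patch border ring: robust to blobs whose tails cover
  # much of the patch interior
  ring <- c(patch[1, ], patch[nrow(patch), ], patch[, 1], patch[, ncol(patch)])
  bg <- stats::median(ring)
  sub <- patch - bg
  peak <- max(sub)
  if (peak <= 0) {
    return(data.frame(major_axis = NA_real_, minor_axis = NA_real_,
                      eccentricity = NA_real_, orientation = NA_real_,
                      border = TRUE))
  }
  mask <- sub >= threshold_frac * peak
  sx <- cx - x0 + 1L; sy <- cy - y0 + 1L
  # if the centre pixel itself is below threshold, seed from the patch peak
  if (!mask[sx, sy]) {
    pk <- which(sub == peak, arr.ind = TRUE)[1, ]
    sx <- pk[1]; sy <- pk[2]
  }
  comp <- flood_component(mask, sx, sy)
  idx <- which(comp, arr.ind = TRUE)
  border <- any(idx[, 1] %in% c(1, nrow(comp))) ||
    any(idx[, 2] %in% c(1, ncol(comp)))
  mx <- mean(idx[, 1]); my <- mean(idx[, 2])
  cxx <- mean((idx[, 1] - mx)^2); cyy <- mean((idx[, 2] - my)^2)
  cxy <- mean((idx[, 1] - mx) * (idx[, 2] - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  lam <- pmax(ev$values, 1e-12)
  major <- 4 * sqrt(lam[1]); minor <- 4 * sqrt(lam[2])
  data.frame(major_axis = major * pixel_size,
             minor_axis = minor * pixel_size,
             eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
             orientation = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
             border = border)
}

#' Per-track morphology from a movie channel
#'
#' Fits an ellipse at every observed track point and summarises per track
#' with the median size (major axis), median eccentricity and the sd of
#' eccentricity over time.
#'
#' @param mv An [movie()].
#' @param channel Channel name.
#' @param tracks `lm_tracks` table for that channel (pixel coordinates).
#' @param ... Passed to [fit_ellipse()].
#' @return `data.frame` per track: `track_id`, `median_size`, `median_ecc`,
#'   `ecc_std`, `n_shapes`.
#' @export
track_morphology <- function(mv, channel, tracks, ...) {
  stopifnot(inherits(mv, "lm_movie"))
  a <- mv$channels[[channel]]
  rows <- lapply(split(tracks, tracks$track_id), function(d) {
    sh <- lapply(seq_len(nrow(d)), function(i) {
      t <- d$frame[i] + 1L
      if (t < 1 || t > dim(a)[3]) return(NULL)
      fit_ellipse(a[, , t],
                  data.frame(x = d$x_px[i] %||% d$x[i],
                             y = d$y_px[i] %||% d$y[i]),
                  pixel_size = mv$pixel_size, ...)
    })
    sh <- do.call(rbind, sh)
    sh <- sh[!sh$border & is.finite(sh$major_axis), , drop = FALSE]
    if (!nrow(sh)) return(NULL)
    data.frame(track_id = d$track_id[1],
               median_size = stats::median(sh$major_axis),
               median_ecc = stats::median(sh$eccentricity),
               ecc_std = if (nrow(sh) > 1) stats::sd(sh$eccentricity) else 0,
               n_shapes = nrow(sh))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal component summary of morphology
#'
#' PCA of per-track median size and median eccentricity (standardized). The
#' size loading of PC1 is forced positive for reproducibility. When a
#' velocity column is supplied, correlations of PC1 scores (and of the
#' eccentricity sd) with velocity are reported.
#'
#' @param morph Per-track morphology (`median_size`, `median_ecc`, optionally
#'   `ecc_std`, `median_velocity`).
#' @return List: `scores`, `loadings` (2 x 2, columns PC1/PC2),
#'   `var_fraction`, `cor_pc1_velocity`, `cor_eccstd_velocity` (NA when no
#'   velocity supplied).
#' @export
morphology_pca <- function(morph) {
  if (nrow(morph) < 3) stop("need at least 3 tracks for PCA", call. = FALSE)
  feats <- c("median_size", "median_ecc")
  for (f in feats) {
    if (stats::sd(morph[[f]]) == 0) {
      stop(sprintf("feature '%s' is constant; PCA is degenerate", f),
           call. = FALSE)
    }
  }
  x <- scale(as.matrix(morph[, feats]))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  flip <- ifelse(pc$rotation["median_size", ] < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  cor_pc1 <- cor_ecc <- NA_real_
  if (!is.null(morph$median_velocity)) {
    cor_pc1 <- stats::cor(scores[, 1], morph$median_velocity)
    if (!is.null(morph$ecc_std)) {
      cor_ecc <- stats::cor(morph$ecc_std, morph$median_velocity)
    }
  }
  list(scores = scores, loadings = rot, var_fraction = vf,
       cor_pc1_velocity = cor_pc1, cor_eccstd_velocity = cor_ecc)
}
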
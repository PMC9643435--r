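# anisotropic Gaussian blob splat, additive, on a window around the centre;
# x, y 0-based continuous px; fwhm_major in px; ecc in [0,1); theta radians
splat_blob <- function(img, x, y, fwhm_major, ecc, theta, peak) {
  nx <- nrow(img); ny <- ncol(img)
  sa <- fwhm_major / (2 * sqrt(2 * log(2)))
  sb <- sa * sqrt(1 - ecc^2)
  r <- ceiling(3 * sa)
  x0 <- max(0L, floor(x) - r); x1 <- min(nx - 1L, floor(x) + r)
  y0 <- max(0L, floor(y) - r); y1 <- min(ny - 1L, floor(y) + r)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - x, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - y)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  g <- peak * exp(-0.5 * ((u / sa)^2 + (v / sb)^2))
  img[xs + 1L, ys + 1L] <- img[xs + 1L, ys + 1L] + g
  img
}

# rejection-sample n positions (0-based px) with pairwise min separation
sample_origins <- function(n, nx, ny, margin, min_sep_px) {
  pos <- matrix(NA_real_, n, 2)
  tries <- 0L
  max_tries <- 2000L * n
  got <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("overcrowding: cells cannot satisfy the configured separation",
           call. = FALSE)
    }
    cand <- c(stats::runif(1, margin, nx - 1 - margin),
              stats::runif(1, margin, ny - 1 - margin))
    if (got == 0L ||
        min(sqrt(colSums((t(pos[seq_len(got), , drop = FALSE]) - cand)^2))) >=
        min_sep_px) {
      got <- got + 1L
      pos[got, ] <- cand
    }
  }
  pos
}

# reflect a coordinate vector into [lo, hi]
reflect_into <- function(z, lo, hi) {
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  z <- ifelse(z > span, 2 * span - z, z)
  z + lo
}

#' Render a full synthetic multi-channel scene
#'
#' Produces a movie with one channel per phenotype preset plus an `FDC`
#' channel, together with complete ground truth. Cells are rendered as
#' anisotropic Gaussian blobs whose orientation and eccentricity drift slowly
#' over time; Poisson-Gaussian imaging noise is applied last. When
#' `coupling_strength > 0`, lymphocyte steps acquire an additive component
#' proportional to the local (spatially smoothed) FDC velocity.
#'
#' @param config A [scene_config()].
#' @param presets Named list of [phenotype_preset()] objects (at least one).
#' @param patient_id,movie_id Identifiers stored in the movie.
#' @return List with `movie` (an [movie()] with noise applied), `truth`
#'   (list: `tracks` ground-truth table incl. regimes, `pixel_labels`
#'   X x Y x M integer array with 0 = background and i = i-th preset,
#'   `fdc_flow` true per-pair displacement fields in px/frame, `fdc_valid`,
#'   `clean_channels` noise-free renders).
#' @export
render_scene <- function(config, presets, patient_id = "P0", movie_id = "M0") {
  stopifnot(inherits(config, "scene_config"), length(presets) >= 1)
  if (is.null(names(presets))) {
    names(presets) <- vapply(presets, `[[`, "", "name")
  }
  nx <- config$frame_shape[1]; ny <- config$frame_shape[2]
  M <- config$n_frames
  pxsz <- config$pixel_size

  fdc <- simulate_fdc_channel(config)

  # smoothed FDC flow for the lymphocyte coupling term
  smooth_flow <- NULL
  if (config$coupling_strength > 0) {
    smooth_flow <- lapply(fdc$flow, function(fl) {
      w <- blur2d(fdc$valid * 1, 6)
      fx <- blur2d(fl[, , 1] * fdc$valid, 6)
      fy <- blur2d(fl[, , 2] * fdc$valid, 6)
      ok <- w > 0.02
      out <- array(0, c(nx, ny, 2))
      out[, , 1][ok] <- fx[ok] / w[ok]
      out[, , 2][ok] <- fy[ok] / w[ok]
      out
    })
  }

  margin <- 8
  all_tracks <- list()
  clean <- list()
  id_offset <- 0L
  for (k in seq_along(presets)) {
    preset <- presets[[k]]
    n <- config$n_cells_per_phenotype
    set.seed(child_seed(config$seed, 10L + k))
    origins_px <- sample_origins(n, nx, ny, margin,
                                 config$min_separation_um / pxsz)
    tr <- simulate_tracks(preset, config, n_tracks = n,
                          origins = origins_px * pxsz,
                          seed = child_seed(config$seed, 20L + k))
    # coupling: re-integrate steps adding a term from the local FDC velocity
    if (!is.null(smooth_flow)) {
      for (id in unique(tr$track_id)) {
        sel <- which(tr$track_id == id)
        xs <- tr$x_um[sel]; ys <- tr$y_um[sel]
        dx <- diff(xs); dy <- diff(ys)
        x <- xs[1]; y <- ys[1]
        for (t in seq_along(dx)) {
          ix <- round(x / pxsz) + 1L; iy <- round(y / pxsz) + 1L
          if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny) {
            fl <- smooth_flow[[min(t, length(smooth_flow))]]
            dx[t] <- dx[t] + config$coupling_strength * fl[ix, iy, 1] * pxsz
            dy[t] <- dy[t] + config$coupling_strength * fl[ix, iy, 2] * pxsz
          }
          x <- x + dx[t]; y <- y + dy[t]
          xs[t + 1L] <- x; ys[t + 1L] <- y
        }
        tr$x_um[sel] <- xs; tr$y_um[sel] <- ys
      }
    }
    # keep cells inside the frame
    tr$x_um <- reflect_into(tr$x_um, margin * pxsz, (nx - 1 - margin) * pxsz)
    tr$y_um <- reflect_into(tr$y_um, margin * pxsz, (ny - 1 - margin) * pxsz)
    tr$x_px <- tr$x_um / pxsz
    tr$y_px <- tr$y_um / pxsz
    tr$track_id <- tr$track_id + id_offset
    id_offset <- id_offset + n
    all_tracks[[k]] <- tr

    # render: per-cell slowly drifting orientation/eccentricity
    set.seed(child_seed(config$seed, 30L + k))
    ch <- array(0, c(nx, ny, M))
    fwhm_px <- preset$cell_diameter_mean / pxsz
    for (id in unique(tr$track_id)) {
      sel <- which(tr$track_id == id)
      theta <- cumsum(c(stats::runif(1, -pi, pi),
                        stats::rnorm(length(sel) - 1L, 0, 0.15)))
      ecc_dev <- stats::filter(stats::rnorm(length(sel), 0, 0.05), 0.9,
                               method = "recursive")
      ecc <- pmin(0.95, pmax(0, preset$eccentricity_mean + as.numeric(ecc_dev)))
      for (j in seq_along(sel)) {
        t <- tr$frame[sel[j]] + 1L
        ch[, , t] <- splat_blob(ch[, , t], tr$x_px[sel[j]], tr$y_px[sel[j]],
                                fwhm_px, ecc[j], theta[j],
                                preset$intensity_mean)
      }
    }
    clean[[preset$name]] <- ch
  }
  truth_tracks <- do.call(rbind, all_tracks)
  attr(truth_tracks, "pixel_size") <- pxsz
  attr(truth_tracks, "frame_interval") <- config$frame_interval
  class(truth_tracks) <- c("lm_tracks", "data.frame")

  # ground-truth per-pixel phenotype labels
  labels <- array(0L, c(nx, ny, M))
  if (length(clean) >= 1) {
    floors <- vapply(presets, function(p) 0.05 * p$intensity_mean, 0)
    for (t in seq_len(M)) {
      stack <- vapply(clean, function(ch) as.vector(ch[, , t]),
                      numeric(nx * ny))
      stack <- matrix(stack, ncol = length(clean))
      best <- max.col(stack, ties.method = "first")
      bestval <- stack[cbind(seq_len(nrow(stack)), best)]
      lab <- ifelse(bestval > floors[best], best, 0L)
      labels[, , t] <- matrix(as.integer(lab), nx, ny)
    }
  }

  clean_all <- c(clean, list(FDC = fdc$frames))
  noisy <- Map(function(ch, ci) {
    set.seed(child_seed(config$seed, 90L + ci))
    if (config$psf_sigma > 0) {
      for (t in seq_len(M)) ch[, , t] <- blur2d(ch[, , t], config$psf_sigma)
    }
    out <- ch
    if (config$poisson_noise) {
      out <- array(stats::rpois(length(ch), pmax(ch, 0)), dim(ch))
    }
    if (config$noise_sigma > 0) {
      out <- out + stats::rnorm(length(out), 0, config$noise_sigma)
    }
    pmax(out, 0)
  }, clean_all, seq_along(clean_all))

  mv <- movie(noisy, pixel_size = pxsz, frame_interval = config$frame_interval,
              patient_id = patient_id, movie_id = movie_id)
  list(movie = mv,
       truth = list(tracks = truth_tracks,
                    pixel_labels = labels,
                    fdc_flow = fdc$flow,
                    fdc_valid = fdc$valid,
                    fdc_mean_node_speed = fdc$mean_node_speed,
                    clean_channels = clean_all))
}
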
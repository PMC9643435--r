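#' Amplitude giving a target mean FDC node speed
#'
#' Nodes oscillate sinusoidally with amplitude A (um) and period T (frames);
#' the per-frame displacement is `2 A sin(pi/T) |cos(.)|`, whose time mean is
#' `(4/pi) A sin(pi/T)` um/frame. Inverting gives the amplitude that realises
#' a requested time-mean node speed.
#'
#' @param target_um_min Desired time-mean absolute node speed, um/min.
#' @param period Oscillation period, frames.
#' @param frame_interval Seconds per frame.
#' @return Amplitude in um.
#' @export
fdc_amplitude_for_speed <- function(target_um_min, period,
                                    frame_interval = DEFAULT_FRAME_INTERVAL) {
  check_nonneg(target_um_min, "target_um_min")
  target_per_frame <- target_um_min * frame_interval / 60
  target_per_frame * pi / (4 * sin(pi / period))
}

# analytic mean node speed (um/min) implied by a config
fdc_mean_node_speed <- function(config) {
  per_frame <- (4 / pi) * config$fdc_pulse_amplitude *
    sin(pi / config$fdc_pulse_period)
  per_frame * 60 / config$frame_interval
}

#' Simulate the pulsating follicular dendritic cell channel
#'
#' Renders a random geometric network of line segments whose nodes oscillate
#' sinusoidally ("localized and pulsative" motion). Node phase and direction
#' vary smoothly across the field of view, so the interior of a segment moves
#' coherently with its endpoints. Filaments carry an intensity modulation
#' along their length (bead texture) so that optical flow is well conditioned
#' in both image directions. The returned ground-truth displacement field is
#' rasterized with the same bilinear splatting used for the intensity render,
#' i.e. it matches the rendered deformation.
#'
#' @param config A [scene_config()].
#' @param seed Optional seed override.
#' @return List with `frames` (array X x Y x M, noise-free), `flow` (list of
#'   M-1 arrays X x Y x 2, px/frame), `valid` (X x Y logical network mask),
#'   `mean_node_speed` (analytic, um/min), `nodes`, `edges`.
#' @export
simulate_fdc_channel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(child_seed(seed, 2L))
  nx <- config$frame_shape[1]; ny <- config$frame_shape[2]
  M <- config$n_frames
  px <- config$pixel_size
  amp_px <- config$fdc_pulse_amplitude / px
  period <- config$fdc_pulse_period

  # random geometric graph: nodes + edges to 2 nearest neighbours
  n_nodes <- config$fdc_n_nodes
  margin <- 6
  nodes <- cbind(stats::runif(n_nodes, margin, nx - 1 - margin),
                 stats::runif(n_nodes, margin, ny - 1 - margin))
  d <- as.matrix(stats::dist(nodes))
  diag(d) <- Inf
  edges <- unique(t(apply(
    cbind(rep(seq_len(n_nodes), 2),
          c(apply(d, 1, which.min),
            apply(d, 1, function(r) order(r)[2]))),
    1, sort)))

  # smooth phase and direction fields over the frame
  coefs <- stats::runif(6, -1, 1)
  phase_of <- function(p) pi * (coefs[1] + coefs[2] * p[, 1] / nx +
                                  coefs[3] * p[, 2] / ny)
  angle_of <- function(p) pi * (coefs[4] + coefs[5] * p[, 1] / nx +
                                  coefs[6] * p[, 2] / ny)
  # sample points along each edge with bead texture; each segment moves
  # rigidly with the phase/direction of the smooth field at its midpoint, so
  # the rendered deformation magnitude matches the node oscillation exactly
  spacing <- 0.5
  pts <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- nodes[edges[e, 1], ]; b <- nodes[edges[e, 2], ]
    len <- sqrt(sum((b - a)^2))
    ns <- max(2L, ceiling(len / spacing))
    al <- seq(0, 1, length.out = ns)
    tex <- 0.65 + 0.35 * sin(2 * pi * al * len / 10 + stats::runif(1, 0, 2 * pi))
    mid <- matrix((a + b) / 2, 1)
    pts[[e]] <- cbind(
      x = a[1] + al * (b[1] - a[1]),
      y = a[2] + al * (b[2] - a[2]),
      w = tex,
      ph = phase_of(mid), th = angle_of(mid)
    )
  }
  pts <- do.call(rbind, pts)

  # displacement (px) at frame t for each sample point
  disp_at <- function(t) {
    osc <- amp_px * sin(2 * pi * t / period + pts[, "ph"])
    cbind(osc * cos(pts[, "th"]), osc * sin(pts[, "th"]))
  }

  sigma_line <- 1.2
  frames <- array(0, c(nx, ny, M))
  flow <- vector("list", M - 1L)
  peak <- NULL
  u_prev <- disp_at(0)
  wimg_prev <- NULL
  for (t in seq_len(M)) {
    xs <- pts[, "x"] + u_prev[, 1]
    ys <- pts[, "y"] + u_prev[, 2]
    wimg <- blur2d(deposit_points(xs, ys, pts[, "w"], nx, ny), sigma_line)
    if (is.null(peak)) peak <- max(wimg)
    frames[, , t] <- wimg / peak * 150
    if (t < M) {
      u_next <- disp_at(t)
      du <- u_next - u_prev
      fx <- blur2d(deposit_points(xs, ys, pts[, "w"] * du[, 1], nx, ny),
                   sigma_line)
      fy <- blur2d(deposit_points(xs, ys, pts[, "w"] * du[, 2], nx, ny),
                   sigma_line)
      wmask <- wimg > 0.02 * peak
      fl <- array(0, c(nx, ny, 2))
      fl[, , 1][wmask] <- fx[wmask] / wimg[wmask]
      fl[, , 2][wmask] <- fy[wmask] / wimg[wmask]
      flow[[t]] <- fl
      u_prev <- u_next
    }
  }
  # network-occupancy mask: filament core (15% of peak) — excludes blur tails
  # where contributions from unrelated segments mix
  valid <- frames[, , 1] > 0.15 * 150
  list(frames = frames, flow = flow, valid = valid,
       mean_node_speed = fdc_mean_node_speed(config),
       nodes = nodes, edges = edges)
}
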
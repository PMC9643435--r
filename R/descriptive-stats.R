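#' Group motility summary
#'
#' Two velocity statistics per phenotype: the grand mean over all steps of
#' all tracks ("mean velocity per time frame", pooled) and the mean over
#' tracks of the per-track median step speed ("mean track median velocity").
#' The mean absolute turning angle is reported alongside.
#'
#' @param tracks `lm_tracks` table (one or more tracks).
#' @param phenotype Optional label to subset on (uses the `phenotype`
#'   column).
#' @param scheme Velocity scheme (see [compute_velocity()]).
#' @param conversion_factor Optional unit conversion override.
#' @return `data.frame` with `phenotype`, `mean_velocity`,
#'   `mean_track_median_velocity`, `angle_abs_mean`, `n_tracks`, `n_steps`.
#' @export
summarize_group <- function(tracks, phenotype = NULL,
                            scheme = c("centered", "forward"),
                            conversion_factor = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(phenotype)) tracks <- tracks[tracks$phenotype == phenotype, ]
  if (!nrow(tracks)) stop("empty group", call. = FALSE)
  ps <- attr(tracks, "pixel_size"); fi <- attr(tracks, "frame_interval")
  per_track <- lapply(split(tracks, tracks$track_id), function(d) {
    if (nrow(d) < 3) return(NULL)
    attr(d, "pixel_size") <- ps; attr(d, "frame_interval") <- fi
    v <- compute_velocity(d, scheme, conversion_factor)
    r <- compute_turning_angles(d)
    list(v = v, absr = abs(as.numeric(r)))
  })
  per_track <- per_track[!vapply(per_track, is.null, TRUE)]
  if (!length(per_track)) stop("no track with enough points", call. = FALSE)
  all_v <- unlist(lapply(per_track, `[[`, "v"))
  data.frame(
    phenotype = phenotype %||% tracks$phenotype[1] %||% NA_character_,
    mean_velocity = mean(all_v),
    mean_track_median_velocity =
      mean(vapply(per_track, function(z) stats::median(z$v), 0)),
    angle_abs_mean = mean(unlist(lapply(per_track, `[[`, "absr"))),
    n_tracks = length(per_track),
    n_steps = length(all_v))
}

#' Mann-Whitney U comparison of two samples
#'
#' Two-sided test; exact for small samples without ties, normal approximation
#' with tie correction otherwise (delegated to [stats::wilcox.test()]). The
#' significance threshold follows the published convention p < 1e-4.
#'
#' @param a,b Numeric samples.
#' @param alpha Significance level (default 1e-4).
#' @return List `U`, `p`, `significant`, `flag` (set when all values tie).
#' @export
mannwhitney_compare <- function(a, b, alpha = 1e-4) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1, significant = FALSE,
                flag = "all values tied"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha, flag = NULL)
}

#' Displacement versus square root of time
#'
#' Mean net displacement at each time lag, regressed on the square root of
#' the lag: a diffusive (random-walk) population gives a straight line
#' through the origin, a ballistic one shows systematic curvature.
#'
#' @param tracks `lm_tracks` table; tracks shorter than `min_length` points
#'   are ignored.
#' @param max_lag Largest lag (frames); default half the longest track.
#' @param min_length Minimum track length used.
#' @return List `slope`, `intercept`, `r_squared`, `lags`, `mean_disp`
#'   (displacement in the positions' units).
#' @export
displacement_vs_sqrt_time <- function(tracks, max_lag = NULL,
                                      min_length = 20L) {
  trs <- split_tracks(tracks, units = "px")
  trs <- trs[vapply(trs, nrow, 0L) >= min_length]
  if (!length(trs)) stop("no track with at least min_length points",
                         call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(vapply(trs, nrow, 0L)) %/% 2
  lags <- seq_len(max_lag)
  mean_disp <- vapply(lags, function(tau) {
    d <- unlist(lapply(trs, function(p) {
      n <- nrow(p)
      if (n <= tau) return(NULL)
      i <- seq_len(n - tau)
      sqrt((p[i + tau, "x"] - p[i, "x"])^2 + (p[i + tau, "y"] - p[i, "y"])^2)
    }))
    mean(d)
  }, 0)
  ok <- is.finite(mean_disp)
  if (sum(ok) < 3) stop("fewer than 3 usable lags", call. = FALSE)
  fit <- stats::lm(mean_disp[ok] ~ sqrt(lags[ok]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       lags = lags[ok], mean_disp = mean_disp[ok])
}
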
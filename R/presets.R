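#' Phenotype presets for the synthetic generator
#'
#' A preset describes the "prototypical" motion and morphology of one cell
#' population: B-cells (CD20), T-cells (CD3), follicular T-helper cells (PD1)
#' and the follicular dendritic cell network (FDC). Per-frame speeds follow a
#' heavy-tailed log-normal law, headings follow a correlated random walk, and
#' each track belongs to a directed or an undirected movement regime.
#'
#' @param name Phenotype label, one of `"CD20"`, `"CD3"`, `"PD1"`, `"FDC"`.
#' @param mean_speed Population mean per-frame speed, um/min.
#' @param speed_dispersion Log-normal shape (sdlog) of per-frame speeds.
#' @param turning_angle_std Wrapped-normal turning-angle sd (radians) of the
#'   undirected regime; directed tracks use `directed_turning_std`.
#' @param directed_fraction Proportion of tracks in the directed regime.
#' @param directed_turning_std Turning-angle sd (radians) of directed tracks.
#' @param cell_diameter_mean Blob full-width-at-half-maximum along the major
#'   axis, um ("cell size").
#' @param eccentricity_mean Mean blob eccentricity, in [0, 1).
#' @param intensity_mean Peak blob intensity, arbitrary units.
#' @param speed_calibration `"mean"` (log-normal mean equals `mean_speed`) or
#'   `"median"` (log-normal median equals `mean_speed`).
#' @return An object of class `phenotype_preset`.
#' @export
phenotype_preset <- function(name,
                             mean_speed,
                             speed_dispersion = 0.6,
                             turning_angle_std = 1.8,
                             directed_fraction = 0.3,
                             directed_turning_std = 0.25,
                             cell_diameter_mean = 6,
                             eccentricity_mean = 0.6,
                             intensity_mean = 150,
                             speed_calibration = c("mean", "median")) {
  speed_calibration <- match.arg(speed_calibration)
  check_nonneg(mean_speed, "mean_speed")
  check_positive(speed_dispersion, "speed_dispersion")
  check_nonneg(turning_angle_std, "turning_angle_std")
  check_nonneg(directed_turning_std, "directed_turning_std")
  check_positive(cell_diameter_mean, "cell_diameter_mean")
  check_positive(intensity_mean, "intensity_mean")
  if (directed_fraction < 0 || directed_fraction > 1) {
    stop("'directed_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (eccentricity_mean < 0 || eccentricity_mean >= 1) {
    stop("'eccentricity_mean' must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    name = name,
    mean_speed = mean_speed,
    speed_dispersion = speed_dispersion,
    turning_angle_std = turning_angle_std,
    directed_fraction = directed_fraction,
    directed_turning_std = directed_turning_std,
    cell_diameter_mean = cell_diameter_mean,
    eccentricity_mean = eccentricity_mean,
    intensity_mean = intensity_mean,
    speed_calibration = speed_calibration
  ), class = "phenotype_preset")
}

#' Log-normal shape from a mean/median speed pair
#'
#' For a log-normal law, `mean/median = exp(sdlog^2 / 2)`, so a published
#' (mean velocity, track-median velocity) pair pins down the dispersion:
#' `sdlog = sqrt(2 log(mean/median))`.
#'
#' @param mean_speed,median_speed Speeds in um/min (mean > median > 0).
#' @return The log-normal sdlog.
#' @export
dispersion_from_mean_median <- function(mean_speed, median_speed) {
  stopifnot(mean_speed > median_speed, median_speed > 0)
  sqrt(2 * log(mean_speed / median_speed))
}

#' Default phenotype presets
#'
#' Mean speeds are the published per-phenotype mean velocities (PD1 2.55,
#' CD3 2.06, CD20 2 um/min) and each dispersion is chosen so the law's median
#' matches the published track-median velocity (PD1 2.11, CD3 1.72, CD20
#' 1.65 um/min); see [dispersion_from_mean_median()]. Directed fractions are
#' the published DD-cluster directed proportions (CD20 0.23, CD3 0.35, PD1
#' 0.38). Qualitative ordering follows the phenotype description table: PD1
#' fastest and largest, CD20 highest step angle and lowest directed ratio,
#' CD20 most eccentric.
#'
#' @return Named list of `phenotype_preset` objects (CD20, CD3, PD1).
#' @export
default_presets <- function() {
  list(
    CD20 = phenotype_preset("CD20", mean_speed = 2.00,
                            speed_dispersion =
                              dispersion_from_mean_median(2.00, 1.65),
                            turning_angle_std = 2.2,
                            directed_fraction = 0.23,
                            cell_diameter_mean = 6,
                            eccentricity_mean = 0.80,
                            intensity_mean = 150),
    CD3 = phenotype_preset("CD3", mean_speed = 2.06,
                           speed_dispersion =
                             dispersion_from_mean_median(2.06, 1.72),
                           turning_angle_std = 1.2,
                           directed_fraction = 0.35,
                           cell_diameter_mean = 6,
                           eccentricity_mean = 0.60,
                           intensity_mean = 150),
    PD1 = phenotype_preset("PD1", mean_speed = 2.55,
                           speed_dispersion =
                             dispersion_from_mean_median(2.55, 2.11),
                           turning_angle_std = 1.6,
                           directed_fraction = 0.38,
                           cell_diameter_mean = 9,
                           eccentricity_mean = 0.45,
                           intensity_mean = 150)
  )
}

#' Scene configuration for the synthetic generator
#'
#' @param n_cells_per_phenotype Cells rendered per phenotype channel.
#' @param n_frames Number of frames M (>= 20).
#' @param frame_shape Integer c(X, Y) pixels, each >= 64.
#' @param pixel_size um per pixel.
#' @param frame_interval Seconds per frame.
#' @param noise_sigma Gaussian read-noise sd (intensity units).
#' @param poisson_noise Apply Poisson shot noise before Gaussian noise?
#' @param psf_sigma Extra isotropic PSF blur applied at render time (pixels).
#' @param fdc_pulse_amplitude Node oscillation amplitude, um.
#' @param fdc_pulse_period Oscillation period, frames.
#' @param fdc_n_nodes Number of nodes of the random geometric network.
#' @param coupling_strength Lymphocyte-to-FDC velocity coupling (unitless).
#' @param coupling_radius Radius (um) within which coupling acts.
#' @param min_separation_um Minimum initial distance between cells of one
#'   channel, um.
#' @param seed Integer seed; fully determines generator output.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_cells_per_phenotype = 10,
                         n_frames = 60,
                         frame_shape = c(256L, 256L),
                         pixel_size = DEFAULT_PIXEL_SIZE,
                         frame_interval = DEFAULT_FRAME_INTERVAL,
                         noise_sigma = 2,
                         poisson_noise = TRUE,
                         psf_sigma = 0,
                         fdc_pulse_amplitude = 0.5,
                         fdc_pulse_period = 12,
                         fdc_n_nodes = 40,
                         coupling_strength = 0,
                         coupling_radius = 8,
                         min_separation_um = 8,
                         seed = 1L) {
  if (n_cells_per_phenotype < 0) stop("non-positive counts are not allowed")
  if (n_frames < 20) stop("'n_frames' must be >= 20", call. = FALSE)
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 64L)) {
    stop("'frame_shape' must be two integers >= 64", call. = FALSE)
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  check_nonneg(noise_sigma, "noise_sigma")
  check_nonneg(psf_sigma, "psf_sigma")
  check_nonneg(fdc_pulse_amplitude, "fdc_pulse_amplitude")
  check_positive(fdc_pulse_period, "fdc_pulse_period")
  check_nonneg(coupling_strength, "coupling_strength")
  structure(list(
    n_cells_per_phenotype = as.integer(n_cells_per_phenotype),
    n_frames = as.integer(n_frames),
    frame_shape = frame_shape,
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    noise_sigma = noise_sigma,
    poisson_noise = isTRUE(poisson_noise),
    psf_sigma = psf_sigma,
    fdc_pulse_amplitude = fdc_pulse_amplitude,
    fdc_pulse_period = fdc_pulse_period,
    fdc_n_nodes = as.integer(fdc_n_nodes),
    coupling_strength = coupling_strength,
    coupling_radius = coupling_radius,
    min_separation_um = min_separation_um,
    seed = as.integer(seed)
  ), class = "scene_config")
}
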
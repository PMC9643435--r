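# Shared fixtures, built once per test run (all generated in code; no files).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small rendered multi-phenotype scene with defaults
small_scene <- function() {
  memo("small_scene", function() {
    cfg <- scene_config(seed = 5, n_cells_per_phenotype = 8,
                        frame_shape = c(160, 160), n_frames = 40,
                        min_separation_um = 12)
    render_scene(cfg, default_presets())
  })
}

# noise-free well-separated single-phenotype scene for tracking recovery
noisefree_scene <- function() {
  memo("noisefree_scene", function() {
    # undirected diffusive motion keeps initially separated cells apart for
    # the whole clip (no occlusion, per the recovery contract)
    cfg <- scene_config(seed = 9, n_cells_per_phenotype = 6,
                        frame_shape = c(160, 160), n_frames = 40,
                        noise_sigma = 0, poisson_noise = FALSE,
                        min_separation_um = 20)
    preset <- list(CD3 = phenotype_preset("CD3", mean_speed = 1,
                                          turning_angle_std = 2,
                                          directed_fraction = 0,
                                          cell_diameter_mean = 6,
                                          eccentricity_mean = 0.4))
    render_scene(cfg, preset)
  })
}

# draw an isolated Gaussian blob frame (access to the internal splat)
blob_frame <- function(nx, ny, x, y, fwhm, ecc = 0, theta = 0, peak = 200) {
  splat <- get("splat_blob", envir = asNamespace("lymphmotion"))
  splat(matrix(0, nx, ny), x, y, fwhm, ecc, theta, peak)
}

# random jitter tracks (for property loops)
random_track <- function(n, sd_step = 1.5) {
  data.frame(frame = 0:(n - 1),
             x = cumsum(c(0, stats::rnorm(n - 1, sd = sd_step))),
             y = cumsum(c(0, stats::rnorm(n - 1, sd = sd_step))))
}

# three-patient two-class track+movie world where classes differ only in
# heading persistence (same speed law, same morphology); initial positions
# effectively unconstrained so per-frame configurations match in law
persistence_world <- function() {
  memo("persistence_world", function() {
    presets <- list(
      A = phenotype_preset("A", mean_speed = 2, turning_angle_std = 2.8,
                           directed_fraction = 1, directed_turning_std = 0.15),
      B = phenotype_preset("B", mean_speed = 2, turning_angle_std = 2.8,
                           directed_fraction = 0, directed_turning_std = 0.15))
    movies <- list(); tracks <- list()
    for (pi in 1:3) {
      cfg <- scene_config(seed = 100 + pi, n_cells_per_phenotype = 14,
                          frame_shape = c(192, 192), n_frames = 40,
                          min_separation_um = 0.5)
      sc <- render_scene(cfg, presets, patient_id = paste0("P", pi),
                         movie_id = paste0("M", pi))
      movies[[paste0("M", pi)]] <- normalize_and_blur(sc$movie,
                                                      blur_sigma = 1)
      tt <- sc$truth$tracks
      tt$movie_id <- paste0("M", pi)
      tt$patient_id <- paste0("P", pi)
      tracks[[pi]] <- tt
    }
    all_tr <- do.call(rbind, tracks)
    attr(all_tr, "pixel_size") <- 0.4
    attr(all_tr, "frame_interval") <- 20
    class(all_tr) <- c("lm_tracks", "data.frame")
    list(tracks = all_tr, movies = movies)
  })
}

# three-patient two-class world where classes differ only in blob size
size_world <- function() {
  memo("size_world", function() {
    presets <- list(
      BIG = phenotype_preset("BIG", mean_speed = 2, cell_diameter_mean = 10),
      SMALL = phenotype_preset("SMALL", mean_speed = 2,
                               cell_diameter_mean = 4))
    movies <- list(); tracks <- list()
    for (pi in 1:3) {
      cfg <- scene_config(seed = 200 + pi, n_cells_per_phenotype = 10,
                          frame_shape = c(128, 128), n_frames = 30,
                          min_separation_um = 10)
      sc <- render_scene(cfg, presets, patient_id = paste0("P", pi),
                         movie_id = paste0("M", pi))
      movies[[paste0("M", pi)]] <- normalize_and_blur(sc$movie,
                                                      blur_sigma = 1)
      tt <- sc$truth$tracks
      tt$movie_id <- paste0("M", pi)
      tt$patient_id <- paste0("P", pi)
      tracks[[pi]] <- tt
    }
    all_tr <- do.call(rbind, tracks)
    attr(all_tr, "pixel_size") <- 0.4
    attr(all_tr, "frame_interval") <- 20
    class(all_tr) <- c("lm_tracks", "data.frame")
    list(tracks = all_tr, movies = movies, presets = presets)
  })
}
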
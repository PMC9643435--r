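test_that("simulate_tracks honours the zero-motion and persistence limits", {
  cfg <- scene_config(seed = 1, n_frames = 25)
  still <- simulate_tracks(phenotype_preset("X", mean_speed = 0), cfg,
                           n_tracks = 3)
  expect_true(all(tapply(still$x_um, still$track_id,
                         function(z) diff(range(z))) == 0))
  expect_true(all(tapply(still$y_um, still$track_id,
                         function(z) diff(range(z))) == 0))

  # near-constant speed, no turning: straight line, net == total
  straight <- simulate_tracks(
    phenotype_preset("X", mean_speed = 2, speed_dispersion = 1e-9,
                     turning_angle_std = 0, directed_turning_std = 0,
                     directed_fraction = 1),
    cfg, n_tracks = 2)
  for (d in split(straight, straight$track_id)) {
    dist <- compute_distances(data.frame(frame = d$frame, x = d$x_um,
                                         y = d$y_um), scale = 1)
    expect_equal(dist[["net"]], dist[["total"]], tolerance = 1e-8)
  }
})

test_that("per-frame speeds follow the calibrated heavy-tailed law", {
  cfg <- scene_config(seed = 4)
  tr <- simulate_tracks(phenotype_preset("PD1", mean_speed = 2.55),
                        cfg, n_tracks = 400)
  v <- unlist(lapply(split(tr, tr$track_id), function(d) {
    attr(d, "pixel_size") <- cfg$pixel_size
    attr(d, "frame_interval") <- cfg$frame_interval
    compute_velocity(d, "forward")
  }))
  expect_equal(mean(v), 2.55, tolerance = 0.03)
  # heavy tail: sample skewness of a log-normal is clearly positive
  expect_gt(mean(((v - mean(v)) / sd(v))^3), 0.5)

  med <- simulate_tracks(
    phenotype_preset("X", mean_speed = 2.11, speed_calibration = "median"),
    cfg, n_tracks = 400)
  med_v <- vapply(split(med, med$track_id), function(d) {
    attr(d, "pixel_size") <- cfg$pixel_size
    attr(d, "frame_interval") <- cfg$frame_interval
    stats::median(compute_velocity(d, "forward"))
  }, 0)
  expect_equal(mean(med_v), 2.11, tolerance = 0.05)
})

test_that("directed and undirected regimes differ as configured", {
  cfg <- scene_config(seed = 2)
  tr <- simulate_tracks(
    phenotype_preset("X", mean_speed = 2, turning_angle_std = 2.5,
                     directed_fraction = 0.5, directed_turning_std = 0.2),
    cfg, n_tracks = 200)
  ft <- track_feature_table(tr)
  net_dir <- ft$net_distance[ft$regime == "directed"]
  net_und <- ft$net_distance[ft$regime == "undirected"]
  expect_gt(mean(net_dir), 3 * mean(net_und))
  expect_lt(mean(ft$angle_std[ft$regime == "directed"]),
            mean(ft$angle_std[ft$regime == "undirected"]))
})

test_that("FDC channel: static limit, linearity, flow conservation", {
  base <- scene_config(seed = 6, frame_shape = c(128, 128), n_frames = 24,
                       fdc_pulse_amplitude = 0)
  fdc0 <- simulate_fdc_channel(base)
  expect_equal(fdc0$frames[, , 1], fdc0$frames[, , 24])
  expect_true(all(vapply(fdc0$flow, function(f) max(abs(f)), 0) == 0))

  mean_speed <- function(amp) {
    cfg <- scene_config(seed = 6, frame_shape = c(128, 128), n_frames = 24,
                        fdc_pulse_amplitude = amp, fdc_pulse_period = 8)
    f <- simulate_fdc_channel(cfg)
    mg <- vapply(f$flow, function(fl) {
      mean(sqrt(fl[, , 1]^2 + fl[, , 2]^2)[f$valid])
    }, 0)
    c(measured = mean(mg) * velocity_factor(cfg$pixel_size,
                                            cfg$frame_interval),
      analytic = f$mean_node_speed)
  }
  s1 <- mean_speed(0.4)
  s2 <- mean_speed(0.8)
  # rendered deformation matches the analytic node speed within 5%
  expect_equal(s1[["measured"]], s1[["analytic"]], tolerance = 0.05)
  # doubling the amplitude doubles the mean speed
  expect_equal(s2[["analytic"]] / s1[["analytic"]], 2, tolerance = 1e-9)
  expect_equal(s2[["measured"]] / s1[["measured"]], 2, tolerance = 0.05)

  # amplitude inversion helper hits a requested speed
  cfg <- scene_config(seed = 1,
                      fdc_pulse_amplitude = fdc_amplitude_for_speed(0.27, 12),
                      fdc_pulse_period = 12)
  expect_equal(lymphmotion:::fdc_mean_node_speed(cfg), 0.27,
               tolerance = 1e-12)
})

test_that("render_scene is seed-deterministic and geometrically faithful", {
  sc <- small_scene()
  cfg <- scene_config(seed = 5, n_cells_per_phenotype = 8,
                      frame_shape = c(160, 160), n_frames = 40,
                      min_separation_um = 12)
  sc2 <- render_scene(cfg, default_presets())
  expect_identical(sc$movie$channels, sc2$movie$channels)
  expect_identical(sc$truth$tracks, sc2$truth$tracks)

  # noiseless static cell: intensity-weighted centroid at ground truth
  cfg1 <- scene_config(seed = 3, n_cells_per_phenotype = 1,
                       frame_shape = c(64, 64), n_frames = 20,
                       noise_sigma = 0, poisson_noise = FALSE)
  one <- render_scene(cfg1, list(X = phenotype_preset("X", mean_speed = 0)))
  fr <- one$movie$channels$X[, , 1]
  w <- fr / sum(fr)
  cx <- sum(row(fr) * w) - 1
  cy <- sum(col(fr) * w) - 1
  gt <- one$truth$tracks[one$truth$tracks$frame == 0, ]
  expect_lt(abs(cx - gt$x_px), 0.5)
  expect_lt(abs(cy - gt$y_px), 0.5)
})

test_that("overcrowded scenes raise an explicit error", {
  cfg <- scene_config(seed = 1, n_cells_per_phenotype = 60,
                      frame_shape = c(64, 64), n_frames = 20,
                      min_separation_um = 10)
  expect_error(render_scene(cfg, list(X = phenotype_preset("X", 1))),
               "overcrowding")
})

test_that("preset and config invariants are enforced", {
  expect_error(phenotype_preset("X", mean_speed = 1, directed_fraction = 1.2),
               "directed_fraction")
  expect_error(phenotype_preset("X", mean_speed = 1, eccentricity_mean = 1),
               "eccentricity")
  expect_error(phenotype_preset("X", mean_speed = 1, cell_diameter_mean = -2))
  expect_error(scene_config(n_frames = 10), "n_frames")
  expect_error(scene_config(frame_shape = c(32, 128)), "frame_shape")
})

test_that("scene config round-trips through the key-value file", {
  cfg <- scene_config(seed = 77, n_frames = 33, frame_shape = c(96, 80),
                      noise_sigma = 1.5, coupling_strength = 2)
  path <- tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  cfg2 <- read_scene_config(path)
  for (k in c("seed", "n_frames", "frame_shape", "noise_sigma",
              "coupling_strength", "pixel_size")) {
    expect_equal(cfg2[[k]], cfg[[k]], info = k)
  }
})
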
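test_that("velocity schemes match hand-computed values", {
  still <- data.frame(frame = 0:4, x = rep(2, 5), y = rep(3, 5))
  expect_true(all(compute_velocity(still, "forward") == 0))
  expect_true(all(compute_velocity(still, "centered") == 0))

  # one (3,4) px step per frame with the conventional factor 1.23
  one <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4))
  expect_equal(compute_velocity(one, "forward", conversion_factor = 1.23),
               5 * 1.23)

  # zig-zag: centered differences cancel, forward do not
  zz <- data.frame(frame = 0:5, x = c(0, 2, 0, 2, 0, 2), y = 0)
  expect_true(all(compute_velocity(zz, "centered", conversion_factor = 1) == 0))
  expect_true(all(compute_velocity(zz, "forward", conversion_factor = 1) > 0))

  # metadata-derived conversion wins over the 1.23 default
  tr <- data.frame(frame = 0:1, x_px = c(0, 1), y_px = 0)
  attr(tr, "pixel_size") <- 0.4
  attr(tr, "frame_interval") <- 20
  expect_equal(compute_velocity(tr, "forward"), 1.2)

  expect_error(compute_velocity(one[1, ], "forward"), "at least 2")
  expect_error(compute_velocity(one, "centered"), "at least 3")
})

test_that("turning angles carry the image-coordinate sign convention", {
  line <- data.frame(frame = 0:3, x = 0:3, y = 0)
  expect_true(all(compute_turning_angles(line) == 0))
  # heading +x then +y (y down): clockwise quarter turn, +pi/2
  turn <- data.frame(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(as.numeric(compute_turning_angles(turn)), pi / 2)
  mirrored <- data.frame(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, -1))
  expect_equal(as.numeric(compute_turning_angles(mirrored)), -pi / 2)

  # independent heading-difference oracle on random tracks
  set.seed(7)
  for (rep in 1:5) {
    d <- random_track(5)
    got <- as.numeric(compute_turning_angles(d))
    seg <- diff(as.matrix(d[, c("x", "y")]))
    headings <- atan2(seg[, 2], seg[, 1])
    want <- lymphmotion:::wrap_angle(diff(headings))
    expect_equal(got, as.numeric(want), tolerance = 1e-12)
  }

  # degenerate zero-length segment: angle 0, flagged
  stall <- data.frame(frame = 0:3, x = c(0, 1, 1, 2), y = 0)
  a <- compute_turning_angles(stall)
  expect_equal(as.numeric(a), c(0, 0))
  expect_equal(attr(a, "degenerate"), c(TRUE, TRUE))
})

test_that("distances match closed-form geometry", {
  lpath <- data.frame(frame = 0:2, x = c(0, 3, 3), y = c(0, 0, 4))
  expect_equal(unname(compute_distances(lpath, scale = 1)), c(7, 5, 5))
  one <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4))
  d1 <- compute_distances(one, scale = 1)
  expect_true(all(d1 == 5))
  loop <- data.frame(frame = 0:4, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  dl <- compute_distances(loop, scale = 1)
  expect_equal(dl[["net"]], 0)
  expect_equal(dl[["total"]], 4)
})

test_that("the feature vector has the 15-entry contract", {
  set.seed(1)
  d <- random_track(25)
  fv <- summarize_features(relative_track(d, conversion_factor = 1),
                           compute_distances(d, scale = 1))
  expect_length(fv, 15)
  expect_named(fv, lymphmotion:::FEATURE_NAMES)

  # constant-speed straight track: zero spread, zero angles
  straight <- data.frame(frame = 0:20, x = 2 * (0:20), y = 0)
  fs <- summarize_features(relative_track(straight, conversion_factor = 1),
                           compute_distances(straight, scale = 1))
  expect_equal(unname(fs[c("velocity_std", "accel_mean", "angle_mean",
                           "angle_std", "angle_min", "angle_max")]),
               rep(0, 6))

  # independent re-aggregation oracle
  rel <- relative_track(d, conversion_factor = 1)
  expect_equal(unname(fv["velocity_mean"]), mean(rel[, "v"]))
  expect_equal(unname(fv["accel_max"]), max(rel[, "a"]))
  expect_equal(unname(fv["angle_std"]), sd(rel[, "r"]))
  expect_equal(unname(fv["total_distance"]),
               sum(sqrt(rowSums(diff(as.matrix(d[, c("x", "y")]))^2))))
})

test_that("the relative representation is rigid-motion invariant", {
  set.seed(11)
  for (rep in 1:25) {
    d <- random_track(sample(10:40, 1))
    th <- runif(1, -pi, pi)
    shift <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy <- as.matrix(d[, c("x", "y")]) %*% R
    d2 <- data.frame(frame = d$frame, x = xy[, 1] + shift[1],
                     y = xy[, 2] + shift[2])
    expect_equal(relative_track(d2, conversion_factor = 1),
                 relative_track(d, conversion_factor = 1), tolerance = 1e-9)
    expect_equal(
      summarize_features(relative_track(d2, conversion_factor = 1),
                         compute_distances(d2, scale = 1)),
      summarize_features(relative_track(d, conversion_factor = 1),
                         compute_distances(d, scale = 1)),
      tolerance = 1e-9)
  }
})

test_that("total >= maximum >= net over 10^4 random tracks", {
  set.seed(13)
  n <- 1e4
  ok <- vapply(seq_len(n), function(i) {
    d <- random_track(sample(3:12, 1), sd_step = runif(1, 0.1, 5))
    z <- compute_distances(d, scale = 1)
    z[["total"]] >= z[["maximum"]] - 1e-12 &&
      z[["maximum"]] >= z[["net"]] - 1e-12 && z[["net"]] >= 0
  }, TRUE)
  expect_true(all(ok))
})

test_that("standardization is reusable across folds without leakage", {
  cfg <- scene_config(seed = 3, n_frames = 30)
  tr <- simulate_tracks(phenotype_preset("CD3", 2), cfg, n_tracks = 40)
  ft <- track_feature_table(tr)
  a <- ft[1:20, ]; b <- ft[21:40, ]
  sa <- standardize_features(a)
  st <- attr(sa, "standardization")
  expect_equal(unname(colMeans(sa[lymphmotion:::FEATURE_NAMES])),
               rep(0, 15), tolerance = 1e-10)
  sb <- standardize_features(b, st)
  # held-out data standardized with training statistics, not its own
  expect_false(isTRUE(all.equal(unname(colMeans(
    sb[lymphmotion:::FEATURE_NAMES])), rep(0, 15), tolerance = 1e-6)))
})
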
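test_that("detect_cells finds well-separated blobs at sub-pixel accuracy", {
  fr <- blob_frame(100, 100, 30, 50, fwhm = 10) +
    blob_frame(100, 100, 70, 50, fwhm = 10)
  d <- detect_cells(fr / 255, diameter = 15, separation = 15, minmass = 2000)
  expect_equal(nrow(d), 2)
  d <- d[order(d$x), ]
  expect_lt(max(abs(d$x - c(30, 70))), 0.5)
  expect_lt(max(abs(d$y - 50)), 0.5)
})

test_that("minmass filters dim blobs and separation suppresses close pairs", {
  dim_fr <- blob_frame(60, 60, 30, 30, fwhm = 6, peak = 3)
  expect_equal(nrow(detect_cells(dim_fr / 255, diameter = 15, separation = 15,
                                 minmass = 5000)), 0)
  close_fr <- blob_frame(100, 100, 45, 50, fwhm = 10, peak = 200) +
    blob_frame(100, 100, 55, 50, fwhm = 10, peak = 150)
  d <- detect_cells(close_fr / 255, diameter = 15, separation = 15,
                    minmass = 2000)
  expect_equal(nrow(d), 1)

  # oracle: exhaustive local-maxima enumeration with brightness-ranked
  # suppression on the same band-passed image
  bp <- blur2d(close_fr / 255, 1) - blur2d(close_fr / 255, 15 / 4)
  bp[bp < 0] <- 0
  cand <- which(bp == lymphmotion:::max_filter(bp, 7) &
                  bp >= 0.05 * max(bp), arr.ind = TRUE)
  cand <- cand[order(bp[cand], decreasing = TRUE), , drop = FALSE]
  kept <- 0L
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (!nrow(centers) ||
        min(sqrt((centers[, 1] - cand[i, 1])^2 +
                   (centers[, 2] - cand[i, 2])^2)) >= 15) {
      centers <- rbind(centers, cand[i, ])
    }
  }
  expect_equal(nrow(d), nrow(centers))
})

test_that("the assignment solver is optimal on enumerable toys", {
  solve_assignment <- lymphmotion:::solve_assignment
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    got <- solve_assignment(cost)
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(p) !any(duplicated(p))), ,
                   drop = FALSE]
    best <- min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
    expect_equal(sum(cost[cbind(seq_len(n), got)]), best, tolerance = 1e-12)
  }
})

test_that("link_tracks follows, bridges and splits correctly", {
  # unambiguous single cell
  det <- data.frame(frame = 0:29, x = 10 + 3 * (0:29), y = 20)
  tr <- link_tracks(det, max_speed = 20, memory = 10, filter_frames = 20)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 30)

  # invisible for 5 frames (<= memory): one track spans the gap
  det2 <- det[!(det$frame %in% 10:14), ]
  tr2 <- link_tracks(det2, 20, 10, 20)
  expect_equal(length(unique(tr2$track_id)), 1)
  expect_equal(diff(range(tr2$frame)), 29)

  # 25 px jump (> max_speed): link refused; short fragments dropped
  det3 <- rbind(data.frame(frame = 0:24, x = 3 * (0:24), y = 10),
                data.frame(frame = 25:49, x = 72 + 25 + 3 * (0:24), y = 10))
  tr3 <- link_tracks(det3, 20, 10, 20)
  expect_equal(length(unique(tr3$track_id)), 2)
  tr3b <- link_tracks(det3[det3$frame <= 34, ], 20, 10, 20)
  expect_equal(length(unique(tr3b$track_id)), 1)  # 10-frame fragment dropped

  # two crossing cells resolved by minimal total squared displacement
  det4 <- do.call(rbind, lapply(0:24, function(f) {
    data.frame(frame = f, x = c(10 + 2 * f, 60 - 2 * f), y = c(10, 14))
  }))
  tr4 <- link_tracks(det4, max_speed = 10, memory = 0, filter_frames = 20)
  expect_equal(length(unique(tr4$track_id)), 2)
  for (d in split(tr4, tr4$track_id)) {
    expect_true(all(abs(diff(d$y)) < 1e-9))  # tracks keep their own row
  }
})

test_that("impute_gaps interpolates linearly and flags filled points", {
  d <- data.frame(track_id = 1, frame = c(0, 2), x = c(0, 2), y = c(0, 2))
  out <- impute_gaps(d)
  expect_equal(out$x[out$frame == 1], 1)
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE))
  # no gaps: identity
  d2 <- data.frame(track_id = 1, frame = 0:3, x = 0:3, y = 0)
  expect_equal(impute_gaps(d2)$x, 0:3)
  # multi-frame gap: points on the chord, equally spaced
  d3 <- data.frame(track_id = 1, frame = c(0, 4), x = c(0, 8), y = c(0, 4))
  out3 <- impute_gaps(d3)
  expect_equal(out3$x, c(0, 2, 4, 6, 8))
  expect_equal(out3$y, c(0, 1, 2, 3, 4))
})

test_that("tracking recovers ground truth on noise-free separable scenes", {
  sc <- noisefree_scene()
  mv <- normalize_and_blur(sc$movie, blur_sigma = 1)
  tr <- track_movie(mv, "CD3", diameter = 15, separation = 10,
                    minmass = 1000, filter_frames = 20)
  gt <- sc$truth$tracks
  # track count equals simulated cell count
  expect_equal(length(unique(tr$track_id)), length(unique(gt$track_id)))
  # >= 99% of points within 2 px of a same-frame ground-truth point
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    g <- gt[gt$frame == tr$frame[i], ]
    min(sqrt((g$x_px - tr$x_px[i])^2 + (g$y_px - tr$y_px[i])^2)) < 2
  }, TRUE)
  expect_gte(mean(hits), 0.99)
  # every retained track satisfies the minimum length
  expect_true(all(table(tr$track_id) >= 20))
  # no duplicated (frame, position): no two tracks share a detection
  expect_false(any(duplicated(tr[, c("frame", "x_px", "y_px")])))
})
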
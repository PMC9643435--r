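ns <- asNamespace("lymphmotion")

# hand-built tiny "level 3" CNN accepting any patch size
stub_model <- function(seed = 1) {
  set.seed(seed)
  structure(list(level = 3L,
                 layers = list(ns$layer_conv(c(3L, 3L), 1L, 4L),
                               ns$layer_relu(), ns$layer_globalpool(),
                               ns$layer_dense(8L, 2L)),
                 trained = TRUE),
            class = "lm_model")
}

test_that("spatial rendering averages windows and covers every pixel", {
  mv <- movie(list(A = array(runif(16 * 16 * 2), c(16, 16, 2))))
  m <- stub_model()
  expect_error(render_spatial_predictions(m, mv, "A", window = 8,
                                          stride = 9), "coverage")
  pm <- render_spatial_predictions(m, mv, "A", window = 8, stride = 4)
  expect_false(anyNA(pm$scores))

  # brute-force accumulation oracle on an 8x8 toy with window 4, stride 2
  mv2 <- movie(list(A = array(runif(8 * 8 * 1), c(8, 8, 1))))
  pm2 <- render_spatial_predictions(m, mv2, "A", window = 4, stride = 2)
  acc <- array(0, c(8, 8, 1)); cnt <- array(0, c(8, 8, 1))
  pos <- c(1, 3, 5)
  for (x0 in pos) for (y0 in pos) {
    sc <- predict_scores(m, list(array(
      mv2$channels$A[x0:(x0 + 3), y0:(y0 + 3), 1], c(4, 4, 1))))
    acc[x0:(x0 + 3), y0:(y0 + 3), 1] <- acc[x0:(x0 + 3), y0:(y0 + 3), 1] + sc
    cnt[x0:(x0 + 3), y0:(y0 + 3), 1] <- cnt[x0:(x0 + 3), y0:(y0 + 3), 1] + 1
  }
  expect_equal(pm2$scores, acc / cnt, tolerance = 1e-12)

  # interior pixels covered by >= 2 windows at stride = window/2
  interior <- cnt[3:6, 3:6, 1]
  expect_true(all(interior >= 2))
})

test_that("track painting uses disks and averages overlaps", {
  trks <- data.frame(track_id = c(1, 2), frame = 0,
                     x_px = c(5, 7), y_px = c(5, 5))
  pm <- render_track_predictions(data.frame(track_id = c(1, 2),
                                            score = c(0, 1)),
                                 trks, shape = c(12, 12, 1), paint_width = 2)
  # overlap pixels average to 0.5
  expect_equal(pm$scores[7, 6, 1], 0.5)
  expect_equal(pm$scores[5, 6, 1], 0)
  expect_equal(pm$scores[9, 6, 1], 1)
  # painted area matches rasterised-circle enumeration for one track
  pm1 <- render_track_predictions(data.frame(track_id = 1, score = 1),
                                  trks[1, ], shape = c(12, 12, 1),
                                  paint_width = 2)
  want <- sum(outer(-2:2, -2:2, function(a, b) a^2 + b^2 <= 4))
  expect_equal(sum(!is.na(pm1$scores)), want)
  # width 0 paints only the track pixel itself
  pm0 <- render_track_predictions(data.frame(track_id = 1, score = 1),
                                  trks[1, ], shape = c(12, 12, 1),
                                  paint_width = 0)
  expect_equal(which(!is.na(pm0$scores)), which(array(
    seq_len(12 * 12) == 5 + 12 * 5 + 1, c(12, 12, 1))))
})

test_that("watershed fill equals brute-force nearest-seed search", {
  set.seed(9)
  d <- c(6, 6, 3)
  scores <- array(NA_real_, d)
  seeds <- cbind(sample(6, 4, TRUE), sample(6, 4, TRUE), sample(3, 4, TRUE))
  seeds <- unique(seeds)
  for (i in seq_len(nrow(seeds))) {
    scores[seeds[i, 1], seeds[i, 2], seeds[i, 3]] <- i / 10
  }
  pm <- ns$new_prediction_map(scores)
  f <- watershed_fill(pm)
  # brute force with the documented tie rule (lowest t, then y, then x)
  ord <- order(seeds[, 3], seeds[, 2], seeds[, 1])
  s2 <- seeds[ord, , drop = FALSE]
  for (x in 1:6) for (y in 1:6) for (t in 1:3) {
    dd <- (s2[, 1] - x)^2 + (s2[, 2] - y)^2 + (s2[, 3] - t)^2
    want <- ord[which.min(dd)] / 10
    expect_equal(f$scores[x, y, t], want)
  }
  # scored pixels unchanged; idempotent; filled flags correct
  expect_equal(f$scores[!pm$filled & !is.na(pm$scores)],
               pm$scores[!is.na(pm$scores)])
  expect_identical(watershed_fill(f)$scores, f$scores)
  expect_equal(sum(f$filled), prod(d) - nrow(seeds))
  # two seeds at opposite corners bisect the volume
  sc2 <- array(NA_real_, c(7, 7, 1)); sc2[1, 1, 1] <- 0; sc2[7, 7, 1] <- 1
  f2 <- watershed_fill(ns$new_prediction_map(sc2))
  expect_equal(f2$scores[2, 2, 1], 0)
  expect_equal(f2$scores[6, 6, 1], 1)
  expect_error(watershed_fill(ns$new_prediction_map(
    array(NA_real_, c(3, 3, 1)))), "blank")
})

test_that("pixel AUC is the Mann-Whitney rank statistic", {
  set.seed(2)
  scores <- array(runif(20), c(20, 1, 1))
  truth <- array(rbinom(20, 1, 0.5), c(20, 1, 1))
  pm <- ns$new_prediction_map(scores)
  got <- pixel_auc(pm, truth)
  w <- suppressWarnings(stats::wilcox.test(scores[truth == 1],
                                           scores[truth == 0]))
  expect_equal(got, unname(w$statistic) /
                 (sum(truth == 1) * sum(truth == 0)), tolerance = 1e-12)
  # perfect and inverted maps
  expect_equal(pixel_auc(ns$new_prediction_map(array(as.numeric(truth),
                                                     dim(truth))), truth), 1)
  expect_equal(pixel_auc(ns$new_prediction_map(array(1 - truth, dim(truth))),
                         truth), 0)
  # random scores near 0.5 at 1e4 pixels
  big_t <- array(rbinom(1e4, 1, 0.5), c(100, 100, 1))
  big_s <- array(runif(1e4), c(100, 100, 1))
  expect_lt(abs(pixel_auc(ns$new_prediction_map(big_s), big_t) - 0.5), 0.05)
  # single-class truth errors
  expect_error(pixel_auc(pm, array(1, dim(truth))), "single-class")
  # empty-area exclusion drops context-free pixels
  ctx <- array(0, dim(truth)); ctx[1:10, 1, 1] <- 100
  keep_auc <- pixel_auc(pm, truth, context = list(ctx))
  manual <- auc_score(scores[1:10], truth[1:10])
  expect_equal(keep_auc, manual, tolerance = 1e-12)
})

test_that("all levels can produce comparable maps for one movie", {
  # level-1 scores painted + filled give a complete map of the movie's
  # shape (cropped clip: the exact fill is O(blank x seeds))
  sc <- noisefree_scene()
  gt <- sc$truth$tracks
  gt <- gt[gt$frame < 4, ]
  shape <- c(dim(sc$movie)[1:2], 4L)
  ids <- unique(gt$track_id)
  set.seed(3)
  pm <- render_track_predictions(
    data.frame(track_id = ids, score = runif(length(ids))),
    gt, shape, paint_width = 4)
  f <- watershed_fill(pm)
  expect_false(anyNA(f$scores))
  expect_equal(dim(f$scores), shape)
})
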
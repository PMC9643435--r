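ns <- asNamespace("lymphmotion")

# minimal handcrafted model helpers
dense_only_model <- function(W, b = numeric(ncol(W))) {
  ly <- ns$layer_dense(nrow(W), ncol(W))
  ly$W <- W; ly$b <- b
  structure(list(level = 2L, layers = list(ly), trained = TRUE),
            class = "lm_model")
}

test_that("LRP on a single linear layer is w_i * x_i exactly", {
  W <- cbind(c(0.5, -1, 2), c(1, 1, 1))
  m <- dense_only_model(W)
  x <- array(c(2, 3, -1), c(1, 3))      # 1 spatial position, 3 channels
  r <- lrp_explain(m, x, target_class = 0, eps = 1e-12)
  expect_equal(as.numeric(r), c(0.5 * 2, -1 * 3, 2 * -1), tolerance = 1e-6)
  expect_equal(sum(r), attr(r, "target_logit"), tolerance = 1e-6)
  # all-zero input: all-zero relevance
  r0 <- lrp_explain(m, array(0, c(1, 3)), target_class = 0)
  expect_true(all(r0 == 0))
})

test_that("LRP matches a hand-unrolled two-layer ReLU propagation", {
  W1 <- matrix(c(1, -1, 0.5, 2, 0, 1), 3, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1.5, -0.5, 0.3, 0.7), 2, 2)
  l1 <- ns$layer_dense(3, 2); l1$W <- W1; l1$b <- b1
  l2 <- ns$layer_dense(2, 2); l2$W <- W2; l2$b <- c(0, 0)
  m <- structure(list(level = 2L,
                      layers = list(l1, ns$layer_relu(), l2),
                      trained = TRUE), class = "lm_model")
  x <- c(1, 2, -0.5)
  eps <- 1e-9
  # forward by hand
  h_pre <- as.vector(x %*% W1 + b1)
  h <- pmax(h_pre, 0)
  z <- as.vector(h %*% W2)
  # epsilon-rule by hand, explaining unit 2 (target_class = 1)
  Rk <- c(0, z[2])
  s2 <- Rk / (z + eps * sign(z))
  Rh <- as.vector((h * W2) %*% s2)
  s1 <- Rh / (h_pre + eps * sign(h_pre))   # relu passthrough
  Rx <- as.vector((x * W1) %*% s1)
  got <- lrp_explain(m, array(x, c(1, 3)), target_class = 1, eps = eps)
  expect_equal(as.numeric(got), Rx, tolerance = 1e-6)
  # conservation with explicit bias bookkeeping
  expect_equal(sum(got) + attr(got, "bias_relevance"),
               attr(got, "target_logit"), tolerance = 1e-6)
})

test_that("LRP conserves relevance through trained conv stacks", {
  set.seed(3)
  xs <- lapply(1:40, function(i) array(rnorm(60 * 3, mean = (i %% 2)),
                                       c(60, 3)))
  y <- (1:40) %% 2
  m <- build_model(level_spec(2), filter_scale = 1 / 8, dropout = 0.1,
                   seed = 4)
  m <- ns$nn_train(m, xs, y, epochs = 5, seed = 5)
  for (i in c(1, 2)) {
    r <- lrp_explain(m, xs[[i]], target_class = 1)
    f <- attr(r, "target_logit")
    leak <- abs(sum(r) + attr(r, "bias_relevance") - f)
    expect_lt(leak, 0.05 * max(abs(f), 1e-6))
    expect_equal(dim(r), dim(xs[[i]]))
  }
  # unsupported layer type named in the error
  bad <- m; bad$layers <- c(bad$layers, list(list(type = "mystery")))
  expect_error(lrp_explain(bad, xs[[1]], 1), "mystery")
})

test_that("top true positives are the exhaustive-sort answer", {
  set.seed(6)
  feats <- as.data.frame(matrix(rnorm(30 * 15), 30))
  names(feats) <- lymphmotion:::FEATURE_NAMES
  y <- as.integer(feats$velocity_mean + rnorm(30, 0, 0.2) > 0)
  m <- ns$fit_level1(feats, y)
  ds <- list(x = feats, y = y, masks = NULL,
             meta = data.frame(sample_id = seq_len(30)))
  sc <- predict_scores(m, feats)
  tp <- which(y == 1 & sc > 0.5)
  want <- tp[order(-sc[tp])][1:3]
  got <- top_true_positives(m, ds, y = y, k = 3)
  expect_equal(got$sample_id, want)
  # k larger than #TP returns all TPs
  all_tp <- top_true_positives(m, ds, y = y, k = 1000)
  expect_equal(nrow(all_tp), length(tp))
  # no true positives: empty with warning
  expect_warning(none <- top_true_positives(m, ds, y = rep(0L, 30), k = 3),
                 "no true positives")
  expect_equal(nrow(none), 0)
})

test_that("coefficient report ranks the informative feature first", {
  set.seed(8)
  feats <- as.data.frame(matrix(rnorm(200 * 15), 200))
  names(feats) <- lymphmotion:::FEATURE_NAMES
  y <- as.integer(feats$net_distance > 0)
  m <- ns$fit_level1(feats, y)
  rep_ <- coefficient_report(m)
  expect_equal(rep_$feature[1], "net_distance")
  expect_gt(rep_$coefficient[1], 0)
  # duplicated feature column flags collinearity
  feats2 <- feats
  feats2$angle_std <- feats2$angle_mean
  expect_warning(ns$fit_level1(feats2, y), "collinear")
  # unfitted model errors
  expect_error(coefficient_report(build_model(level_spec(1))), "fitted")
})

test_that("directed class gets a positive displacement coefficient", {
  cfg <- scene_config(seed = 17)
  p <- function(lab, frac) phenotype_preset(lab, 2, turning_angle_std = 2.5,
                                            directed_fraction = frac,
                                            directed_turning_std = 0.25)
  t1 <- simulate_tracks(p("DIR", 1), cfg, n_tracks = 60, seed = 17)
  t2 <- simulate_tracks(p("UND", 0), cfg, n_tracks = 60, seed = 18)
  t2$track_id <- t2$track_id + 100
  tr <- rbind(t1, t2)
  attr(tr, "pixel_size") <- cfg$pixel_size
  attr(tr, "frame_interval") <- cfg$frame_interval
  class(tr) <- c("lm_tracks", "data.frame")
  ft <- standardize_features(track_feature_table(tr))
  # fit on the two DD-cluster features: the displacement sign is then
  # well-identified (the full 15-feature fit has collinear distance columns)
  m <- ns$fit_level1(ft[c("net_distance", "angle_std")],
                     as.integer(ft$phenotype == "DIR"))
  co <- m$coef
  expect_gt(co[["net_distance"]], 0)
  expect_lt(co[["angle_std"]], 0)
})
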
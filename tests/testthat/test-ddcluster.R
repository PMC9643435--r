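ns <- asNamespace("lymphmotion")

# feature table of two well-separated movement regimes
regime_features <- function(seed = 23, n = 300, frac_directed = 0.35) {
  cfg <- scene_config(seed = seed)
  p <- phenotype_preset("X", 2, turning_angle_std = 2.5,
                        directed_fraction = frac_directed,
                        directed_turning_std = 0.2)
  tr <- simulate_tracks(p, cfg, n_tracks = n)
  track_feature_table(tr)
}

test_that("select_features finds the two planted signals", {
  # two-signal design: only net_distance and angle_std carry class signal
  set.seed(2)
  feats <- as.data.frame(matrix(rnorm(400 * 15), 400))
  names(feats) <- lymphmotion:::FEATURE_NAMES
  y <- as.integer(feats$net_distance - feats$angle_std +
                    rnorm(400, 0, 0.4) > 0)
  m2 <- ns$fit_level1(feats, y)
  expect_setequal(select_features(coefficient_report(m2), 2),
                  c("net_distance", "angle_std"))

  # on the generator, the top features come from the displacement/angle
  # families (the only ones that differ between regimes)
  ft <- regime_features()
  std <- standardize_features(ft)
  m <- ns$fit_level1(std, as.integer(std$regime == "directed"))
  rep_ <- coefficient_report(m)
  fam <- function(f) ifelse(grepl("distance", f), "disp",
                            ifelse(grepl("angle", f), "angle", "other"))
  top2 <- select_features(rep_, 2)
  expect_true(all(fam(top2) %in% c("disp", "angle")))
  # n = 15 returns all features ranked by |coefficient|
  expect_setequal(select_features(rep_, 15), lymphmotion:::FEATURE_NAMES)
  expect_error(select_features(rep_, 16), "exceeds")
  # deterministic tie-breaking by canonical feature order
  tie <- data.frame(feature = c("b_feat", "a_feat"),
                    coefficient = c(1, -1))
  tie <- tie[order(-abs(tie$coefficient), tie$feature), ]
  tie$rank <- 1:2
  expect_equal(select_features(tie, 1), "a_feat")
})

test_that("kmeans_dd recovers regimes and labels them semantically", {
  ft <- regime_features(seed = 29, n = 400)
  res <- kmeans_dd(ft, seed = 1)
  expect_gte(mean(res$cluster == ft$regime), 0.95)
  # labelling never flips across restarts/seeds
  for (s in 2:6) {
    r2 <- kmeans_dd(ft, seed = s)
    expect_equal(r2$cluster, res$cluster)
  }
  # shuffled morphology columns cannot change assignments (movement only)
  ft2 <- ft
  ft2$median_size <- sample(seq_len(nrow(ft2)))
  ft2$median_ecc <- runif(nrow(ft2))
  r3 <- kmeans_dd(ft2, seed = 1)
  expect_equal(r3$cluster, res$cluster)
})

test_that("two-point k-means puts centres on the points", {
  ft <- data.frame(track_id = 1:8,
                   net_distance = rep(c(0, 10), each = 4),
                   angle_std = rep(c(2, 0.2), each = 4),
                   phenotype = "X")
  res <- kmeans_dd(ft, seed = 3)
  expect_equal(as.integer(sort(table(res$cluster))), c(4L, 4L))
  # standardized coordinates: centres at the two duplicated locations
  x <- scale(as.matrix(ft[c("net_distance", "angle_std")]))
  expect_equal(unname(sort(res$centers[, "net_distance"])),
               sort(unique(x[, "net_distance"])), tolerance = 1e-9)
  # degenerate identical vectors error
  ft0 <- ft; ft0$net_distance <- 1; ft0$angle_std <- 1
  expect_error(kmeans_dd(ft0, seed = 1), "degenerate")
})

test_that("compositions match brute-force counting and handle edge cases", {
  ft <- regime_features(seed = 31, n = 200)
  res <- kmeans_dd(ft, seed = 2)
  comp <- composition_report(res)
  # brute force
  und <- mean(res$cluster == "undirected")
  expect_equal(comp$undirected_pct, round(100 * und, 1))
  expect_equal(comp$undirected_pct + comp$directed_pct, 100)

  # a phenotype whose tracks all land in one cluster reports (100, 0)
  ft2 <- rbind(
    transform(regime_features(seed = 33, n = 60, frac_directed = 0),
              phenotype = "ALLUND"),
    transform(regime_features(seed = 34, n = 60, frac_directed = 1),
              phenotype = "ALLDIR"))
  ft2$track_id <- seq_len(nrow(ft2))
  res2 <- kmeans_dd(ft2, seed = 5)
  comp2 <- composition_report(res2)
  expect_gte(comp2$undirected_pct[comp2$phenotype == "ALLUND"], 95)
  expect_lte(comp2$undirected_pct[comp2$phenotype == "ALLDIR"], 5)
  # missing phenotype is omitted with a warning
  expect_warning(c3 <- composition_report(res2, phenotypes = c("ALLUND",
                                                               "GHOST")),
                 "GHOST")
  expect_equal(c3$phenotype, "ALLUND")
  # per-phenotype proportions sum to 1
  expect_true(all(abs(res2$composition$undirected +
                        res2$composition$directed - 1) < 1e-9))
})

test_that("cluster overlay export writes polylines per track", {
  ft <- regime_features(seed = 35, n = 20)
  res <- kmeans_dd(ft, seed = 1)
  cfg <- scene_config(seed = 35)
  tr <- simulate_tracks(phenotype_preset("X", 2), cfg, n_tracks = 20)
  path <- tempfile(fileext = ".svg")
  export_cluster_tracks(res, tr, path)
  svg <- readLines(path)
  expect_equal(sum(grepl("polyline", svg)), 20)
})
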
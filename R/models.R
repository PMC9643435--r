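#' Information-level specification
#'
#' The four data-representation/model pairings: (1) track features +
#' logistic regression (long-term movement), (2) raw (v, a, r) tracks + 1D
#' CNN (short-term movement), (3) single-frame 64x64 patches + 2D CNN
#' (morphology), (4) 16x64x64 video patches + 3D CNN (morphology and
#' movement).
#'
#' @param level Integer 1..4.
#' @return List `level`, `input_kind`, `model_family`.
#' @export
level_spec <- function(level) {
  level <- as.integer(level)
  stopifnot(level %in% 1:4)
  kinds <- c("track-features", "raw-track", "frame-patch", "video-patch")
  fams <- c("linear", "conv-1d", "conv-2d", "conv-3d")
  list(level = level, input_kind = kinds[level], model_family = fams[level])
}

# expected input shapes (spatial dims, excluding channel axis)
level_input_shape <- function(level) {
  switch(level, NULL, c(60L), c(64L, 64L), c(16L, 64L, 64L))
}

#' Build a classifier for an information level
#'
#' Level 1 is a logistic regression on the 15 standardized track features.
#' Levels 2-4 are CNNs: three conv blocks (filters 128/64/32 with kernel 3
#' for level 2; 256/128/64 with kernel 3x3 resp. 3x3x3 for levels 3-4), each
#' followed by ReLU and max pooling of size 2, then concatenated global max
#' and average pooling and a softmax classification head. All conv stacks use
#' L2 weight decay 0.001 and dropout. Level 2 trains with plain SGD (lr
#' 0.001), levels 3-4 with Adam (lr 0.001).
#'
#' @param spec A [level_spec()].
#' @param input_shape Spatial input shape: level 2 `c(L)` with L <= 60,
#'   level 3 `c(64, 64)`, level 4 `c(16, 64, 64)`. Level 1 ignores it.
#' @param n_channels Input channels (3 for level 2 sequences, 1 for images).
#' @param filter_scale Multiplier on the filter counts; 1 reproduces the
#'   reference architecture, smaller values give desk-scale models for
#'   testing (clearly non-default).
#' @param dropout Dropout rate on the conv stacks (default 0.25).
#' @param seed Seed for weight initialisation.
#' @return An `lm_model` object.
#' @export
build_model <- function(spec, input_shape = NULL, n_channels = NULL,
                        filter_scale = 1, dropout = 0.25, seed = 1L) {
  level <- spec$level
  if (level == 1L) {
    return(structure(list(level = 1L, coef = NULL, feature_names = NULL,
                          trained = FALSE),
                     class = "lm_model"))
  }
  want <- level_input_shape(level)
  if (is.null(input_shape)) input_shape <- want
  if (level == 2L) {
    if (length(input_shape) != 1L || input_shape[1] > 60L ||
        input_shape[1] < 3L) {
      stop("level 2 expects input shape c(L) with 3 <= L <= 60", call. = FALSE)
    }
    n_channels <- n_channels %||% 3L
    filters <- c(128L, 64L, 32L)
    kernel <- 3L
  } else {
    if (!identical(as.integer(input_shape), want)) {
      stop(sprintf("level %d expects input shape c(%s); got c(%s)", level,
                   paste(want, collapse = ", "),
                   paste(input_shape, collapse = ", ")), call. = FALSE)
    }
    n_channels <- n_channels %||% 1L
    filters <- c(256L, 128L, 64L)
    kernel <- rep(3L, length(want))
  }
  filters <- pmax(1L, round(filters * filter_scale))
  set.seed(seed)
  layers <- list()
  in_ch <- n_channels
  for (f in filters) {
    layers <- c(layers, list(layer_conv(kernel, in_ch, f), layer_relu(),
                             layer_pool(), layer_dropout(dropout)))
    in_ch <- f
  }
  layers <- c(layers, list(layer_globalpool(),
                           layer_dense(2L * in_ch, 2L)))
  structure(list(level = level, layers = layers,
                 input_shape = as.integer(input_shape),
                 n_channels = n_channels,
                 optimizer = if (level == 2L) "sgd" else "adam",
                 lr = 0.001, filter_scale = filter_scale,
                 trained = FALSE),
            class = "lm_model")
}

#' @export
print.lm_model <- function(x, ...) {
  if (x$level == 1L) {
    cat("<lm_model> level 1 logistic regression",
        if (isTRUE(x$trained)) "(fitted)" else "(unfitted)", "\n")
  } else {
    cat(sprintf("<lm_model> level %d CNN, %d parameters, %s, %s\n",
                x$level, nn_param_count(x), x$optimizer,
                if (isTRUE(x$trained)) "trained" else "untrained"))
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `lm_model`.
#' @return Integer parameter count (coefficients + intercept for level 1).
#' @export
param_count <- function(model) {
  if (model$level == 1L) {
    if (is.null(model$coef)) return(16L)
    return(length(model$coef))
  }
  nn_param_count(model)
}

# ---- level 1 ----------------------------------------------------------------

# fit logistic regression on standardized features; y is a 0/1 vector
fit_level1 <- function(features, y) {
  cols <- intersect(FEATURE_NAMES, names(features))
  x <- as.matrix(features[cols])
  dup <- duplicated(t(x))
  if (any(dup) || qr(cbind(1, x))$rank < ncol(x) + 1) {
    warning("collinear feature columns detected")
  }
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  structure(list(level = 1L, coef = stats::coef(fit),
                 feature_names = cols, trained = TRUE, glm_rank = fit$rank),
            class = "lm_model")
}

predict_level1 <- function(model, features) {
  x <- cbind(1, as.matrix(features[model$feature_names]))
  co <- model$coef
  co[is.na(co)] <- 0
  as.vector(1 / (1 + exp(-x %*% co)))
}

#' Predict class-1 scores
#'
#' @param model Fitted `lm_model`.
#' @param newdata Feature table (level 1) or list of input arrays (levels
#'   2-4).
#' @param masks Optional padding masks (level 2).
#' @return Numeric score vector in [0, 1].
#' @export
predict_scores <- function(model, newdata, masks = NULL) {
  if (model$level == 1L) {
    if (!isTRUE(model$trained)) stop("model is not fitted", call. = FALSE)
    predict_level1(model, newdata)
  } else {
    nn_predict(model, newdata, masks)
  }
}

# ---- folds ------------------------------------------------------------------

#' Cross-validation fold assignment
#'
#' Intra-patient: leave-one-movie-out (one fold per movie). Inter-patient:
#' 3 folds partitioning the patients with no patient overlap; assignment is
#' seed-deterministic.
#'
#' @param meta `data.frame` with `movie_id` and `patient_id` per sample.
#' @param scheme `"intra"` or `"inter"`.
#' @param n_folds Folds for the inter scheme (default 3).
#' @param seed Seed for the patient shuffle.
#' @return Integer fold id per sample.
#' @export
make_folds <- function(meta, scheme = c("intra", "inter"), n_folds = 3L,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("movie_id", "patient_id") %in% names(meta)))
  if (scheme == "intra") {
    movies <- sort(unique(meta$movie_id))
    if (length(movies) < 2) stop("intra scheme needs at least 2 movies",
                                 call. = FALSE)
    match(meta$movie_id, movies)
  } else {
    patients <- sort(unique(meta$patient_id))
    if (length(patients) < n_folds) {
      stop(sprintf("inter scheme needs at least %d patients", n_folds),
           call. = FALSE)
    }
    set.seed(seed)
    shuffled <- sample(patients)
    fold_of <- setNames(rep(seq_len(n_folds), length.out = length(patients)),
                        shuffled)
    unname(fold_of[as.character(meta$patient_id)])
  }
}

#' Clip tracks to a maximum length
#'
#' Keeps the first `max_length` observed frames of every track; used for the
#' temporal-context ablation.
#'
#' @param tracks `lm_tracks` table.
#' @param max_length Maximum points per track (>= 3).
#' @return Clipped track table.
#' @export
truncate_tracks <- function(tracks, max_length) {
  if (max_length < 3) stop("'max_length' must be >= 3", call. = FALSE)
  out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(d) {
    d[order(d$frame), ][seq_len(min(nrow(d), max_length)), , drop = FALSE]
  }))
  rownames(out) <- NULL
  for (a in c("pixel_size", "frame_interval")) {
    attr(out, a) <- attr(tracks, a)
  }
  class(out) <- class(tracks)
  out
}

# ---- AUC --------------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank statistic identity: `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where
#' `R1` is the rank sum of positive scores (midranks for ties).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- datasets ---------------------------------------------------------------

#' Assemble a dataset for one information level
#'
#' @param tracks `lm_tracks` table with `phenotype`, and `movie_id` /
#'   `patient_id` columns (added by the caller when pooling movies).
#' @param level Integer 1..4.
#' @param movies Named list of [movie()] objects (required for levels 3-4),
#'   names matching `tracks$movie_id`.
#' @param n_patches Patches sampled per movie and phenotype (levels 3-4).
#' @param patch_xy Patch edge, px (64).
#' @param patch_t Temporal depth for level 4 (16).
#' @param seed Sampling seed.
#' @param scheme Velocity scheme for the invariant representation.
#' @return A `level_dataset`: list with `level`, `x`, `y` (phenotype labels),
#'   `masks`, `meta` (`movie_id`, `patient_id`, `sample_id`).
#' @export
make_level_dataset <- function(tracks, level, movies = NULL, n_patches = 50,
                               patch_xy = 64L, patch_t = 16L, seed = 1L,
                               scheme = "centered") {
  level <- as.integer(level)
  if (is.null(tracks$movie_id)) tracks$movie_id <- "M0"
  if (is.null(tracks$patient_id)) tracks$patient_id <- "P0"
  if (level == 1L) {
    ft <- do.call(rbind, lapply(split(tracks, tracks$movie_id), function(tt) {
      for (a in c("pixel_size", "frame_interval"))
        attr(tt, a) <- attr(tracks, a)
      track_feature_table(tt, scheme = scheme)
    }))
    rownames(ft) <- NULL
    return(structure(list(level = 1L, x = ft, y = ft$phenotype, masks = NULL,
                          meta = data.frame(movie_id = ft$movie_id,
                                            patient_id = ft$patient_id,
                                            sample_id = seq_len(nrow(ft)))),
                     class = "level_dataset"))
  }
  if (level == 2L) {
    ps <- attr(tracks, "pixel_size"); fi <- attr(tracks, "frame_interval")
    key <- paste(tracks$movie_id, tracks$track_id)
    xs <- list(); masks <- list(); y <- c(); mid <- c(); pid <- c()
    for (d in split(tracks, key)) {
      if (nrow(d) < 5) next
      attr(d, "pixel_size") <- ps; attr(d, "frame_interval") <- fi
      rel <- relative_track(d, scheme)
      L <- min(nrow(rel), 60L)
      pad <- matrix(0, 60, 3)
      pad[seq_len(L), ] <- rel[seq_len(L), ]
      xs[[length(xs) + 1]] <- array(pad, c(60L, 3L))
      masks[[length(masks) + 1]] <- seq_len(60) <= L
      y <- c(y, d$phenotype[1]); mid <- c(mid, d$movie_id[1])
      pid <- c(pid, d$patient_id[1])
    }
    return(structure(list(level = 2L, x = xs, y = y, masks = masks,
                          meta = data.frame(movie_id = mid, patient_id = pid,
                                            sample_id = seq_along(xs))),
                     class = "level_dataset"))
  }
  # levels 3-4: patches from the phenotype channels
  stopifnot(!is.null(movies))
  set.seed(seed)
  half <- patch_xy %/% 2L
  xs <- list(); y <- c(); mid <- c(); pid <- c()
  for (mname in unique(tracks$movie_id)) {
    mv <- movies[[mname]]
    stopifnot(inherits(mv, "lm_movie"))
    d <- dim(mv)
    tt <- tracks[tracks$movie_id == mname, ]
    for (phen in unique(tt$phenotype)) {
      if (!phen %in% mv$channel_names) next
      a <- mv$channels[[phen]]
      tp <- tt[tt$phenotype == phen, ]
      for (s in seq_len(n_patches)) {
        # centre on a detection with probability 0.5, else uniform
        if (stats::runif(1) < 0.5 && nrow(tp)) {
          row <- tp[sample(nrow(tp), 1), ]
          cx <- round(row$x_px); cy <- round(row$y_px)
          t0 <- row$frame + 1L
        } else {
          cx <- sample(d[1], 1); cy <- sample(d[2], 1)
          t0 <- sample(d[3], 1)
        }
        cx <- min(max(cx, half), d[1] - half)
        cy <- min(max(cy, half), d[2] - half)
        xr <- (cx - half + 1L):(cx + half)
        yr <- (cy - half + 1L):(cy + half)
        if (level == 3L) {
          patch <- a[xr, yr, t0]
          xs[[length(xs) + 1]] <- array(patch, c(patch_xy, patch_xy, 1L))
        } else {
          t0 <- min(max(t0, 1L), d[3] - patch_t + 1L)
          patch <- a[xr, yr, t0:(t0 + patch_t - 1L)]
          # reorder to (t, x, y, channel)
          patch <- aperm(patch, c(3, 1, 2))
          xs[[length(xs) + 1]] <- array(patch,
                                        c(patch_t, patch_xy, patch_xy, 1L))
        }
        y <- c(y, phen); mid <- c(mid, mname)
        pid <- c(pid, mv$patient_id)
      }
    }
  }
  structure(list(level = level, x = xs, y = y, masks = NULL,
                 meta = data.frame(movie_id = mid, patient_id = pid,
                                   sample_id = seq_along(xs))),
            class = "level_dataset")
}

# ---- cross-validated task ---------------------------------------------------

#' Run one binary classification task under cross-validation
#'
#' Fits the model of the given information level on each training fold
#' (standardization and class balancing computed on the training fold only),
#' scores the test fold, and repeats `n_repeats` times with different
#' initialisations. AUC is computed at sample level by default; the unified
#' pixel-level evaluation lives in [render_track_predictions()] /
#' [pixel_auc()] and can be applied to any fitted model's scores.
#'
#' @param dataset A `level_dataset` from [make_level_dataset()].
#' @param pair Character vector of the two phenotype labels, e.g.
#'   `c("CD20", "CD3")`; the second is the positive class.
#' @param scheme `"intra"` or `"inter"`.
#' @param n_repeats Fits per fold (default 5).
#' @param seed Base seed (controls folds, balancing and initialisation).
#' @param epochs,filter_scale,batch_size Training controls for CNN levels.
#' @param balance Downsample training folds to 1:1 class balance?
#' @return List of class `cv_result`: `task`, `scheme`, `auc` (fold x repeat
#'   matrix), `mean_auc`, `std_auc`, `n_folds`, `n_repeats`, `models` (last
#'   repeat's fitted model per fold).
#' @export
run_task <- function(dataset, pair, scheme = c("intra", "inter"),
                     n_repeats = 5L, seed = 1L, epochs = 20L,
                     filter_scale = 1, batch_size = 32L, balance = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "level_dataset"), length(pair) == 2)
  keep <- dataset$y %in% pair
  if (!any(dataset$y == pair[1]) || !any(dataset$y == pair[2])) {
    stop("dataset must contain both phenotypes of the pair", call. = FALSE)
  }
  y <- as.integer(dataset$y[keep] == pair[2])
  meta <- dataset$meta[keep, ]
  folds <- make_folds(meta, scheme, seed = seed)
  level <- dataset$level
  xsub <- if (level == 1L) dataset$x[keep, ] else dataset$x[keep]
  msub <- if (!is.null(dataset$masks)) dataset$masks[keep] else NULL

  fold_ids <- sort(unique(folds))
  auc <- matrix(NA_real_, length(fold_ids), n_repeats)
  models <- vector("list", length(fold_ids))
  skipped <- character(0)
  for (fi in seq_along(fold_ids)) {
    te <- folds == fold_ids[fi]
    tr <- !te
    if (length(unique(y[te])) < 2) {
      warning(sprintf("fold %s has a single-class test set; skipped",
                      fold_ids[fi]))
      skipped <- c(skipped, as.character(fold_ids[fi]))
      next
    }
    for (rep_i in seq_len(n_repeats)) {
      rs <- child_seed(seed, 100L * fi + rep_i)
      tr_idx <- which(tr)
      if (balance) {
        set.seed(rs)
        n_min <- min(table(y[tr_idx]))
        tr_idx <- unlist(lapply(c(0L, 1L), function(cl) {
          ids <- tr_idx[y[tr_idx] == cl]
          sample(ids, n_min)
        }))
      }
      if (level == 1L) {
        st <- NULL
        xtr <- standardize_features(xsub[tr_idx, ], NULL)
        st <- attr(xtr, "standardization")
        model <- fit_level1(xtr, y[tr_idx])
        xte <- standardize_features(xsub[which(te), ], st)
        sc <- predict_scores(model, xte)
      } else {
        model <- build_model(level_spec(level),
                             input_shape = dim(xsub[[1]])[-length(dim(xsub[[1]]))],
                             n_channels = dim(xsub[[1]])[length(dim(xsub[[1]]))],
                             filter_scale = filter_scale, seed = rs)
        model <- nn_train(model, xsub[tr_idx], y[tr_idx],
                          masks = if (!is.null(msub)) msub[tr_idx] else NULL,
                          epochs = epochs, batch_size = batch_size, seed = rs)
        sc <- predict_scores(model, xsub[which(te)],
                             masks = if (!is.null(msub)) msub[which(te)]
                                     else NULL)
      }
      auc[fi, rep_i] <- auc_score(sc, y[te])
      if (rep_i == n_repeats) models[[fi]] <- model
    }
  }
  vals <- auc[is.finite(auc)]
  structure(list(task = paste(pair, collapse = "-"), scheme = scheme,
                 auc = auc, mean_auc = mean(vals), std_auc = stats::sd(vals),
                 n_folds = length(fold_ids), n_repeats = n_repeats,
                 skipped_folds = skipped, models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s (%s): AUC %.3f +/- %.3f over %d folds x %d repeats\n",
              x$task, x$scheme, x$mean_auc, x$std_auc, x$n_folds,
              x$n_repeats))
  invisible(x)
}
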
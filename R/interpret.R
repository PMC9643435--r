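stab <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

#' Layer-wise relevance propagation for the CNN levels
#'
#' Propagates the pre-softmax score of the target class back onto the input:
#' epsilon-rule on dense layers, the average-pooling branch and the first
#' (possibly signed-input) convolution; z+-rule on the remaining convolution
#' layers; winner-takes-all through max pooling. Relevance absorbed by biases
#' is tracked explicitly, so the conservation identity
#' `sum(relevance) + bias_relevance = target logit` holds up to epsilon
#' leakage.
#'
#' @param model Fitted CNN `lm_model` (level 2-4).
#' @param input Input array (spatial dims x channels, as in the datasets).
#' @param target_class 0 or 1 (softmax unit to explain; default 1).
#' @param mask Optional padding mask (level 2).
#' @param eps Epsilon stabiliser (default 1e-6).
#' @return Relevance array with the input's shape; attributes
#'   `bias_relevance` and `target_logit`.
#' @export
lrp_explain <- function(model, input, target_class = 1L, mask = NULL,
                        eps = 1e-6) {
  if (model$level == 1L) {
    stop("level 1 is interpretable by design; see coefficient_report()",
         call. = FALSE)
  }
  d <- dim(input)
  inp <- list(mat = matrix(input, prod(d[-length(d)]), d[length(d)]),
              sdims = d[-length(d)], mask = mask)
  fw <- nn_forward(model$layers, inp, train = FALSE)
  layers <- fw$layers
  caches <- fw$caches
  unit <- as.integer(target_class) + 1L
  logit <- fw$out[unit]
  R <- matrix(0, 1, length(fw$out))
  R[unit] <- logit
  bias_rel <- 0
  conv_ids <- which(vapply(layers, function(l) l$type == "conv", TRUE))
  first_conv <- if (length(conv_ids)) min(conv_ids) else -1L

  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cache <- caches[[li]]
    if (ly$type == "dense") {
      x <- cache$v
      z <- x * ly$W                        # n_in x n_out contributions
      denom <- stab(colSums(z) + ly$b, eps)
      s <- as.vector(R) / denom
      bias_rel <- bias_rel + sum(ly$b * s)
      R <- matrix(as.vector(z %*% s), nrow = 1)
    } else if (ly$type == "globalpool") {
      C <- ncol(cache$x$mat)
      Rv <- as.vector(R)
      Rmax <- Rv[seq_len(C)]; Ravg <- Rv[C + seq_len(C)]
      out <- matrix(0, nrow(cache$x$mat), C)
      out[cbind(cache$arg, seq_len(C))] <- Rmax
      xs <- cache$x$mat[cache$sel, , drop = FALSE]
      denom <- stab(colSums(xs), eps)
      out[cache$sel, ] <- out[cache$sel, , drop = FALSE] +
        sweep(xs, 2, Ravg / denom, "*")
      R <- out
    } else if (ly$type == "pool") {
      C <- ncol(R)
      out <- matrix(0, cache$in_S, C)
      for (c in seq_len(C)) {
        rs <- rowsum(R[, c], cache$arg[, c])
        out[as.integer(rownames(rs)), c] <-
          out[as.integer(rownames(rs)), c] + as.vector(rs)
      }
      R <- out
    } else if (ly$type == "conv") {
      use_eps <- li == first_conv
      Wm <- if (use_eps) ly$W else pmax(ly$W, 0)
      bm <- if (use_eps) ly$b else numeric(length(ly$b))
      cols <- cache$cols
      zdenom <- sweep(cols %*% Wm, 2, bm, "+")
      s <- R / stab(zdenom, eps)
      bias_rel <- bias_rel + sum(sweep(s, 2, bm, "*"))
      dcols <- (s %*% t(Wm)) * cols
      ci <- ly$cidx
      C_in <- ncol(cache$x$mat)
      Rxp <- matrix(0, ci$n_padded + 1L, C_in)
      for (c in seq_len(C_in)) {
        block <- dcols[, ((c - 1) * ci$K + 1):(c * ci$K), drop = FALSE]
        rs <- rowsum(as.vector(block), as.vector(ci$idx))
        Rxp[as.integer(rownames(rs)), c] <- as.vector(rs)
      }
      R <- Rxp[ci$inner_idx, , drop = FALSE]
    } else if (ly$type %in% c("relu", "dropout")) {
      # relevance passes through unchanged
    } else {
      stop(sprintf("unsupported layer type for LRP: '%s'", ly$type),
           call. = FALSE)
    }
  }
  out <- array(R, d)
  attr(out, "bias_relevance") <- bias_rel
  attr(out, "target_logit") <- logit
  out
}

#' Top true-positive prototypes
#'
#' The k correctly-classified positive samples with the highest
#' positive-class score; ties break deterministically by sample id.
#'
#' @param model Fitted `lm_model`.
#' @param dataset A `level_dataset` (with `pair`-restricted labels) or a list
#'   with `x`, `y` (0/1), `masks`, `meta`.
#' @param y 0/1 labels when `dataset$y` is not already binary.
#' @param k Number of prototypes.
#' @param threshold Classification threshold (0.5).
#' @return `data.frame` `sample_id`, `score`, ordered by descending score;
#'   empty (with a warning) when there is no true positive.
#' @export
top_true_positives <- function(model, dataset, y = NULL, k = 5L,
                               threshold = 0.5) {
  if (is.null(y)) y <- as.integer(dataset$y)
  sc <- if (model$level == 1L) predict_scores(model, dataset$x)
        else predict_scores(model, dataset$x, dataset$masks)
  tp <- which(y == 1L & sc > threshold)
  if (!length(tp)) {
    warning("no true positives")
    return(data.frame(sample_id = integer(0), score = numeric(0)))
  }
  sid <- dataset$meta$sample_id %||% seq_along(sc)
  ord <- tp[order(-sc[tp], sid[tp])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(sample_id = sid[ord], score = sc[ord])
}

#' Signed coefficients of the level-1 model, ranked by magnitude
#'
#' @param model Fitted level-1 `lm_model`.
#' @return `data.frame` `feature`, `coefficient`, `rank` (1 = largest
#'   absolute coefficient).
#' @export
coefficient_report <- function(model) {
  if (model$level != 1L || !isTRUE(model$trained)) {
    stop("need a fitted level-1 model", call. = FALSE)
  }
  co <- model$coef[-1]                 # drop intercept
  names(co) <- model$feature_names
  co[is.na(co)] <- 0
  ord <- order(-abs(co), names(co))    # ties: canonical feature-name order
  data.frame(feature = names(co)[ord], coefficient = unname(co[ord]),
             rank = seq_along(co))
}
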
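# Minimal neural-network engine for the 1D/2D/3D convolutional classifiers.
# Tensors are arrays with dim c(spatial..., channels); internally each layer
# works on a (prod(spatial) x channels) matrix. Convolutions use "same"
# zero padding, stride 1, im2col + BLAS matmul. No external framework exists
# in the target environment, hence this module.

# ---- index caches -----------------------------------------------------------

# im2col index set for spatial dims `sdims` and kernel `kernel` (same padding)
build_conv_index <- function(sdims, kernel) {
  nd <- length(sdims)
  pad <- kernel %/% 2L
  pdims <- sdims + 2L * pad
  koff <- as.matrix(expand.grid(lapply(kernel, function(k) 0:(k - 1L))))
  opos <- as.matrix(expand.grid(lapply(sdims, seq_len)))
  strides <- cumprod(c(1, pdims[-nd]))
  idx <- matrix(0L, nrow(opos), nrow(koff))
  for (q in seq_len(nrow(koff))) {
    coord <- sweep(opos, 2, koff[q, ], "+")
    idx[, q] <- as.integer((coord - 1) %*% strides) + 1L
  }
  inner <- as.matrix(expand.grid(lapply(seq_len(nd),
                                        function(i) seq_len(sdims[i]) + pad[i])))
  inner_idx <- as.integer((inner - 1) %*% strides) + 1L
  list(idx = idx, inner_idx = inner_idx, n_padded = prod(pdims),
       K = nrow(koff), n_out = nrow(opos))
}

# 2^nd candidate indices per output cell for non-overlapping pooling (size 2)
build_pool_index <- function(sdims) {
  nd <- length(sdims)
  odims <- pmax(sdims %/% 2L, 1L)
  strides <- cumprod(c(1, sdims[-nd]))
  opos <- as.matrix(expand.grid(lapply(odims, seq_len)))
  koff <- as.matrix(expand.grid(lapply(seq_len(nd), function(i) {
    if (sdims[i] >= 2L) 0:1 else 0L
  })))
  idx <- matrix(0L, nrow(opos), nrow(koff))
  for (q in seq_len(nrow(koff))) {
    coord <- opos
    for (i in seq_len(nd)) {
      coord[, i] <- if (sdims[i] >= 2L) 2L * opos[, i] - 1L + koff[q, i]
                    else opos[, i]
    }
    idx[, q] <- as.integer((coord - 1) %*% strides) + 1L
  }
  list(idx = idx, odims = odims)
}

# ---- layers -----------------------------------------------------------------

layer_conv <- function(kernel, in_ch, out_ch) {
  K <- prod(kernel)
  fan_in <- K * in_ch
  list(type = "conv", kernel = kernel, in_ch = in_ch, out_ch = out_ch,
       W = matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch), cache_key = NULL, cidx = NULL)
}

layer_relu <- function() list(type = "relu")
layer_pool <- function() list(type = "pool")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_globalpool <- function() list(type = "globalpool")
layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

conv_cols <- function(ci, x) {
  C <- ncol(x)
  xp <- matrix(0, ci$n_padded + 1L, C)       # +1: zero slot for padding
  xp[ci$inner_idx, ] <- x
  cols <- matrix(0, ci$n_out, ci$K * C)
  for (c in seq_len(C)) {
    cols[, ((c - 1) * ci$K + 1):(c * ci$K)] <-
      matrix(xp[, c][ci$idx], ci$n_out, ci$K)
  }
  cols
}

# ---- forward / backward (single sample) -------------------------------------

# x: list(mat = (S x C) matrix, sdims = spatial dims, mask = optional logical
# spatial validity vector)
nn_forward <- function(layers, x, train = FALSE, rng_dropout = NULL) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    cache <- list(x = x)
    if (ly$type == "conv") {
      key <- paste(x$sdims, collapse = "x")
      if (is.null(ly$cidx) || !identical(ly$cache_key, key)) {
        ly$cidx <- build_conv_index(x$sdims, ly$kernel)
        ly$cache_key <- key
        layers[[li]] <- ly
      }
      cols <- conv_cols(ly$cidx, x$mat)
      out <- sweep(cols %*% ly$W, 2, ly$b, "+")
      cache$cols <- cols
      x <- list(mat = out, sdims = x$sdims, mask = x$mask)
    } else if (ly$type == "relu") {
      cache$pre <- x$mat
      x$mat <- pmax(x$mat, 0)
    } else if (ly$type == "pool") {
      pi_ <- build_pool_index(x$sdims)
      C <- ncol(x$mat)
      out <- matrix(0, nrow(pi_$idx), C)
      arg <- matrix(0L, nrow(pi_$idx), C)
      for (c in seq_len(C)) {
        vals <- matrix(x$mat[, c][pi_$idx], nrow(pi_$idx), ncol(pi_$idx))
        w <- max.col(vals, ties.method = "first")
        arg[, c] <- pi_$idx[cbind(seq_len(nrow(vals)), w)]
        out[, c] <- vals[cbind(seq_len(nrow(vals)), w)]
      }
      mask <- NULL
      if (!is.null(x$mask)) {
        mvals <- matrix(x$mask[pi_$idx], nrow(pi_$idx), ncol(pi_$idx))
        mask <- rowSums(mvals) > 0
      }
      cache$arg <- arg
      cache$in_S <- nrow(x$mat)
      x <- list(mat = out, sdims = pi_$odims, mask = mask)
    } else if (ly$type == "dropout") {
      if (train) {
        m <- matrix(stats::runif(length(x$mat)) > ly$rate, nrow(x$mat))
        cache$m <- m
        x$mat <- x$mat * m / (1 - ly$rate)
      }
    } else if (ly$type == "globalpool") {
      sel <- if (!is.null(x$mask)) which(x$mask) else seq_len(nrow(x$mat))
      sub <- x$mat[sel, , drop = FALSE]
      arg <- sel[apply(sub, 2, which.max)]
      mx <- sub[cbind(match(arg, sel), seq_len(ncol(sub)))]
      av <- colMeans(sub)
      cache$arg <- arg
      cache$sel <- sel
      x <- list(mat = matrix(c(mx, av), nrow = 1),
                sdims = 1L, mask = NULL, vec = TRUE)
    } else if (ly$type == "dense") {
      v <- as.vector(x$mat)
      cache$v <- v
      x <- list(mat = matrix(v %*% ly$W + ly$b, nrow = 1), sdims = 1L,
                vec = TRUE)
    }
    caches[[li]] <- cache
  }
  list(out = as.vector(x$mat), caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, grad_out) {
  grads <- vector("list", length(layers))
  g <- matrix(grad_out, nrow = 1)
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cache <- caches[[li]]
    if (ly$type == "dense") {
      grads[[li]] <- list(dW = outer(cache$v, as.vector(g)),
                          db = as.vector(g))
      g <- matrix(as.vector(ly$W %*% t(g)), nrow = 1)
      # reshape to the input of dense (flattened)
    } else if (ly$type == "globalpool") {
      C <- ncol(cache$x$mat)
      gv <- as.vector(g)
      gmax <- gv[seq_len(C)]; gavg <- gv[C + seq_len(C)]
      out <- matrix(0, nrow(cache$x$mat), C)
      out[cbind(cache$arg, seq_len(C))] <- gmax
      out[cache$sel, ] <- out[cache$sel, , drop = FALSE] +
        matrix(gavg / length(cache$sel), length(cache$sel), C, byrow = TRUE)
      g <- out
    } else if (ly$type == "dropout") {
      if (!is.null(cache$m)) g <- g * cache$m / (1 - ly$rate)
    } else if (ly$type == "pool") {
      C <- ncol(g)
      out <- matrix(0, cache$in_S, C)
      for (c in seq_len(C)) {
        rs <- rowsum(g[, c], cache$arg[, c])
        out[as.integer(rownames(rs)), c] <-
          out[as.integer(rownames(rs)), c] + as.vector(rs)
      }
      g <- out
    } else if (ly$type == "relu") {
      g <- g * (cache$pre > 0)
    } else if (ly$type == "conv") {
      cols <- cache$cols
      grads[[li]] <- list(dW = crossprod(cols, g), db = colSums(g))
      dcols <- g %*% t(ly$W)
      ci <- ly$cidx
      C_in <- ncol(cache$x$mat)
      dxp <- matrix(0, ci$n_padded + 1L, C_in)
      for (c in seq_len(C_in)) {
        block <- dcols[, ((c - 1) * ci$K + 1):(c * ci$K), drop = FALSE]
        rs <- rowsum(as.vector(block), as.vector(ci$idx))
        dxp[as.integer(rownames(rs)), c] <- as.vector(rs)
      }
      g <- dxp[ci$inner_idx, , drop = FALSE]
    }
  }
  grads
}

# ---- training ---------------------------------------------------------------

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# xs: list of inputs (arrays dim c(spatial, C)); y in {0, 1}; masks optional
# list of spatial validity vectors (level-2 padding)
nn_train <- function(model, xs, y, masks = NULL, epochs = 20, batch_size = 32,
                     lr = NULL, l2 = 0.001, val_fraction = 0.1, patience = 8,
                     seed = 1L, verbose = FALSE) {
  layers <- model$layers
  opt <- model$optimizer
  if (is.null(lr)) lr <- model$lr
  set.seed(seed)
  n <- length(xs)
  to_input <- function(i) {
    a <- xs[[i]]
    d <- dim(a)
    list(mat = matrix(a, prod(d[-length(d)]), d[length(d)]),
         sdims = d[-length(d)],
         mask = if (!is.null(masks)) masks[[i]] else NULL)
  }
  n_val <- if (val_fraction > 0 && n >= 20) max(2L, round(val_fraction * n))
           else 0L
  idx <- sample(n)
  val_idx <- head(idx, n_val)
  tr_idx <- setdiff(idx, val_idx)

  # adam state
  mstate <- list()
  step <- 0L
  apply_grads <- function(acc, scale) {
    step <<- step + 1L
    for (li in seq_along(layers)) {
      if (is.null(acc[[li]])) next
      for (pn in c("W", "b")) {
        gname <- paste0("d", pn)
        gr <- acc[[li]][[gname]] * scale
        if (pn == "W" && l2 > 0) gr <- gr + l2 * layers[[li]][[pn]]
        key <- paste(li, pn)
        if (opt == "adam") {
          st <- mstate[[key]] %||% list(m = 0 * gr, v = 0 * gr)
          st$m <- 0.9 * st$m + 0.1 * gr
          st$v <- 0.999 * st$v + 0.001 * gr^2
          mstate[[key]] <<- st
          mh <- st$m / (1 - 0.9^step)
          vh <- st$v / (1 - 0.999^step)
          layers[[li]][[pn]] <<- layers[[li]][[pn]] - lr * mh / (sqrt(vh) + 1e-8)
        } else {
          layers[[li]][[pn]] <<- layers[[li]][[pn]] - lr * gr
        }
      }
    }
  }
  eval_loss <- function(which_idx) {
    if (!length(which_idx)) return(NA_real_)
    tot <- 0
    for (i in which_idx) {
      fw <- nn_forward(layers, to_input(i), train = FALSE)
      p <- softmax(fw$out)
      tot <- tot - log(max(p[y[i] + 1L], 1e-12))
    }
    tot / length(which_idx)
  }

  best <- Inf; best_layers <- layers; bad <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      acc <- NULL
      for (i in bs) {
        fw <- nn_forward(layers, to_input(i), train = TRUE)
        layers <- fw$layers           # keep index caches
        p <- softmax(fw$out)
        gout <- p
        gout[y[i] + 1L] <- gout[y[i] + 1L] - 1
        gr <- nn_backward(layers, fw$caches, gout)
        if (is.null(acc)) acc <- gr
        else for (li in seq_along(gr)) {
          if (!is.null(gr[[li]])) {
            acc[[li]]$dW <- acc[[li]]$dW + gr[[li]]$dW
            acc[[li]]$db <- acc[[li]]$db + gr[[li]]$db
          }
        }
      }
      apply_grads(acc, 1 / length(bs))
    }
    if (n_val > 0) {
      vl <- eval_loss(val_idx)
      if (verbose) message(sprintf("epoch %d val loss %.4f", ep, vl))
      if (vl < best - 1e-4) { best <- vl; best_layers <- layers; bad <- 0L }
      else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    } else best_layers <- layers
  }
  model$layers <- best_layers
  model$trained <- TRUE
  model
}

# class-1 probability for each sample
nn_predict <- function(model, xs, masks = NULL) {
  vapply(seq_along(xs), function(i) {
    a <- xs[[i]]
    d <- dim(a)
    inp <- list(mat = matrix(a, prod(d[-length(d)]), d[length(d)]),
                sdims = d[-length(d)],
                mask = if (!is.null(masks)) masks[[i]] else NULL)
    fw <- nn_forward(model$layers, inp, train = FALSE)
    softmax(fw$out)[2]
  }, 0)
}

# total trainable parameter count
nn_param_count <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
  }, 0))
}
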
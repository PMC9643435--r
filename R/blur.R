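# Separable Gaussian blur with reflective edge handling. Shift-and-accumulate
# implementation: cost ~ 2 * kernel_length matrix additions per image.

gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect-pad index vector for length n and pad r (abc -> cba|abc|cba)
reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  left <- pmin(pmax(rev(seq_len(r)), 1L), n)
  right <- pmin(pmax(n - seq_len(r) + 1L, 1L), n)
  c(left, seq_len(n), right)
}

#' Gaussian blur of a single frame
#'
#' @param img Numeric matrix.
#' @param sigma Blur sd in pixels; `0` returns the input unchanged.
#' @return Blurred matrix of the same shape.
#' @export
blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  nx <- nrow(img); ny <- ncol(img)
  # along rows (x)
  pad <- img[reflect_idx(nx, r), , drop = FALSE]
  out <- matrix(0, nx, ny)
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + nx - 1L), , drop = FALSE]
  }
  # along cols (y)
  pad <- out[, reflect_idx(ny, r), drop = FALSE]
  out <- matrix(0, nx, ny)
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[, j:(j + ny - 1L), drop = FALSE]
  }
  out
}

# bilinear deposit of point masses onto an nx x ny grid; x, y are 0-based
# continuous pixel coordinates, w the masses. Points outside are dropped.
deposit_points <- function(x, y, w, nx, ny) {
  keep <- x > -1 & x < nx & y > -1 & y < ny
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  img <- matrix(0, nx, ny)
  if (!length(x)) return(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  for (dx in 0:1) for (dy in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    wt <- w * (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xi >= 0 & xi < nx & yi >= 0 & yi < ny
    if (any(ok)) {
      lin <- xi[ok] + 1L + nx * yi[ok]
      add <- rowsum(wt[ok], lin)
      img[as.integer(rownames(add))] <- img[as.integer(rownames(add))] +
        as.vector(add)
    }
  }
  img
}
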